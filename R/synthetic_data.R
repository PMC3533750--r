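# Synthetic study generator: a toy genome with multi-isoform genes (exon
# skip, alternative 5'/3' splice sites, optional intron retention), a
# matched tumor/normal sample design with per-individual random effects,
# and 36-mer reads drawn from transcript space so the expected number of
# junction-spanning reads has a closed form. Count-level generators for the
# same design are provided for statistical calibration at scale.

#' Simulation configuration
#'
#' Defaults emulate the study design this package targets: ten individuals
#' with matched tumor/normal samples, 36-base reads, overdispersed
#' (negative binomial) per-gene counts with individual-level random effects
#' shared within a matched pair, a subset of genes with a planted isoform
#' switch (linear fold change `splicing_fc` on the minor isoform's exclusive
#' junctions) and a subset with a pure gene-expression change.
#'
#' @param seed integer seed; every generator call is deterministic given it.
#' @param n_genes number of genes.
#' @param exons_per_gene integer range (min, max) of exons per gene.
#' @param exon_length,intron_length base-pair ranges.
#' @param isoforms_per_gene isoforms per gene (first is the full model;
#'   additional ones cycle through skip / alt-donor / alt-acceptor).
#' @param include_retention also generate an intron-retention isoform?
#' @param n_individuals matched pairs (two samples each).
#' @param read_length read length R in bases.
#' @param reads_per_gene mean sequenced reads per gene per sample.
#' @param dispersion negative binomial size parameter (inter-individual
#'   biological noise; Poisson is the `dispersion -> Inf` limit).
#' @param indiv_sd SD (log2 scale) of the individual random effect shared by
#'   a matched pair.
#' @param base_error_rate per-base substitution probability.
#' @param n_splicing_genes genes given a tumor-specific isoform switch.
#' @param splicing_fc linear fold change of minor-isoform usage in tumor.
#' @param n_de_genes genes given a pure gene-expression change in tumor.
#' @param gene_fc linear fold change of expression for those genes.
#' @param minor_usage baseline (normal) usage fraction of the minor isoform
#'   in switch genes; `minor_usage * splicing_fc` must be < 1.
#' @param alt_shift range of splice-site shifts (bases) for alt-donor /
#'   alt-acceptor isoforms.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_genes = 20L, exons_per_gene = c(4L, 8L),
                              exon_length = c(80L, 250L), intron_length = c(60L, 400L),
                              isoforms_per_gene = 2L, include_retention = FALSE,
                              n_individuals = 10L, read_length = 36L,
                              reads_per_gene = 500, dispersion = 8,
                              indiv_sd = 0.25, base_error_rate = 0.005,
                              n_splicing_genes = 4L, splicing_fc = 4,
                              n_de_genes = 3L, gene_fc = 4,
                              minor_usage = 0.2, alt_shift = c(9L, 15L)) {
  cfg <- as.list(environment())
  if (exon_length[1] < 2L * 28L)
    stopf("exon_length minimum must be at least twice the probe flank (56)")
  if (intron_length[1] < 4L) stopf("introns must be at least 4 bases")
  if (minor_usage * splicing_fc >= 1)
    stopf("minor_usage * splicing_fc must stay below 1")
  if (n_splicing_genes + n_de_genes > n_genes)
    stopf("more planted genes than genes")
  if (read_length < 16L) stopf("read_length too short")
  if (reads_per_gene < 0) stopf("reads_per_gene must be non-negative")
  class(cfg) <- "simulation_config"
  cfg
}

# sample() that never falls into the length-1 integer expansion trap
pick <- function(x, n = 1L, replace = FALSE) x[sample.int(length(x), n, replace = replace)]

# Apply an isoform-altering edit to a gene's full exon table (0-based
# half-open data.frame with start/end). Internal exon index chosen with rng.
make_isoform <- function(exons, type, alt_shift) {
  k <- nrow(exons)
  switch(type,
    skip = {
      i <- if (k > 2L) pick(2:(k - 1L)) else 1L
      exons[-i, , drop = FALSE]
    },
    alt_donor = {   # shift an exon's genomic end inward
      i <- pick(seq_len(k - 1L))
      d <- pick(alt_shift[1]:alt_shift[2])
      exons$end[i] <- exons$end[i] - d
      exons
    },
    alt_acceptor = {   # shift an exon's genomic start inward
      i <- pick(2:k)
      d <- pick(alt_shift[1]:alt_shift[2])
      exons$start[i] <- exons$start[i] + d
      exons
    },
    retention = {
      i <- pick(seq_len(k - 1L))
      exons$end[i] <- exons$end[i + 1L]
      exons[-(i + 1L), , drop = FALSE]
    },
    stopf("unknown isoform type: %s", type))
}

#' Simulate a toy genome and multi-isoform gene models
#'
#' Genes are laid out on one synthetic chromosome with canonical GT-AG
#' motifs planted at every intron boundary of every isoform (strand-aware).
#' Deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @return list with `genome` (DNAStringSet), `models` (`gene_models`
#'   data.frame covering all isoforms), `isoforms` (data.frame
#'   `transcript_id`, `gene_symbol`, `type`), `gene_info` (data.frame
#'   `gene_symbol`, `strand`, `splicing`, `de`).
#' @export
simulate_genome_and_models <- function(config) {
  set.seed(config$seed)
  gap <- 500L
  cursor <- gap
  rows <- list(); iso_rows <- list(); gene_rows <- list()
  iso_types <- c("skip", "alt_donor", "alt_acceptor")
  if (config$include_retention) iso_types <- c(iso_types, "retention")
  planted <- sample(config$n_genes,
                    config$n_splicing_genes + config$n_de_genes)
  splice_genes <- planted[seq_len(config$n_splicing_genes)]
  de_genes <- setdiff(planted, splice_genes)
  for (g in seq_len(config$n_genes)) {
    sym <- sprintf("G%03d", g)
    k <- pick(config$exons_per_gene[1]:config$exons_per_gene[2])
    elens <- pick(config$exon_length[1]:config$exon_length[2], k, replace = TRUE)
    ilens <- pick(config$intron_length[1]:config$intron_length[2], k - 1L, replace = TRUE)
    starts <- cursor + cumsum(c(0L, elens[-k] + ilens))
    full <- data.frame(start = starts, end = starts + elens)
    strand <- pick(c("+", "-"))
    iso_list <- list(full)
    types <- "full"
    if (config$isoforms_per_gene > 1L) {
      for (j in seq_len(config$isoforms_per_gene - 1L)) {
        ty <- iso_types[(j - 1L) %% length(iso_types) + 1L]
        iso_list[[j + 1L]] <- make_isoform(full, ty, config$alt_shift)
        types <- c(types, ty)
      }
    }
    for (j in seq_along(iso_list)) {
      tid <- sprintf("%s.T%d", sym, j)
      e <- iso_list[[j]]
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = tid, gene_symbol = sym, chrom = "chrS", strand = strand,
        start = e$start, end = e$end,
        source = if (j == 1L) "refseq" else pick(c("mrna", "est")),
        stringsAsFactors = FALSE)
      iso_rows[[length(iso_rows) + 1L]] <- data.frame(
        transcript_id = tid, gene_symbol = sym, type = types[j],
        stringsAsFactors = FALSE)
    }
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      gene_symbol = sym, strand = strand,
      splicing = g %in% splice_genes, de = g %in% de_genes,
      stringsAsFactors = FALSE)
    cursor <- full$end[nrow(full)] + gap
  }
  models <- gene_models(do.call(rbind, rows))
  chrom_len <- cursor + gap
  seq_chars <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  # plant canonical motifs at every intron boundary of every isoform
  obs <- extract_junctions(models)
  introns <- unique(obs[, c("strand", "intron_start", "intron_end")])
  for (i in seq_len(nrow(introns))) {
    s <- introns$intron_start[i]; e <- introns$intron_end[i]
    if (introns$strand[i] == "+") {
      seq_chars[(s + 1L):(s + 2L)] <- c("G", "T")
      seq_chars[(e - 1L):e] <- c("A", "G")
    } else {
      seq_chars[(s + 1L):(s + 2L)] <- c("C", "T")
      seq_chars[(e - 1L):e] <- c("A", "C")
    }
  }
  genome <- Biostrings::DNAStringSet(paste(seq_chars, collapse = ""))
  names(genome) <- "chrS"
  list(genome = genome, models = models,
       isoforms = do.call(rbind, iso_rows),
       gene_info = do.call(rbind, gene_rows))
}

# Spliced transcript sequence (transcribed orientation) and the transcript
# positions of its junctions (0-based position of the first base after each
# junction), plus genomic intron keys.
transcript_layout <- function(exons, strand, chrom_seq) {
  exons <- exons[order(exons$start), ]
  pieces <- vapply(seq_len(nrow(exons)), function(i)
    as.character(Biostrings::subseq(chrom_seq, exons$start[i] + 1L, exons$end[i])),
    character(1))
  seq_plus <- paste(pieces, collapse = "")
  widths <- exons$end - exons$start
  cuts <- cumsum(widths)[-nrow(exons)]          # junction positions, plus orientation
  tlen <- sum(widths)
  if (identical(strand, "-")) {
    seqs <- revcomp(seq_plus)
    cuts <- tlen - rev(cuts)
  } else seqs <- seq_plus
  keys <- if (nrow(exons) > 1L)
    paste0("chrS:", strand, ":", exons$end[-nrow(exons)], "-", exons$start[-1]) else character(0)
  if (identical(strand, "-")) keys <- rev(keys)
  list(sequence = seqs, junctions = cuts, keys = keys, length = tlen)
}

# Closed-form count of read placements fully contained in the probe window
# around a junction at transcript position x (0-based first base after the
# junction) for read length r, flank f, transcript length tl.
span_placements <- function(x, r, f, tl) {
  lo <- max(0L, x - f)
  hi <- min(tl - r, x + f - r)
  max(0L, hi - lo + 1L)
}

#' Simulate matched tumor/normal read sets with ground truth
#'
#' Reads are drawn uniformly along each selected transcript; per-gene read
#' totals are negative binomial around depth-scaled means, matched pairs
#' share an individual-level expression random effect, isoform usage is
#' condition-specific for the planted switch genes, and bases are
#' substituted at the configured error rate. The ground truth records, per
#' event and sample, the expected number of reads fully contained in the
#' event's probe window.
#'
#' @param sim output of [simulate_genome_and_models()].
#' @param config the same [simulation_config()].
#' @param flank_length probe flank F used for the expected-count geometry.
#' @return list with `reads` (named list of DNAStringSet per sample),
#'   `sample_sheet`, `truth_expected` (events x samples matrix of expected
#'   probe-window read counts keyed by junction), `truth_differential`
#'   (data.frame `key`, `design_fc`, `class` in
#'   `none`/`splicing`/`gene_expression`), `gene_design_fc` (named vector).
#' @export
simulate_reads <- function(sim, config, flank_length = 28L) {
  set.seed(config$seed + 1L)
  r <- config$read_length
  chrom_seq <- sim$genome[[1]]
  iso <- sim$isoforms
  layouts <- lapply(seq_len(nrow(iso)), function(i) {
    e <- sim$models[sim$models$transcript_id == iso$transcript_id[i], c("start", "end")]
    transcript_layout(e, sim$gene_info$strand[match(iso$gene_symbol[i], sim$gene_info$gene_symbol)],
                      chrom_seq)
  })
  names(layouts) <- iso$transcript_id

  ids <- sprintf("%02d", seq_len(config$n_individuals))
  sheet <- data.frame(
    sample_id = c(paste0("T", ids), paste0("N", ids)),
    individual_id = c(ids, ids),
    condition = rep(c("tumor", "normal"), each = config$n_individuals),
    stringsAsFactors = FALSE)

  genes <- sim$gene_info$gene_symbol
  base_expr <- stats::setNames(
    config$reads_per_gene * 2^stats::rnorm(length(genes), 0, 0.5), genes)
  indiv_eff <- matrix(stats::rnorm(length(genes) * config$n_individuals, 0, config$indiv_sd),
                      length(genes), config$n_individuals, dimnames = list(genes, ids))

  # usage fractions per gene x condition over its isoforms
  usage_for <- function(g, condition) {
    tx <- iso$transcript_id[iso$gene_symbol == g]
    n_iso <- length(tx)
    if (n_iso == 1L) return(stats::setNames(1, tx))
    minor0 <- if (sim$gene_info$splicing[match(g, genes)]) config$minor_usage else 0.3
    minor <- if (sim$gene_info$splicing[match(g, genes)] && condition == "tumor")
      minor0 * config$splicing_fc else minor0
    u <- c(1 - minor, rep(minor / (n_iso - 1L), n_iso - 1L))
    stats::setNames(u, tx)
  }

  all_keys <- sort(unique(unlist(lapply(layouts, `[[`, "keys"))))
  expected <- matrix(0, length(all_keys), nrow(sheet),
                     dimnames = list(all_keys, sheet$sample_id))
  reads_out <- vector("list", nrow(sheet))
  names(reads_out) <- sheet$sample_id
  bases <- c("A", "C", "G", "T")

  for (si in seq_len(nrow(sheet))) {
    cond <- sheet$condition[si]; ind <- sheet$individual_id[si]
    seqs_acc <- character(0)
    for (g in genes) {
      gi <- match(g, genes)
      mult <- if (sim$gene_info$de[gi] && cond == "tumor") config$gene_fc else 1
      mu <- base_expr[g] * 2^indiv_eff[g, ind] * mult
      u <- usage_for(g, cond)
      # expected probe-window counts (deterministic design mean)
      for (tx in names(u)) {
        ly <- layouts[[tx]]
        if (ly$length < r) next
        mu_tx <- mu * u[[tx]]
        for (jj in seq_along(ly$junctions)) {
          frac <- span_placements(ly$junctions[jj], r, flank_length, ly$length) /
            (ly$length - r + 1L)
          expected[ly$keys[jj], sheet$sample_id[si]] <-
            expected[ly$keys[jj], sheet$sample_id[si]] + mu_tx * frac
        }
      }
      n <- stats::rnbinom(1L, mu = mu, size = config$dispersion)
      if (n == 0L) next
      n_iso <- as.vector(stats::rmultinom(1L, n, u))
      for (ti in seq_along(u)) {
        if (n_iso[ti] == 0L) next
        ly <- layouts[[names(u)[ti]]]
        if (ly$length < r) next
        starts <- sample.int(ly$length - r + 1L, n_iso[ti], replace = TRUE)
        sq <- substring(ly$sequence, starts, starts + r - 1L)
        if (config$base_error_rate > 0) {
          n_err <- stats::rbinom(length(sq), r, config$base_error_rate)
          for (ii in which(n_err > 0L)) {
            ch <- strsplit(sq[ii], "")[[1]]
            pos <- sample.int(r, n_err[ii])
            ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(bases, b), 1L), character(1))
            sq[ii] <- paste(ch, collapse = "")
          }
        }
        flip <- stats::runif(length(sq)) < 0.5
        sq[flip] <- revcomp(sq[flip])
        seqs_acc <- c(seqs_acc, sq)
      }
    }
    rd <- Biostrings::DNAStringSet(seqs_acc)
    if (length(rd)) names(rd) <- sprintf("%s_r%06d", sheet$sample_id[si], seq_along(rd))
    reads_out[[si]] <- rd
  }

  # design-level fold change per event (individual effects and noise at 0)
  design_exp <- function(cond) {
    out <- stats::setNames(numeric(length(all_keys)), all_keys)
    for (g in genes) {
      gi <- match(g, genes)
      mult <- if (sim$gene_info$de[gi] && cond == "tumor") config$gene_fc else 1
      u <- usage_for(g, cond)
      for (tx in names(u)) {
        ly <- layouts[[tx]]
        if (ly$length < r) next
        for (jj in seq_along(ly$junctions)) {
          frac <- span_placements(ly$junctions[jj], r, flank_length, ly$length) /
            (ly$length - r + 1L)
          out[ly$keys[jj]] <- out[ly$keys[jj]] + base_expr[g] * mult * u[[tx]] * frac
        }
      }
    }
    out
  }
  et <- design_exp("tumor"); en <- design_exp("normal")
  fc <- ifelse(en > 0, et / en, NA_real_)
  key_gene <- stats::setNames(rep(NA_character_, length(all_keys)), all_keys)
  for (i in seq_len(nrow(iso))) {
    ks <- layouts[[iso$transcript_id[i]]]$keys
    key_gene[ks] <- iso$gene_symbol[i]
  }
  cls <- ifelse(sim$gene_info$de[match(key_gene, genes)], "gene_expression",
                ifelse(abs(log2(fc)) > 0.1, "splicing", "none"))
  truth_diff <- data.frame(key = all_keys, gene_symbol = unname(key_gene),
                           design_fc = unname(fc), class = unname(cls),
                           stringsAsFactors = FALSE)
  gene_fc_vec <- stats::setNames(ifelse(sim$gene_info$de, config$gene_fc, 1), genes)
  list(reads = reads_out, sample_sheet = sheet, truth_expected = expected,
       truth_differential = truth_diff, gene_design_fc = gene_fc_vec)
}

#' Write a full synthetic study to a directory
#'
#' Emits `genome.fa`, `models.bed` (BED12), per-sample FASTQ files,
#' `samples.tsv` (with `reads_path`), and truth tables
#' (`truth_expected.tsv`, `truth_differential.tsv`).
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created).
#' @return invisible list with the simulation objects and file paths.
#' @export
simulate_study <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome_and_models(config)
  rs <- simulate_reads(sim, config)
  write_genome(sim$genome, file.path(dir, "genome.fa"))
  write_gene_models_bed(sim$models, file.path(dir, "models.bed"))
  sheet <- rs$sample_sheet
  sheet$reads_path <- file.path(dir, paste0(sheet$sample_id, ".fastq"))
  for (i in seq_len(nrow(sheet)))
    write_reads_fastq(rs$reads[[sheet$sample_id[i]]], sheet$reads_path[i])
  write_tsv(sheet, file.path(dir, "samples.tsv"))
  write_tsv(data.frame(key = rownames(rs$truth_expected), rs$truth_expected,
                       check.names = FALSE),
            file.path(dir, "truth_expected.tsv"))
  write_tsv(rs$truth_differential, file.path(dir, "truth_differential.tsv"))
  invisible(c(sim, rs, list(dir = dir, sample_sheet = sheet)))
}

#' Count-level event simulator for statistical calibration
#'
#' Draws per-event counts for a matched tumor/normal design directly at the
#' count layer (no reads): counts are negative binomial around a per-event
#' mean scaled by an individual random effect shared within each matched
#' pair, with a per-event linear fold change applied in tumor. Events are
#' treated as probe-length features with equal library sizes, so RPKM is a
#' fixed rescaling of counts.
#'
#' @param n_events number of events.
#' @param n_individuals matched pairs.
#' @param mean_count expected count per event per sample at fold change 1
#'   (scalar or per-event vector of baselines).
#' @param dispersion negative binomial size; inter-individual biology is
#'   carried by the shared pair effect, so this is residual within-pair
#'   (largely technical) noise, mildly overdispersed relative to Poisson.
#' @param indiv_sd SD (log2) of the shared individual effect.
#' @param linear_fc scalar or per-event vector of tumor:normal fold changes.
#' @param probe_length,library_size RPKM geometry (defaults: 56-base probes,
#'   one million mapped reads per sample).
#' @param seed optional seed.
#' @return list with `rpkm` and `counts` (events x samples matrices),
#'   `sample_sheet`, `linear_fc`.
#' @export
simulate_event_counts <- function(n_events, n_individuals = 5L, mean_count = 150,
                                  dispersion = 60, indiv_sd = 0.25,
                                  linear_fc = 1, probe_length = 56L,
                                  library_size = 1e6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  linear_fc <- rep_len(linear_fc, n_events)
  ids <- sprintf("%02d", seq_len(n_individuals))
  sheet <- data.frame(sample_id = c(paste0("T", ids), paste0("N", ids)),
                      individual_id = c(ids, ids),
                      condition = rep(c("tumor", "normal"), each = n_individuals),
                      stringsAsFactors = FALSE)
  eff <- matrix(stats::rnorm(n_events * n_individuals, 0, indiv_sd),
                n_events, n_individuals)
  mu_n <- mean_count * 2^eff
  counts <- matrix(0L, n_events, 2L * n_individuals,
                   dimnames = list(sprintf("EV%05d", seq_len(n_events)), sheet$sample_id))
  counts[, seq_len(n_individuals)] <-
    stats::rnbinom(n_events * n_individuals, mu = mu_n * linear_fc, size = dispersion)
  counts[, n_individuals + seq_len(n_individuals)] <-
    stats::rnbinom(n_events * n_individuals, mu = mu_n, size = dispersion)
  rpkm_mat <- rpkm(counts, probe_length, library_size)
  list(rpkm = rpkm_mat, counts = counts, sample_sheet = sheet,
       linear_fc = stats::setNames(linear_fc, rownames(counts)))
}

#' Count-level gene/event simulator for the confound filter
#'
#' Genes carry several junction events whose counts share the gene's
#' individual effect. Three gene classes: `none` (no change), `splicing`
#' (one event per gene changes by `event_fc` in tumor, total gene output
#' unchanged), `gene_expression` (the whole gene — and hence all its events
#' — changes by `gene_fc` in tumor).
#'
#' @param n_genes_per_class named integer vector with entries `none`,
#'   `splicing`, `gene_expression`.
#' @param events_per_gene junction events per gene.
#' @param n_individuals matched pairs.
#' @param mean_count expected count per event per sample.
#' @param dispersion,indiv_sd as in [simulate_event_counts()].
#' @param event_fc fold change of the switched event in `splicing` genes.
#' @param gene_fc fold change of `gene_expression` genes.
#' @param gene_length exonic length used for gene RPKM.
#' @param probe_length,library_size RPKM geometry.
#' @param seed optional seed.
#' @return list with `event_rpkm`, `gene_rpkm`, `event_genes` (named vector
#'   event -> gene), `sample_sheet`, `truth` (data.frame `event_id`, `gene`,
#'   `class`, `is_switched`).
#' @export
simulate_confound_study <- function(n_genes_per_class = c(none = 40L, splicing = 30L,
                                                          gene_expression = 30L),
                                    events_per_gene = 3L, n_individuals = 5L,
                                    mean_count = 150, dispersion = 60, indiv_sd = 0.25,
                                    event_fc = 4, gene_fc = 4,
                                    gene_length = 2000L, probe_length = 56L,
                                    library_size = 1e6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  classes <- rep(names(n_genes_per_class), n_genes_per_class)
  n_genes <- length(classes)
  ids <- sprintf("%02d", seq_len(n_individuals))
  sheet <- data.frame(sample_id = c(paste0("T", ids), paste0("N", ids)),
                      individual_id = c(ids, ids),
                      condition = rep(c("tumor", "normal"), each = n_individuals),
                      stringsAsFactors = FALSE)
  genes <- sprintf("G%04d", seq_len(n_genes))
  ev_ids <- as.vector(t(outer(genes, seq_len(events_per_gene),
                              function(g, e) sprintf("%s.J%d", g, e))))
  ev_gene <- rep(genes, each = events_per_gene)
  switched <- ev_gene %in% genes[classes == "splicing"] &
    rep(seq_len(events_per_gene), n_genes) == 1L
  ev_fc_t <- rep(1, length(ev_ids))
  ev_fc_t[switched] <- event_fc
  ev_fc_t[ev_gene %in% genes[classes == "gene_expression"]] <- gene_fc
  gene_mult <- stats::setNames(ifelse(classes == "gene_expression", gene_fc, 1), genes)

  eff <- matrix(stats::rnorm(n_genes * n_individuals, 0, indiv_sd),
                n_genes, n_individuals, dimnames = list(genes, ids))
  ev_counts <- matrix(0L, length(ev_ids), nrow(sheet),
                      dimnames = list(ev_ids, sheet$sample_id))
  gene_counts <- matrix(0L, n_genes, nrow(sheet),
                        dimnames = list(genes, sheet$sample_id))
  for (si in seq_len(nrow(sheet))) {
    tumor <- sheet$condition[si] == "tumor"
    mu_ev <- mean_count * 2^eff[ev_gene, sheet$individual_id[si]] *
      (if (tumor) ev_fc_t else 1)
    ev_counts[, si] <- stats::rnbinom(length(ev_ids), mu = mu_ev, size = dispersion)
    mu_g <- mean_count * events_per_gene * 2^eff[, sheet$individual_id[si]] *
      (if (tumor) gene_mult else 1)
    gene_counts[, si] <- stats::rnbinom(n_genes, mu = mu_g, size = dispersion)
  }
  list(event_rpkm = rpkm(ev_counts, probe_length, library_size),
       gene_rpkm = rpkm(gene_counts, gene_length, library_size),
       event_genes = stats::setNames(ev_gene, ev_ids),
       sample_sheet = sheet,
       truth = data.frame(event_id = ev_ids, gene = ev_gene,
                          class = rep(classes, each = events_per_gene),
                          is_switched = switched, stringsAsFactors = FALSE))
}
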