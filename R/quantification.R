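# RPKM normalization, the cross-sample "mega table" of event counts, gene
# level expression and base-level coverage profiles around junctions.

#' Reads per kilobase of feature per million mapped reads
#'
#' @param count read count (vector ok).
#' @param feature_length feature length in bases (probe length for events,
#'   exon-union length for genes).
#' @param library_size total mapped reads of the sample.
#' @return `count / ((feature_length/1000) * (library_size/1e6))`.
#' @export
rpkm <- function(count, feature_length, library_size) {
  if (any(feature_length <= 0)) stopf("feature_length must be positive")
  if (any(library_size <= 0)) stopf("library_size must be positive")
  count / ((feature_length / 1000) * (library_size / 1e6))
}

#' Assemble the cross-sample mega table of event counts and RPKM
#'
#' Combines per-sample hybridization results counted against one probe
#' database into an events-by-samples matrix of unique-hit counts and RPKM.
#' All samples must have been counted against the same probe set (enforced
#' by checksum). Library size defaults to the sample's total uniquely
#' probe-mapped reads; pass explicit sizes (e.g. total sequenced reads) to
#' override.
#'
#' @param results named list of `hybridization_result`, one per sample.
#' @param probes the probe data.frame the results were counted against.
#' @param library_sizes optional named numeric of per-sample library sizes.
#' @return object of class `event_count_table`: list with `counts` and
#'   `rpkm` matrices (rows = events in database order, columns = samples),
#'   `events` (probe annotations), `samples`, `library_sizes`.
#' @export
build_mega_table <- function(results, probes, library_sizes = NULL) {
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stopf("results must be a named list (names = sample ids)")
  checksum <- content_checksum(probes$sequence)
  for (s in names(results)) {
    if (!identical(results[[s]]$probe_checksum, checksum))
      stopf("sample %s was counted against a different probe set", s)
  }
  samples <- names(results)
  counts <- vapply(results, function(r) r$counts[probes$probe_id],
                   numeric(nrow(probes)))
  counts <- matrix(as.integer(counts), nrow = nrow(probes),
                   dimnames = list(probes$event_id, samples))
  if (is.null(library_sizes)) {
    library_sizes <- vapply(results, function(r) as.numeric(r$total_unique), numeric(1))
  } else {
    if (!all(samples %in% names(library_sizes)))
      stopf("library_sizes must cover every sample")
    library_sizes <- library_sizes[samples]
  }
  if (any(library_sizes <= 0))
    stopf("sample(s) with zero mapped reads cannot be normalized: %s",
          paste(samples[library_sizes <= 0], collapse = ","))
  lens <- nchar(probes$sequence)
  rpkm_mat <- vapply(samples, function(s) rpkm(counts[, s], lens, library_sizes[[s]]),
                     numeric(nrow(probes)))
  rpkm_mat <- matrix(rpkm_mat, nrow = nrow(probes),
                     dimnames = list(probes$event_id, samples))
  structure(list(counts = counts, rpkm = rpkm_mat, events = probes,
                 samples = samples, library_sizes = library_sizes,
                 probe_checksum = checksum),
            class = "event_count_table")
}

#' @export
print.event_count_table <- function(x, ...) {
  cat(sprintf("event count table: %d events x %d samples\n",
              nrow(x$counts), length(x$samples)))
  invisible(x)
}

#' Write an event count table as TSV
#'
#' Rows are events with their annotations followed by per-sample
#' `count.<sample>` and `rpkm.<sample>` columns.
#'
#' @param tab an `event_count_table`.
#' @param path output path.
#' @export
write_mega_table <- function(tab, path) {
  df <- tab$events
  for (s in tab$samples) df[[paste0("count.", s)]] <- tab$counts[, s]
  for (s in tab$samples) df[[paste0("rpkm.", s)]] <- tab$rpkm[, s]
  write_tsv(df, path)
}

#' Total exonic length per gene (union of exons across isoforms)
#'
#' Shared exons are counted once: intervals are unioned per gene before
#' summing lengths.
#'
#' @param models a `gene_models` data.frame.
#' @return named integer vector of exon-union lengths per gene symbol.
#' @export
gene_exonic_lengths <- function(models) {
  vapply(split(models, models$gene_symbol), function(e) {
    ir <- IRanges::reduce(IRanges::IRanges(e$start + 1L, e$end))
    sum(IRanges::width(ir))
  }, integer(1))
}

#' Per-gene read counts from probe-mapped hits
#'
#' Projects unique probe hits to genes: each event's count is attributed to
#' every gene symbol annotated on it (events mapping to more than one gene
#' are rare and counted for each).
#'
#' @param tab an `event_count_table`.
#' @return genes-by-samples integer matrix.
#' @export
gene_counts_from_hits <- function(tab) {
  syms <- strsplit(tab$events$gene_symbols, ",")
  per <- lengths(syms)
  long <- data.frame(gene = unlist(syms), row = rep(seq_len(nrow(tab$counts)), per))
  genes <- sort(unique(long$gene))
  out <- matrix(0L, length(genes), length(tab$samples),
                dimnames = list(genes, tab$samples))
  for (g in genes) {
    rows <- long$row[long$gene == g]
    out[g, ] <- as.integer(colSums(tab$counts[rows, , drop = FALSE]))
  }
  out
}

#' Gene-level RPKM table
#'
#' @param gene_counts genes-by-samples count matrix (e.g. from
#'   [gene_counts_from_hits()] or a simulator's ground truth).
#' @param gene_lengths named exonic lengths from [gene_exonic_lengths()].
#' @param library_sizes named per-sample library sizes.
#' @return genes-by-samples RPKM matrix.
#' @export
gene_expression <- function(gene_counts, gene_lengths, library_sizes) {
  genes <- rownames(gene_counts)
  if (!all(genes %in% names(gene_lengths)))
    stopf("missing exonic length for gene(s): %s",
          paste(setdiff(genes, names(gene_lengths)), collapse = ","))
  if (any(gene_lengths[genes] <= 0)) stopf("gene with zero exonic length")
  samples <- colnames(gene_counts)
  if (!all(samples %in% names(library_sizes)))
    stopf("library_sizes must cover every sample")
  out <- vapply(samples, function(s) rpkm(gene_counts[, s], gene_lengths[genes],
                                          library_sizes[[s]]),
                numeric(length(genes)))
  matrix(out, nrow = length(genes), dimnames = list(genes, samples))
}

#' Base-level coverage profile around a junction
#'
#' Projects uniquely probe-mapped reads through the probe's genomic anchors
#' and reports per-base coverage over the last `window` exonic bases before
#' the donor site and the first `window` exonic bases after the acceptor
#' site, per sample. Used to corroborate a differential event by the raw
#' coverage on either side of its junction.
#'
#' @param results named list of `hybridization_result` objects run with
#'   `keep_hits = TRUE`.
#' @param probes probe data.frame.
#' @param event_id event to profile.
#' @param window flank width in bases; truncated to the probe flank length
#'   (with attribute `truncated = TRUE`) when larger.
#' @return list with matrices `upstream` and `downstream`
#'   (samples x window), columns ordered toward/away from the junction in
#'   genome-forward orientation of the probe.
#' @export
base_level_profile <- function(results, probes, event_id, window = 28L) {
  row <- match(event_id, probes$event_id)
  if (is.na(row)) stopf("unknown event_id: %s", event_id)
  l <- nchar(probes$sequence[row])
  f <- l %/% 2L
  truncated <- window > f
  if (truncated) window <- f
  pid <- probes$probe_id[row]
  samples <- names(results)
  up <- matrix(0, length(samples), window,
               dimnames = list(samples, paste0("donor-", window:1)))
  dn <- matrix(0, length(samples), window,
               dimnames = list(samples, paste0("acceptor+", seq_len(window))))
  for (s in samples) {
    h <- results[[s]]$hits
    if (is.null(h)) stopf("hybridization result for %s lacks hits; rerun with keep_hits = TRUE", s)
    h <- h[h$probe_id == pid, , drop = FALSE]
    if (!nrow(h)) next
    cov <- numeric(l)
    for (i in seq_len(nrow(h))) {
      span <- (h$offset[i] + 1L):(h$offset[i] + h$read_length[i])
      cov[span] <- cov[span] + 1
    }
    up[s, ] <- cov[(f - window + 1L):f]
    dn[s, ] <- cov[(f + 1L):(f + window)]
  }
  structure(list(upstream = up, downstream = dn), truncated = truncated)
}
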