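# End-to-end pipeline: database construction, probe design, hybridization,
# quantification, differential calling and clustering, with a provenance
# manifest. Each stage is also independently callable through the exported
# module functions; `inst/scripts/splicearray` wraps the stages for shell
# use.

#' Pipeline run configuration
#'
#' Aggregates every tunable of the pipeline. The defaults pin the reference
#' operating point: 36-base reads, 28-base flanks (56-base probes, 8-base
#' guaranteed overhang), mismatch budget 2, signature thresholds
#' p < 1e-4 (primary) and p < 1e-3 (relaxed) with linear fold change > 1.5,
#' gene-confound alpha 0.01, paired testing, pseudocount 1 RPKM,
#' correlation distance with average linkage.
#'
#' @param read_length,required_overhang probe geometry inputs.
#' @param k mismatch budget for hybridization.
#' @param canonical canonical motif pairs for the database quality filter.
#' @param min_multi_evidence evidence count waiving the motif requirement.
#' @param epsilon pseudocount (RPKM) for logs and fold changes.
#' @param paired paired statistical testing?
#' @param alpha1,alpha2 primary and relaxed raw p-value cutoffs.
#' @param fc_min minimum linear fold change.
#' @param gene_alpha gene-level differential-expression cutoff.
#' @param distance,linkage clustering choices.
#' @param include_exon_intron build intron-retention boundary events too?
#' @param seed integer seed for any stochastic step.
#' @return list of class `run_config`.
#' @export
run_config <- function(read_length = 36L, required_overhang = 8L, k = 2L,
                       canonical = CANONICAL_MOTIFS, min_multi_evidence = 2L,
                       epsilon = 1, paired = TRUE,
                       alpha1 = 1e-4, alpha2 = 1e-3, fc_min = 1.5,
                       gene_alpha = 0.01, distance = "correlation",
                       linkage = "average", include_exon_intron = FALSE,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$geometry <- probe_geometry(read_length, required_overhang)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full virtual-microarray pipeline
#'
#' Chains: junction database construction from gene models, probe design
#' with ambiguity collapsing, per-sample hybridization, the cross-sample
#' mega table, event and gene statistics, signature calling at both
#' thresholds, the gene-expression confound filter, and hierarchical
#' clustering. All stage artifacts are written under `out_dir` together
#' with a JSON manifest of input checksums, the full configuration and
#' per-stage counts.
#'
#' @param genome_path genome FASTA.
#' @param models_path gene models (BED12).
#' @param sample_sheet_path sample sheet TSV with `reads_path` column.
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @param models_format format passed to [read_gene_models()].
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(genome_path, models_path, sample_sheet_path, out_dir,
                         config = run_config(), models_format = "bed12") {
  for (p in c(genome_path, models_path, sample_sheet_path))
    if (!file.exists(p)) stopf("input not found: %s", p)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  geom <- config$geometry
  genome <- stage("read_genome", read_genome(genome_path))
  models <- stage("read_models", read_gene_models(models_path, format = models_format))
  sheet <- stage("read_samples", read_sample_sheet(sample_sheet_path))
  if (!"reads_path" %in% names(sheet)) stopf("sample sheet needs a reads_path column")

  events <- stage("build_db", build_junction_db(
    models, genome, flank_length = geom$flank_length,
    canonical = config$canonical, min_multi_evidence = config$min_multi_evidence,
    include_exon_intron = config$include_exon_intron))
  write_tsv(events, file.path(out_dir, "events.tsv"))
  write_junction_bed(events, file.path(out_dir, "events.bed"),
                     flank = geom$flank_length)

  pr <- stage("design_probes", collapse_ambiguous_probes(
    build_probes(events, genome, geom)))
  probes <- pr$probes
  write_probe_fasta(probes, file.path(out_dir, "probes.fa"))

  results <- stage("hybridize", {
    out <- list()
    for (i in seq_len(nrow(sheet))) {
      reads <- read_reads(sheet$reads_path[i])
      out[[sheet$sample_id[i]]] <- hybridize(reads, probes, k = config$k,
                                             min_read_length = 2L * geom$min_overhang)
    }
    out
  })
  per_sample <- data.frame(
    sample_id = names(results),
    total_reads = vapply(results, `[[`, numeric(1), "total_reads"),
    unique = vapply(results, `[[`, numeric(1), "total_unique"),
    multimapped = vapply(results, `[[`, numeric(1), "multimapped"),
    unmapped = vapply(results, `[[`, numeric(1), "unmapped"))
  write_tsv(per_sample, file.path(out_dir, "mapping_summary.tsv"))

  tab <- stage("mega_table", build_mega_table(results, probes))
  write_mega_table(tab, file.path(out_dir, "mega_table.tsv"))

  st <- stage("event_stats", event_stats(tab, sheet, paired = config$paired,
                                         epsilon = config$epsilon))
  write_tsv(st, file.path(out_dir, "event_stats.tsv"))
  write_tsv(volcano_data(st), file.path(out_dir, "volcano.tsv"))

  sig1 <- call_signature(st, p_max = config$alpha1, fc_min = config$fc_min)
  sig2 <- call_signature(st, p_max = config$alpha2, fc_min = config$fc_min)

  glen <- gene_exonic_lengths(models)
  gexp <- gene_expression(gene_counts_from_hits(tab), glen, tab$library_sizes)
  gst <- gene_stats(gexp, sheet, paired = config$paired, epsilon = config$epsilon)
  write_tsv(gst, file.path(out_dir, "gene_stats.tsv"))
  cf <- confound_filter(sig2, gst, gene_alpha = config$gene_alpha)
  write_tsv(cf$kept, file.path(out_dir, "signature_filtered.tsv"))
  write_tsv(sig1, file.path(out_dir, "signature_strict.tsv"))

  clustering <- NULL
  if (nrow(cf$kept) > 0L && length(tab$samples) > 1L) {
    clustering <- cluster_samples(tab$rpkm[cf$kept$event_id, , drop = FALSE],
                                  epsilon = config$epsilon,
                                  distance = config$distance,
                                  linkage = config$linkage, cut_k = 2L)
    clustering_newick(clustering, file.path(out_dir, "clustering.nwk"))
  }

  manifest <- list(
    inputs = list(genome = unname(tools::md5sum(genome_path)),
                  models = unname(tools::md5sum(models_path)),
                  sample_sheet = unname(tools::md5sum(sample_sheet_path))),
    config = config[setdiff(names(config), "geometry")],
    geometry = unclass(geom),
    counts = list(
      transcripts = length(unique(models$transcript_id)),
      observations = attr(events, "n_observations"),
      anchor_dropped = attr(events, "n_anchor_dropped"),
      motif_dropped = attr(events, "n_motif_dropped"),
      events = nrow(events),
      probes = nrow(probes),
      ambiguous_probes = sum(probes$ambiguous),
      samples = nrow(sheet),
      signature_strict = nrow(sig1),
      signature_relaxed = nrow(sig2),
      confounded_removed = cf$n_removed,
      signature_filtered = cf$n_kept))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(events = events, probes = probes, results = results,
                 mega_table = tab, stats = st, gene_stats = gst,
                 signature_strict = sig1, signature_relaxed = sig2,
                 confound = cf, clustering = clustering, manifest = manifest))
}
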