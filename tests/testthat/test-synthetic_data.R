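small_cfg <- function(...) {
  defaults <- list(n_genes = 4L, n_individuals = 2L, reads_per_gene = 150,
                   n_splicing_genes = 1L, n_de_genes = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

test_that("generation is deterministic under the seed", {
  a <- simulate_genome_and_models(small_cfg(seed = 33))
  b <- simulate_genome_and_models(small_cfg(seed = 33))
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$models, b$models)
  ra <- simulate_reads(a, small_cfg(seed = 33))
  rb <- simulate_reads(b, small_cfg(seed = 33))
  expect_identical(lapply(ra$reads, as.character), lapply(rb$reads, as.character))
  expect_identical(ra$truth_expected, rb$truth_expected)
})

test_that("a three-exon gene with a skip isoform yields the three expected junctions", {
  cfg <- simulation_config(n_genes = 1L, exons_per_gene = c(3L, 3L),
                           isoforms_per_gene = 2L, n_individuals = 2L,
                           n_splicing_genes = 0L, n_de_genes = 0L, seed = 2)
  sim <- simulate_genome_and_models(cfg)
  full <- sim$models[sim$models$transcript_id == paste0(sim$gene_info$gene_symbol[1], ".T1"), ]
  ev <- deduplicate_junctions(extract_junctions(sim$models))
  expect_equal(nrow(ev), 3L)   # J12, J23 from the full isoform, J13 from the skip
  expect_setequal(
    paste(ev$intron_start, ev$intron_end),
    c(paste(full$end[1], full$start[2]), paste(full$end[2], full$start[3]),
      paste(full$end[1], full$start[3])))
})

test_that("alternative donor/acceptor isoforms shift exactly one intron coordinate", {
  cfg <- simulation_config(n_genes = 3L, exons_per_gene = c(5L, 6L),
                           isoforms_per_gene = 4L, n_individuals = 2L,
                           n_splicing_genes = 0L, n_de_genes = 0L, seed = 8)
  sim <- simulate_genome_and_models(cfg)
  ev <- deduplicate_junctions(extract_junctions(sim$models))
  key_pairs <- split(ev[, c("intron_start", "intron_end")], ev$chrom)
  shifted_start <- outer(ev$intron_end, ev$intron_end, "==") &
    outer(ev$intron_start, ev$intron_start, "!=")
  shifted_end <- outer(ev$intron_start, ev$intron_start, "==") &
    outer(ev$intron_end, ev$intron_end, "!=")
  expect_true(any(shifted_start[upper.tri(shifted_start)]))
  expect_true(any(shifted_end[upper.tri(shifted_end)]))
})

test_that("every planted intron boundary carries canonical motifs", {
  cfg <- small_cfg(seed = 5, isoforms_per_gene = 3L)
  sim <- simulate_genome_and_models(cfg)
  ev <- annotate_motifs(deduplicate_junctions(extract_junctions(sim$models)), sim$genome)
  expect_true(all(ev$donor == "GT"))
  expect_true(all(ev$acceptor == "AG"))
})

test_that("zero depth yields empty read sets", {
  cfg <- small_cfg(seed = 4, reads_per_gene = 0)
  sim <- simulate_genome_and_models(cfg)
  rs <- simulate_reads(sim, cfg)
  expect_true(all(vapply(rs$reads, length, integer(1)) == 0L))
})

test_that("expected junction-spanning counts match a placement-counting oracle", {
  # brute-force oracle on the transcript coordinate line
  oracle <- function(x, r, f, tl) {
    sum(vapply(0:(tl - r), function(s) s >= x - f && s + r <= x + f, logical(1)))
  }
  for (x in c(30L, 100L, 500L, 870L)) {
    expect_equal(spliceArray:::span_placements(x, 36L, 28L, 900L),
                 oracle(x, 36L, 28L, 900L))
  }
  # default interior geometry: 2F - R + 1 = 21 placements
  expect_equal(spliceArray:::span_placements(400L, 36L, 28L, 900L), 21L)
})

test_that("error-free reads close the loop through the virtual array", {
  cfg <- simulation_config(n_genes = 3L, n_individuals = 2L, reads_per_gene = 400,
                           base_error_rate = 0, n_splicing_genes = 0L,
                           n_de_genes = 0L, seed = 19)
  sim <- simulate_genome_and_models(cfg)
  rs <- simulate_reads(sim, cfg)
  db <- build_junction_db(sim$models, sim$genome)
  probes <- collapse_ambiguous_probes(build_probes(db, sim$genome))$probes
  res <- hybridize(rs$reads[[1]], probes, k = 0)
  expect_gt(res$total_unique, 0L)
  expect_equal(res$total_unique + res$multimapped + res$unmapped, res$total_reads)
  # probe-window reads map with zero mismatches: unmapped reads are the
  # non-spanning majority, so unique counts should be near expectation
  key_of <- paste0(probes$chrom, ":", probes$strand, ":",
                   probes$intron_start, "-", probes$intron_end)
  exp_counts <- rs$truth_expected[key_of, 1]
  expect_gt(cor(as.numeric(res$counts), exp_counts), 0.5)
})

test_that("observed counts track ground-truth expectations at high depth", {
  cfg <- simulation_config(n_genes = 8L, n_individuals = 1L, reads_per_gene = 3000,
                           dispersion = 1e6, base_error_rate = 0,
                           n_splicing_genes = 0L, n_de_genes = 0L, seed = 27)
  sim <- simulate_genome_and_models(cfg)
  rs <- simulate_reads(sim, cfg)
  db <- build_junction_db(sim$models, sim$genome)
  probes <- collapse_ambiguous_probes(build_probes(db, sim$genome))$probes
  res <- hybridize(rs$reads[["T01"]], probes, k = 0)
  key_of <- paste0(probes$chrom, ":", probes$strand, ":",
                   probes$intron_start, "-", probes$intron_end)
  obs <- as.numeric(res$counts)
  expected <- rs$truth_expected[key_of, "T01"]
  expect_gte(cor(obs, expected), 0.95)
})

test_that("count-level generators have coherent shapes and planted truth", {
  sim <- simulate_event_counts(50, n_individuals = 4, linear_fc = c(rep(4, 10), rep(1, 40)),
                               seed = 3)
  expect_equal(dim(sim$counts), c(50L, 8L))
  expect_equal(sim$sample_sheet$condition, rep(c("tumor", "normal"), each = 4))
  # planted events are visibly shifted on average
  t_mean <- rowMeans(sim$counts[, 1:4]); n_mean <- rowMeans(sim$counts[, 5:8])
  expect_gt(median(t_mean[1:10] / n_mean[1:10]), 2)
  cs <- simulate_confound_study(n_genes_per_class = c(none = 5L, splicing = 5L,
                                                      gene_expression = 5L),
                                n_individuals = 3L, seed = 6)
  expect_equal(sum(cs$truth$is_switched), 5L)
  expect_equal(nrow(cs$event_rpkm), 45L)
  expect_equal(nrow(cs$gene_rpkm), 15L)
  expect_equal(unname(cs$event_genes[cs$truth$event_id[1]]), cs$truth$gene[1])
})

test_that("simulate_study writes a complete, loadable study directory", {
  d <- withr::local_tempdir()
  cfg <- small_cfg(seed = 14)
  simulate_study(cfg, d)
  expect_true(all(file.exists(file.path(d, c("genome.fa", "models.bed", "samples.tsv",
                                             "truth_expected.tsv", "truth_differential.tsv")))))
  sheet <- read_sample_sheet(file.path(d, "samples.tsv"))
  expect_equal(nrow(sheet), 4L)
  expect_true(all(file.exists(sheet$reads_path)))
  rd <- read_reads(sheet$reads_path[1])
  expect_true(all(Biostrings::width(rd) == 36L))
  models <- read_gene_models(file.path(d, "models.bed"), "bed12")
  expect_identical(models, simulate_genome_and_models(cfg)$models)
})
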