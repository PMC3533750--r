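test_that("rpkm follows the kilobase/million formula", {
  expect_equal(rpkm(10, 56, 1e6), 10 / (0.056 * 1))
  expect_equal(rpkm(0, 56, 1e6), 0)
  expect_equal(rpkm(5, 1000, 1e6), 5)
  expect_error(rpkm(1, 56, 0), "library_size")
  expect_error(rpkm(1, 0, 1e6), "feature_length")
})

test_that("rpkm is linear in count and inverse-linear in length and depth", {
  set.seed(3)
  for (rep in 1:20) {
    c0 <- sample(1000, 1); l <- sample(50:5000, 1); n <- sample(1e5:1e7, 1)
    expect_equal(rpkm(2 * c0, l, n) / rpkm(c0, l, n), 2)
    expect_equal(rpkm(c0, 2 * l, n) / rpkm(c0, l, n), 0.5)
    expect_equal(rpkm(c0, l, 2 * n) / rpkm(c0, l, n), 0.5)
  }
})

# small genuine hybridization fixture shared by the table tests
mega_fixture <- function() {
  set.seed(17)
  fx <- tiny_fixture()
  db <- build_junction_db(fx$models, fx$genome)
  probes <- collapse_ambiguous_probes(build_probes(db, fx$genome))$probes
  mk_reads <- function(rows, n_each) {
    rd <- unlist(lapply(rows, function(i)
      vapply(seq_len(n_each), function(j) read_from_probe(probes$sequence[i], 36L), character(1))))
    stats::setNames(rd, paste0("r", seq_along(rd)))
  }
  r1 <- hybridize(mk_reads(1:2, 5L), probes, k = 2)
  r2 <- hybridize(mk_reads(3L, 4L), probes, k = 2)
  list(probes = probes, results = list(s1 = r1, s2 = r2))
}

test_that("the mega table unions events across samples with zero fill", {
  mf <- mega_fixture()
  tab <- build_mega_table(mf$results, mf$probes)
  expect_equal(dim(tab$counts), c(3L, 2L))
  expect_equal(colSums(tab$counts),
               c(s1 = mf$results$s1$total_unique, s2 = mf$results$s2$total_unique))
  expect_true(any(tab$counts[, "s1"] == 0L) && any(tab$counts[, "s2"] == 0L))
  expect_equal(tab$rpkm, rpkm(tab$counts, 56, 1) %*% diag(1 / tab$library_sizes) * 1,
               ignore_attr = TRUE)
  # single sample: table equals that sample's counts
  tab1 <- build_mega_table(mf$results["s1"], mf$probes)
  expect_equal(unname(tab1$counts[, 1]), unname(mf$results$s1$counts))
})

test_that("counting against a different probe set is a hard error", {
  mf <- mega_fixture()
  other <- mf$probes
  other$sequence[1] <- rand_dna(56)
  expect_error(build_mega_table(mf$results, other), "different probe set")
})

test_that("explicit library sizes rescale RPKM inversely", {
  mf <- mega_fixture()
  t1 <- build_mega_table(mf$results, mf$probes, library_sizes = c(s1 = 1e6, s2 = 1e6))
  t2 <- build_mega_table(mf$results, mf$probes, library_sizes = c(s1 = 2e6, s2 = 1e6))
  expect_equal(t2$rpkm[, "s1"], t1$rpkm[, "s1"] / 2)
  expect_equal(t2$rpkm[, "s2"], t1$rpkm[, "s2"])
})

test_that("gene exonic length uses the union of exons across isoforms", {
  m <- gene_models(data.frame(
    transcript_id = c("t1", "t1", "t2", "t2"),
    gene_symbol = "G", chrom = "c", strand = "+",
    start = c(0L, 200L, 0L, 250L), end = c(100L, 300L, 100L, 400L),
    source = "mrna"))
  # interval-union oracle by hand: (0,100) once + (200,300) u (250,400) = 100 + 200
  expect_equal(unname(gene_exonic_lengths(m)), 300L)
})

test_that("gene RPKM normalizes by exon-union length and library size", {
  counts <- matrix(c(100L, 0L), 1, 2, dimnames = list("G1", c("s1", "s2")))
  out <- gene_expression(counts, c(G1 = 1000L), c(s1 = 1e6, s2 = 1e6))
  expect_equal(unname(out[1, ]), c(100, 0))
  expect_error(gene_expression(counts, c(G1 = 0L), c(s1 = 1e6, s2 = 1e6)), "zero exonic")
})

test_that("base-level profiles recover uniform coverage on both flanks", {
  set.seed(23)
  fx <- tiny_fixture()
  db <- build_junction_db(fx$models, fx$genome)
  probes <- collapse_ambiguous_probes(build_probes(db, fx$genome))$probes
  # every junction-spanning placement exactly once: perfectly uniform sampling
  reads <- vapply(0:20, function(o) read_from_probe(probes$sequence[1], 36L, offset = o),
                  character(1))
  names(reads) <- paste0("r", 0:20)
  res <- list(sA = hybridize(reads, probes, k = 0, keep_hits = TRUE))
  prof <- base_level_profile(res, probes, probes$event_id[1], window = 8L)
  # all 21 reads overlap each base within 8 of the junction by construction
  expect_true(all(prof$upstream["sA", ] >= 13))
  expect_equal(ncol(prof$upstream), 8L)
  expect_equal(dim(prof$upstream), dim(prof$downstream))
  # an event with no reads gives all-zero vectors
  prof0 <- base_level_profile(res, probes, probes$event_id[2], window = 8L)
  expect_true(all(prof0$upstream == 0) && all(prof0$downstream == 0))
  # window wider than the flank is truncated and flagged
  profT <- base_level_profile(res, probes, probes$event_id[1], window = 40L)
  expect_true(attr(profT, "truncated"))
  expect_equal(ncol(profT$upstream), 28L)
})

test_that("base-level coverage is donor/acceptor symmetric under uniform sampling", {
  set.seed(29)
  fx <- tiny_fixture()
  db <- build_junction_db(fx$models, fx$genome)
  probes <- collapse_ambiguous_probes(build_probes(db, fx$genome))$probes
  reads <- vapply(sample(0:20, 400, replace = TRUE),
                  function(o) read_from_probe(probes$sequence[1], 36L, offset = o),
                  character(1))
  names(reads) <- paste0("r", seq_along(reads))
  res <- list(sA = hybridize(reads, probes, k = 0, keep_hits = TRUE))
  prof <- base_level_profile(res, probes, probes$event_id[1], window = 8L)
  expect_lt(abs(mean(prof$upstream) - mean(prof$downstream)) /
              mean(c(prof$upstream, prof$downstream)), 0.1)
})
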