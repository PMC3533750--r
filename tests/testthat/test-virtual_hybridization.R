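test_that("exact junction-spanning substrings map with zero mismatches", {
  set.seed(5)
  probes <- data.frame(probe_id = c("P1", "P2"), sequence = rand_dna(56, 2),
                       ambiguous = FALSE, stringsAsFactors = FALSE)
  read <- substr(probes$sequence[1], 11, 46)  # offset 10
  h <- map_read(read, probes, k = 2)
  expect_equal(nrow(h), 1L)
  expect_equal(h$probe_id, "P1")
  expect_equal(h$offset, 10L)
  expect_equal(h$mismatches, 0L)
})

test_that("placements beyond the mismatch budget are rejected", {
  set.seed(6)
  probes <- data.frame(probe_id = "P1", sequence = rand_dna(56), ambiguous = FALSE)
  read <- read_from_probe(probes$sequence, 36L, n_mut = 3L, offset = 10L)
  expect_equal(nrow(map_read(read, probes, k = 2)), 0L)
  expect_gte(nrow(map_read(read, probes, k = 3)), 1L)
})

test_that("reads matching several probes return all hits; short reads error", {
  set.seed(8)
  s <- rand_dna(56)
  probes <- data.frame(probe_id = c("P1", "P2"), sequence = c(s, s), ambiguous = FALSE)
  read <- substr(s, 11, 46)
  h <- map_read(read, probes, k = 0)
  expect_equal(sort(unique(h$probe_id)), c("P1", "P2"))
  expect_error(map_read("ACGTACGTACGTACG", probes, min_read_length = 16L), "shorter")
})

test_that("seeded mapper agrees with the brute-force scanner", {
  set.seed(31)
  for (rep in 1:40) {
    k <- rep %% 4L
    base <- rand_dna(56, 3)
    probes <- data.frame(probe_id = paste0("P", 1:6),
                         sequence = c(base, vapply(base, function(b) {
                           ch <- strsplit(b, "")[[1]]
                           i <- sample(56, 2)
                           ch[i] <- sample(c("A", "C", "G", "T", "N"), 2, replace = TRUE)
                           paste(ch, collapse = "")
                         }, character(1))),
                         ambiguous = FALSE, stringsAsFactors = FALSE)
    reads <- c(read_from_probe(probes$sequence[1], 36L, 0L),
               read_from_probe(probes$sequence[2], 36L, sample(0:3, 1)),
               read_from_probe(probes$sequence[4], 36L, sample(0:2, 1)),
               rand_dna(36))
    # occasionally inject an ambiguous base into the read
    if (rep %% 5L == 0L) substr(reads[1], 5, 5) <- "N"
    for (rd in reads) {
      a <- map_read(rd, probes, k = k)
      b <- map_read_bruteforce(rd, probes, k = k)
      rownames(a) <- rownames(b) <- NULL
      expect_equal(a, b)
    }
  }
})

test_that("hit sets are monotone in the mismatch budget and strand-symmetric", {
  set.seed(13)
  probes <- data.frame(probe_id = paste0("P", 1:5), sequence = rand_dna(56, 5),
                       ambiguous = FALSE, stringsAsFactors = FALSE)
  for (rep in 1:10) {
    rd <- read_from_probe(probes$sequence[sample(5, 1)], 36L, sample(0:2, 1))
    prev <- -1L
    for (k in 0:3) {
      h <- map_read(rd, probes, k = k)
      expect_gte(nrow(h), prev)
      prev <- nrow(h)
    }
    h1 <- map_read(rd, probes, k = 2)
    h2 <- map_read(rc_oracle(rd), probes, k = 2)
    expect_equal(h1[order(h1$probe_id, h1$offset), c("probe_id", "offset", "mismatches")],
                 h2[order(h2$probe_id, h2$offset), c("probe_id", "offset", "mismatches")],
                 ignore_attr = TRUE)
    expect_equal(sort(h1$strand), sort(chartr("+-", "-+", h2$strand)))
  }
})

test_that("saturated budget hits every junction-spanning placement", {
  probes <- data.frame(probe_id = "P1", sequence = rand_dna(56), ambiguous = FALSE)
  h <- map_read_bruteforce(rand_dna(36), probes, k = 36)
  expect_equal(nrow(h), 21L * 2L)   # 21 spanning offsets, both strands
})

test_that("uniqueness is adjudicated per probe, not per placement", {
  # periodic probe: the read matches the same probe at offsets 3 and 17
  probe_seq <- strrep("ACGTTGCAGGATCC", 4)
  probes <- data.frame(probe_id = "P1", sequence = probe_seq, ambiguous = FALSE)
  read <- substr(probe_seq, 4, 39)
  h <- map_read(read, probes, k = 0)
  expect_setequal(h$offset[h$strand == "+"], c(3L, 17L))
  res <- hybridize(Biostrings::DNAStringSet(c(r1 = read)), probes, k = 0)
  expect_equal(unname(res$counts["P1"]), 1L)
  expect_equal(res$multimapped, 0L)
})

test_that("hybridize partitions reads into unique, multimapped and unmapped", {
  set.seed(21)
  probes <- data.frame(probe_id = paste0("P", 1:4),
                       sequence = c(rand_dna(56, 3), NA), ambiguous = c(FALSE, FALSE, FALSE, TRUE),
                       stringsAsFactors = FALSE)
  probes$sequence[4] <- rand_dna(56)
  reads <- c(
    u1 = read_from_probe(probes$sequence[1], 36L, 0L),
    u2 = read_from_probe(probes$sequence[2], 36L, 1L),
    amb = read_from_probe(probes$sequence[4], 36L, 0L),  # only an ambiguous probe
    none = rand_dna(36))
  res <- hybridize(Biostrings::DNAStringSet(reads), probes, k = 2)
  expect_equal(res$total_unique, 2L)
  expect_equal(res$multimapped, 1L)
  expect_equal(res$unmapped, 1L)
  expect_equal(sum(res$counts), res$total_unique)
  expect_equal(res$total_unique + res$multimapped + res$unmapped, res$total_reads)
  # a read matching two distinct probes is multimapped
  twin <- data.frame(probe_id = c("A", "B"), sequence = rep(rand_dna(56), 2),
                     ambiguous = FALSE, stringsAsFactors = FALSE)
  res2 <- hybridize(Biostrings::DNAStringSet(c(r = substr(twin$sequence[1], 11, 46))),
                    twin, k = 0)
  expect_equal(res2$multimapped, 1L)
  expect_equal(res2$total_unique, 0L)
})

test_that("read-count conservation holds for random read sets", {
  set.seed(99)
  probes <- data.frame(probe_id = paste0("P", 1:8), sequence = rand_dna(56, 8),
                       ambiguous = FALSE, stringsAsFactors = FALSE)
  reads <- c(vapply(1:30, function(i) read_from_probe(probes$sequence[sample(8, 1)], 36L,
                                                      sample(0:4, 1)), character(1)),
             rand_dna(36, 20))
  names(reads) <- paste0("r", seq_along(reads))
  res <- hybridize(reads, probes, k = 2)
  expect_equal(res$total_unique + res$multimapped + res$unmapped, length(reads))
  # empty probe set leaves everything unmapped
  res0 <- hybridize(reads[1:5], probes[0, ], k = 2)
  expect_equal(res0$unmapped, 5L)
})

test_that("reads shorter than the declared minimum are dropped with a warning", {
  probes <- data.frame(probe_id = "P1", sequence = rand_dna(56), ambiguous = FALSE)
  reads <- c(a = rand_dna(36), b = rand_dna(10))
  expect_warning(res <- hybridize(reads, probes, k = 2, min_read_length = 16L), "dropping")
  expect_equal(res$total_reads, 2L)
  expect_gte(res$unmapped, 1L)
})
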