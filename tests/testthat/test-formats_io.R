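test_that("BED12 block arithmetic yields 0-based half-open exons", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t140\ttx1|GENE1|refseq\t0\t+\t100\t140\t0\t2\t10,10\t0,30", bed)
  m <- read_gene_models(bed, format = "bed12")
  expect_equal(nrow(m), 2L)
  expect_equal(m$start, c(100L, 130L))
  expect_equal(m$end, c(110L, 140L))
  expect_equal(unique(m$transcript_id), "tx1")
  expect_equal(unique(m$gene_symbol), "GENE1")
})

test_that("GTF exon lines are grouped by transcript and converted to 0-based", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t110\t.\t+\t.\tgene_id "G"; transcript_id "T1";',
    'chr1\tsrc\texon\t131\t140\t.\t+\t.\tgene_id "G"; transcript_id "T1";'
  ), gtf)
  m <- read_gene_models(gtf, format = "gtf")
  expect_equal(nrow(m), 2L)
  expect_equal(unique(m$transcript_id), "T1")
  expect_equal(m$start, c(100L, 130L))
  expect_equal(m$end, c(110L, 140L))
})

test_that("empty model files give empty tables; invalid models are rejected with warning", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), f)
  expect_equal(nrow(read_gene_models(f, "bed12")), 0L)
  # overlapping exons -> model dropped, not a crash
  expect_warning(
    m <- gene_models(data.frame(transcript_id = "t", gene_symbol = "g", chrom = "c",
                                strand = "+", start = c(0L, 5L), end = c(10L, 20L),
                                source = "est")),
    "rejecting")
  expect_equal(nrow(m), 0L)
})

test_that("exon table dialect parses and names malformed lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tgene_symbol\tchrom\tstrand\texon_start\texon_end\tsource",
               "t1\tg1\tchr1\t+\t0\t100\trefseq",
               "t1\tg1\tchr1\t+\t200\tXX\trefseq"), f)
  expect_error(read_gene_models(f, "exon_table"), "line 3")
})

test_that("probe FASTA round-trips losslessly, including escaped values", {
  probes <- data.frame(
    probe_id = c("JP000001", "JP000002"),
    sequence = c(strrep("ACGT", 14), strrep("GGCA", 14)),
    event_id = c("SE000001", "SE000002"),
    gene_symbols = c("KIF1A", "with space=and equals"),
    intron_start = c(1000L, 2000L), intron_end = c(1100L, 2200L),
    n_evidence = c(3L, 1L), ambiguous = c(FALSE, TRUE),
    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".fa")
  expect_equal(write_probe_fasta(probes, f), 2L)
  back <- read_probe_fasta(f)
  expect_equal(back[names(probes)], probes)
  # header carries space-separated key=value pairs
  hdr <- readLines(f)[1]
  expect_match(hdr, "^>JP000001 ")
  expect_equal(length(gregexpr("=", hdr)[[1]]), 6L)
})

test_that("empty probe list writes a valid empty FASTA", {
  f <- withr::local_tempfile(fileext = ".fa")
  expect_equal(write_probe_fasta(data.frame(probe_id = character(), sequence = character()), f), 0L)
  expect_equal(nrow(read_probe_fasta(f)), 0L)
})

test_that("junction BED encodes the intron as the gap between two anchor blocks", {
  ev <- data.frame(event_id = "SE000001", chrom = "chr2", strand = "+",
                   intron_start = 1000L, intron_end = 1100L, kind = "exon_exon",
                   n_evidence = 3L, stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".bed")
  write_junction_bed(ev, f, flank = 28L)
  fields <- strsplit(readLines(f), "\t")[[1]]
  expect_equal(as.integer(fields[2]), 972L)   # chromStart = intron_start - flank
  expect_equal(as.integer(fields[3]), 1128L)  # chromEnd = intron_end + flank
  expect_equal(as.integer(fields[5]), 3L)     # score = evidence count
  expect_equal(fields[11], "28,28,")
  back <- read_junction_bed(f)
  expect_equal(back$intron_start, 1000L)
  expect_equal(back$intron_end, 1100L)
  expect_equal(back$n_evidence, 3L)
  # zero evidence violates the event invariant
  ev$n_evidence <- 0L
  expect_error(write_junction_bed(ev, f), "evidence")
})

test_that("gene models round-trip through BED12 exactly", {
  set.seed(11)
  for (rep in 1:5) {
    n_tx <- sample(1:4, 1)
    rows <- do.call(rbind, lapply(seq_len(n_tx), function(t) {
      k <- sample(1:5, 1)
      starts <- cumsum(sample(100:300, k)) + sample(1000, 1)
      data.frame(transcript_id = sprintf("tx%d", t), gene_symbol = sprintf("g%d", t),
                 chrom = "chr9", strand = sample(c("+", "-"), 1),
                 start = starts, end = starts + sample(30:80, k),
                 source = sample(c("refseq", "est"), 1), stringsAsFactors = FALSE)
    }))
    m <- gene_models(rows)
    f <- withr::local_tempfile(fileext = ".bed")
    write_gene_models_bed(m, f)
    expect_equal(read_gene_models(f, "bed12"), m)
  }
})

test_that("reads round-trip through FASTQ and qualities are ignored", {
  r <- Biostrings::DNAStringSet(c(a = "ACGTACGTAC", b = "TTTTGGGGCC"))
  f <- withr::local_tempfile(fileext = ".fastq")
  write_reads_fastq(r, f)
  back <- read_reads(f)
  expect_equal(as.character(back), as.character(r))
})

test_that("sample sheet validation enforces columns and condition levels", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(data.frame(sample_id = c("T1", "N1"), individual_id = c("1", "1"),
                       condition = c("tumor", "normal")), f)
  expect_silent(read_sample_sheet(f))
  write_tsv(data.frame(sample_id = "S", individual_id = "1", condition = "case"), f)
  expect_error(read_sample_sheet(f), "tumor")
})
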