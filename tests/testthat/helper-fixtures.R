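# Fixtures built in code: a tiny deterministic genome with known exon/intron
# structure, plus random-sequence helpers.

rand_dna <- function(width, n = 1L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = ""),
    character(1))
}

# Reverse complement written independently of the package (chartr + reverse).
rc_oracle <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# A two-gene genome with hand-placed exons and canonical motifs.
# Gene A ('+'): exons (100,200), (300,400), (500,600); introns GT..AG.
# Gene B ('-'): exons (800,900), (1000,1100); intron CT..AC on plus strand.
tiny_fixture <- function(seed = 101) {
  set.seed(seed)
  chars <- sample(c("A", "C", "G", "T"), 1400, replace = TRUE)
  for (s in c(200L, 400L)) chars[(s + 1L):(s + 2L)] <- c("G", "T")
  for (e in c(300L, 500L)) chars[(e - 1L):e] <- c("A", "G")
  chars[901:902] <- c("C", "T")
  chars[999:1000] <- c("A", "C")
  genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genome) <- "chrT"
  models <- gene_models(data.frame(
    transcript_id = c(rep("TA.1", 3), rep("TB.1", 2)),
    gene_symbol = c(rep("GA", 3), rep("GB", 2)),
    chrom = "chrT",
    strand = c(rep("+", 3), rep("-", 2)),
    start = c(100L, 300L, 500L, 800L, 1000L),
    end = c(200L, 400L, 600L, 900L, 1100L),
    source = c(rep("refseq", 3), rep("mrna", 2))))
  list(genome = genome, models = models)
}

# Random mapped-read generator: substring of a probe, optionally mutated.
read_from_probe <- function(probe, r, n_mut = 0L, offset = NULL) {
  l <- nchar(probe)
  f <- l %/% 2L
  lo <- max(0L, f - r + 1L); hi <- min(l - r, f - 1L)
  if (is.null(offset)) offset <- sample(lo:hi, 1L)
  s <- substr(probe, offset + 1L, offset + r)
  if (n_mut > 0L) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample.int(r, n_mut)
    ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                      character(1))
    s <- paste(ch, collapse = "")
  }
  s
}
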