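# Internal helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse complement of a nucleotide string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#' `N` complements to `N`.
#'
#' @param x character vector of sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Stable content fingerprint for probe sets / inputs: md5 of the serialized
# object written to a scratch file (base R has no in-memory md5).
content_checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

# Random DNA string(s); used by the simulator and tests.
random_dna <- function(n, width) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
  }, character(1))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Percent-escape for probe header annotation values: space, '=', '%' and tab.
escape_annot <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(" ", "%20", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  gsub("\t", "%09", x, fixed = TRUE)
}

unescape_annot <- function(x) {
  x <- gsub("%20", " ", x, fixed = TRUE)
  x <- gsub("%3D", "=", x, fixed = TRUE)
  x <- gsub("%09", "\t", x, fixed = TRUE)
  gsub("%25", "%", x, fixed = TRUE)
}
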