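# I/O for every standard format the pipeline touches. All genomic coordinates
# are 0-based half-open internally; GTF (1-based inclusive) and GRanges
# (1-based closed) are converted at the boundary.

#' Read a genome FASTA
#'
#' @param path path to a FASTA file of chromosome sequences.
#' @return a named [Biostrings::DNAStringSet] with uppercase sequences.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stopf("genome FASTA not found: %s", path)
  g <- Biostrings::readDNAStringSet(path)
  if (length(g) == 0L) stopf("genome FASTA is empty: %s", path)
  names(g) <- sub("\\s.*$", "", names(g))
  g <- Biostrings::DNAStringSet(toupper(as.character(g)))
  bad <- setdiff(unique(unlist(strsplit(as.character(g), ""))), DNA_ALPHABET)
  if (length(bad)) stopf("genome contains characters outside {A,C,G,T,N}: %s",
                         paste(bad, collapse = ","))
  g
}

#' Write a genome FASTA
#' @param genome named character vector or DNAStringSet of chromosomes.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet")) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Construct a gene-model table
#'
#' A gene model is a transcript given as ordered exon blocks on the genome.
#' The table has one row per exon with columns `transcript_id`, `gene_symbol`,
#' `chrom`, `strand`, `start`, `end` (0-based half-open) and `source`
#' (evidence class: `refseq`, `mrna`, `est` or `predicted`).
#'
#' @param df data.frame with the columns above.
#' @param validate drop transcripts violating the exon-block invariants
#'   (sorted, non-overlapping, end > start) with a warning?
#' @return a validated `gene_models` data.frame.
#' @export
gene_models <- function(df, validate = TRUE) {
  need <- c("transcript_id", "gene_symbol", "chrom", "strand", "start", "end", "source")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("gene model table lacks columns: %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, need]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (!all(df$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  if (validate && nrow(df)) {
    ok <- vapply(split(seq_len(nrow(df)), df$transcript_id), function(idx) {
      e <- df[idx, ]
      e <- e[order(e$start), ]
      all(e$end > e$start) &&
        (nrow(e) < 2 || all(e$start[-1] >= e$end[-nrow(e)])) &&
        length(unique(e$chrom)) == 1L && length(unique(e$strand)) == 1L
    }, logical(1))
    if (any(!ok)) {
      warnf("rejecting %d gene model(s) with unsorted/overlapping or inconsistent exons: %s",
            sum(!ok), paste(names(ok)[!ok], collapse = ", "))
      df <- df[df$transcript_id %in% names(ok)[ok], , drop = FALSE]
    }
  }
  df <- df[order(df$transcript_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_models", "data.frame")
  df
}

# Split "tx|gene|source" encoded BED names (our own writer's dialect);
# plain names become transcript_id with gene_symbol = transcript_id.
decode_bed_name <- function(nm) {
  parts <- strsplit(nm, "|", fixed = TRUE)
  t(vapply(parts, function(p) {
    c(p[1],
      if (length(p) >= 2) p[2] else p[1],
      if (length(p) >= 3) p[3] else "mrna")
  }, character(3)))
}

#' Read gene models from BED12, GTF or a plain exon table
#'
#' BED12 block arithmetic and GTF 1-based coordinates are converted to the
#' internal 0-based half-open convention. GTF transcripts are assembled from
#' their `exon` lines ordered by coordinate. The exon-table dialect is a TSV
#' with the `gene_models()` columns (already 0-based half-open).
#'
#' @param path input file.
#' @param format one of `"bed12"`, `"gtf"`, `"exon_table"`.
#' @return a `gene_models` data.frame.
#' @export
read_gene_models <- function(path, format = c("bed12", "gtf", "exon_table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("gene model file not found: %s", path)
  if (format == "bed12") {
    if (length(readLines(path, n = 1L)) == 0L) {
      return(gene_models(data.frame(transcript_id = character(), gene_symbol = character(),
                                    chrom = character(), strand = character(),
                                    start = integer(), end = integer(), source = character())))
    }
    gr <- rtracklayer::import(path, format = "bed")
    bl <- rtracklayer::blocks(gr)           # GRangesList, 1-based closed
    nm <- decode_bed_name(gr$name)
    per <- S4Vectors::elementNROWS(bl)
    flat <- unlist(bl, use.names = FALSE)
    df <- data.frame(
      transcript_id = rep(nm[, 1], per),
      gene_symbol   = rep(nm[, 2], per),
      chrom         = rep(as.character(GenomicRanges::seqnames(gr)), per),
      strand        = rep(as.character(GenomicRanges::strand(gr)), per),
      start         = GenomicRanges::start(flat) - 1L,
      end           = GenomicRanges::end(flat),
      source        = rep(nm[, 3], per),
      stringsAsFactors = FALSE
    )
    if (any(df$strand == "*")) stopf("BED12 record without strand")
    gene_models(df)
  } else if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "exon"]
    if (length(gr) == 0L) {
      return(gene_models(data.frame(transcript_id = character(), gene_symbol = character(),
                                    chrom = character(), strand = character(),
                                    start = integer(), end = integer(), source = character())))
    }
    sym <- if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id
    if (is.null(sym)) sym <- gr$transcript_id
    df <- data.frame(
      transcript_id = gr$transcript_id,
      gene_symbol   = ifelse(is.na(sym), gr$transcript_id, sym),
      chrom         = as.character(GenomicRanges::seqnames(gr)),
      strand        = as.character(GenomicRanges::strand(gr)),
      start         = GenomicRanges::start(gr) - 1L,
      end           = GenomicRanges::end(gr),
      source        = as.character(gr$source),
      stringsAsFactors = FALSE
    )
    gene_models(df)
  } else {
    df <- tryCatch(
      utils::read.delim(path, stringsAsFactors = FALSE),
      error = function(e) stopf("cannot parse exon table %s: %s", path, conditionMessage(e))
    )
    names(df)[names(df) == "exon_start"] <- "start"
    names(df)[names(df) == "exon_end"] <- "end"
    need <- c("transcript_id", "gene_symbol", "chrom", "strand", "start", "end", "source")
    miss <- setdiff(need, names(df))
    if (length(miss)) stopf("exon table %s lacks columns: %s", path, paste(miss, collapse = ", "))
    bad <- which(is.na(suppressWarnings(as.integer(df$start))) |
                 is.na(suppressWarnings(as.integer(df$end))))
    if (length(bad)) stopf("exon table %s: malformed coordinates at line %d",
                           path, bad[1] + 1L)   # +1 for the header line
    gene_models(df)
  }
}

#' Write gene models as BED12
#'
#' One BED12 feature per transcript; the name field encodes
#' `transcript_id|gene_symbol|source` so that `read_gene_models()` round-trips
#' all fields.
#'
#' @param models a `gene_models` data.frame.
#' @param path output path.
#' @return number of transcripts written, invisibly.
#' @export
write_gene_models_bed <- function(models, path) {
  if (nrow(models) == 0L) { writeLines(character(0), path); return(invisible(0L)) }
  sp <- split(models, models$transcript_id)
  lines <- vapply(sp, function(e) {
    e <- e[order(e$start), ]
    cs <- e$start[1]
    paste(e$chrom[1], cs, e$end[nrow(e)],
          paste(e$transcript_id[1], e$gene_symbol[1], e$source[1], sep = "|"),
          0, e$strand[1], cs, e$end[nrow(e)], 0, nrow(e),
          paste0(paste(e$end - e$start, collapse = ","), ","),
          paste0(paste(e$start - cs, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(length(lines))
}

#' Read short reads from FASTA or FASTQ
#'
#' Base qualities are read but discarded: mapping uses a mismatch budget only.
#'
#' @param path reads file; format auto-detected from the first character
#'   (`@` = FASTQ, `>` = FASTA) unless given.
#' @param format `"auto"`, `"fasta"` or `"fastq"`.
#' @return a named [Biostrings::DNAStringSet].
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("reads file not found: %s", path)
  if (format == "auto") {
    first <- substr(readLines(path, n = 1L), 1, 1)
    if (length(first) == 0L) return(Biostrings::DNAStringSet())
    format <- if (identical(first, "@")) "fastq" else "fasta"
  }
  r <- Biostrings::readDNAStringSet(path, format = format)
  names(r) <- sub("\\s.*$", "", names(r))
  r
}

#' Write reads as FASTQ with uniform placeholder qualities
#' @param reads named DNAStringSet or character vector.
#' @param path output path.
#' @export
write_reads_fastq <- function(reads, path) {
  if (!methods::is(reads, "DNAStringSet")) reads <- Biostrings::DNAStringSet(reads)
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  if (length(reads) == 0L) { writeLines(character(0), path); return(invisible(0L)) }
  quals <- Biostrings::PhredQuality(
    vapply(Biostrings::width(reads), function(w) paste(rep("I", w), collapse = ""), character(1)))
  qs <- Biostrings::QualityScaledDNAStringSet(reads, quals)
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(length(reads))
}

# -- probe FASTA ---------------------------------------------------------------

# Fixed probe schema: these columns are serialized as key=value header pairs
# (everything except probe_id/sequence) and re-typed on read.
PROBE_ANNOT_INT <- c("intron_start", "intron_end", "n_evidence")
PROBE_ANNOT_LGL <- c("ambiguous")

#' Write probes as annotated FASTA
#'
#' Header dialect: `>probe_id key=value key=value ...`; values percent-escape
#' whitespace, `=` and `%`. This FASTA file is the virtual microarray platform.
#'
#' @param probes probe data.frame from [build_probes()] (columns `probe_id`,
#'   `sequence`, plus annotation columns).
#' @param path output path.
#' @return number of records written, invisibly.
#' @export
write_probe_fasta <- function(probes, path) {
  con <- file(path, "w"); on.exit(close(con))
  if (nrow(probes) == 0L) return(invisible(0L))
  keys <- setdiff(names(probes), c("probe_id", "sequence"))
  for (i in seq_len(nrow(probes))) {
    kv <- vapply(keys, function(k) {
      paste0(k, "=", escape_annot(as.character(probes[[k]][i])))
    }, character(1))
    writeLines(c(paste(c(paste0(">", probes$probe_id[i]), kv), collapse = " "),
                 probes$sequence[i]), con)
  }
  invisible(nrow(probes))
}

#' Read an annotated probe FASTA
#' @param path probe FASTA written by [write_probe_fasta()].
#' @return probe data.frame; known numeric/logical annotations are re-typed.
#' @export
read_probe_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    return(data.frame(probe_id = character(), sequence = character()))
  }
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  annot <- lapply(headers, function(h) {
    toks <- strsplit(h, " +")[[1]][-1]
    toks <- toks[nzchar(toks)]
    if (!length(toks)) return(character(0))
    kv <- regmatches(toks, regexpr("=", toks, fixed = TRUE), invert = TRUE)
    vals <- unescape_annot(vapply(kv, `[`, character(1), 2))
    names(vals) <- vapply(kv, `[`, character(1), 1)
    vals
  })
  keys <- unique(unlist(lapply(annot, names)))
  df <- data.frame(probe_id = ids, sequence = as.character(seqs),
                   stringsAsFactors = FALSE, row.names = NULL)
  for (k in keys) {
    v <- vapply(annot, function(a) if (k %in% names(a)) a[[k]] else NA_character_, character(1))
    if (k %in% PROBE_ANNOT_INT) v <- as.integer(v)
    if (k %in% PROBE_ANNOT_LGL) v <- as.logical(v)
    df[[k]] <- v
  }
  df
}

# -- junction BED --------------------------------------------------------------

#' Write splice events as a junction BED file
#'
#' One BED feature per event: two blocks for the flanking exonic anchors, the
#' intron as the gap between them, and the evidence count in the score column.
#'
#' @param events splice-event data.frame (see [deduplicate_junctions()]).
#' @param path output path.
#' @param flank anchor block size in bases on each side of the intron.
#' @return number of features written, invisibly.
#' @export
write_junction_bed <- function(events, path, flank = 28L) {
  if (nrow(events) == 0L) { writeLines(character(0), path); return(invisible(0L)) }
  if (any(events$n_evidence < 1L)) stopf("splice events must have evidence count >= 1")
  cs <- events$intron_start - flank
  ce <- events$intron_end + flank
  if (any(cs < 0L)) stopf("anchor block extends past chromosome start")
  lines <- paste(events$chrom, cs, ce, events$event_id, events$n_evidence,
                 events$strand, cs, ce, 0, 2,
                 paste0(flank, ",", flank, ","),
                 paste0(0, ",", events$intron_end - cs, ","),
                 sep = "\t")
  writeLines(lines, path)
  invisible(length(lines))
}

#' Read a junction BED file back to intron coordinates
#'
#' Inverse of [write_junction_bed()]: the intron interval is recovered from
#' the gap between the two anchor blocks.
#'
#' @param path junction BED path.
#' @return data.frame with `event_id`, `chrom`, `strand`, `intron_start`,
#'   `intron_end`, `n_evidence` (0-based half-open intron coordinates).
#' @export
read_junction_bed <- function(path) {
  if (length(readLines(path, n = 1L)) == 0L) {
    return(data.frame(event_id = character(), chrom = character(), strand = character(),
                      intron_start = integer(), intron_end = integer(), n_evidence = integer()))
  }
  gr <- rtracklayer::import(path, format = "bed")
  bl <- rtracklayer::blocks(gr)
  if (any(S4Vectors::elementNROWS(bl) != 2L)) stopf("junction BED must have exactly 2 blocks per feature")
  b1 <- unlist(bl)[c(TRUE, FALSE)]
  b2 <- unlist(bl)[c(FALSE, TRUE)]
  data.frame(
    event_id     = gr$name,
    chrom        = as.character(GenomicRanges::seqnames(gr)),
    strand       = as.character(GenomicRanges::strand(gr)),
    intron_start = GenomicRanges::end(b1),          # 1-based closed end == 0-based open start of gap
    intron_end   = GenomicRanges::start(b2) - 1L,
    n_evidence   = as.integer(gr$score),
    stringsAsFactors = FALSE
  )
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `individual_id`, `condition`
#' (`tumor`/`normal`) and optionally `reads_path`, pairing condition and
#' control samples per individual.
#'
#' @param path sample sheet TSV.
#' @return validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "individual_id", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("sample sheet lacks columns: %s", paste(miss, collapse = ", "))
  if (!all(df$condition %in% c("tumor", "normal")))
    stopf("sample sheet condition must be 'tumor' or 'normal'")
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample_id in sample sheet")
  df
}

#' Write a tab-delimited table
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-delimited table
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)
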