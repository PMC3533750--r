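# Turn splice events into fixed-length junction-spanning probes. A probe of
# length 2F (default 56) takes F bases from each exon flanking the intron; a
# fully-contained read of length R then overlaps each adjoining exon by at
# least R - F bases (8 for the default 36-mer geometry).

#' Solve the probe geometry for a read length and required overhang
#'
#' The flank length F is chosen as `read_length - required_overhang` so that
#' any read of length R fully contained in a 2F probe crosses the junction by
#' at least `required_overhang` bases on each side — even reads starting at
#' probe position one or ending at the last probe position.
#'
#' @param read_length read length R in bases.
#' @param required_overhang minimum guaranteed overlap into the adjoining
#'   exon, in bases.
#' @return object of class `probe_geometry`: list with `read_length`,
#'   `flank_length`, `probe_length`, `min_overhang`.
#' @examples
#' probe_geometry(36, 8)   # F = 28, probe length 56
#' @export
probe_geometry <- function(read_length = 36L, required_overhang = 8L) {
  read_length <- as.integer(read_length)
  required_overhang <- as.integer(required_overhang)
  if (required_overhang < 1L || required_overhang >= read_length)
    stopf("required overhang must satisfy 1 <= overhang < read length (got %d vs %d)",
          required_overhang, read_length)
  f <- read_length - required_overhang
  structure(list(read_length = read_length, flank_length = f,
                 probe_length = 2L * f, min_overhang = required_overhang),
            class = "probe_geometry")
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf("probe geometry: read %d nt, flank %d nt, probe %d nt, min overhang %d nt\n",
              x$read_length, x$flank_length, x$probe_length, x$min_overhang))
  invisible(x)
}

#' Build junction-spanning probe sequences for splice events
#'
#' Probe = last F genomic bases of the upstream exon followed by the first F
#' bases of the downstream exon, reported in transcribed orientation (minus
#' strand probes are the reverse complement of the plus-strand
#' concatenation). Events whose recorded anchors cannot hold a full flank are
#' an error — they should have been removed by [filter_anchors()].
#'
#' @param events motif-annotated splice events.
#' @param genome named DNAStringSet.
#' @param geometry a [probe_geometry()].
#' @param id_prefix prefix for serial probe ids.
#' @return probe data.frame: `probe_id`, `sequence`, `event_id`, `chrom`,
#'   `strand`, `intron_start`, `intron_end`, `donor`, `acceptor`,
#'   `gene_symbols`, `n_evidence`, `evidence`, `sources`, `ambiguous`.
#' @export
build_probes <- function(events, genome, geometry = probe_geometry(),
                         id_prefix = "JP") {
  f <- geometry$flank_length
  if (nrow(events) == 0L) {
    return(data.frame(probe_id = character(), sequence = character(),
                      event_id = character(), chrom = character(), strand = character(),
                      intron_start = integer(), intron_end = integer(),
                      donor = character(), acceptor = character(),
                      gene_symbols = character(), n_evidence = integer(),
                      evidence = character(), sources = character(),
                      ambiguous = logical(), stringsAsFactors = FALSE))
  }
  if (any(events$max_up_anchor < f | events$max_down_anchor < f))
    stopf("event anchor shorter than flank length %d; run filter_anchors() first", f)
  lens <- Biostrings::width(genome)[match(events$chrom, names(genome))]
  if (any(events$intron_start - f < 0L) || any(events$intron_end + f > lens))
    stopf("probe flank extends past chromosome bounds")
  seqs <- vapply(seq_len(nrow(events)), function(i) {
    chrom <- genome[[events$chrom[i]]]
    up <- as.character(Biostrings::subseq(chrom, start = events$intron_start[i] - f + 1L, width = f))
    dn <- as.character(Biostrings::subseq(chrom, start = events$intron_end[i] + 1L, width = f))
    s <- paste0(up, dn)
    if (events$strand[i] == "-") revcomp(s) else s
  }, character(1))
  data.frame(
    probe_id = sprintf("%s%06d", id_prefix, seq_len(nrow(events))),
    sequence = seqs,
    event_id = events$event_id, chrom = events$chrom, strand = events$strand,
    intron_start = events$intron_start, intron_end = events$intron_end,
    donor = events$donor, acceptor = events$acceptor,
    gene_symbols = events$gene_symbols, n_evidence = events$n_evidence,
    evidence = events$evidence, sources = events$sources,
    ambiguous = FALSE, stringsAsFactors = FALSE)
}

#' Collapse probes with identical sequences
#'
#' Distinct events can yield identical probe sequences (e.g. recent segmental
#' duplications). One representative is retained per sequence with merged
#' annotations and `ambiguous = TRUE`; reads hitting an ambiguous probe are
#' never counted as uniquely mapped.
#'
#' @param probes probe data.frame from [build_probes()].
#' @return list with `probes` (collapsed) and `report` (data.frame of
#'   collapsed groups: `sequence`, `n`, `probe_ids`, `event_ids`).
#' @export
collapse_ambiguous_probes <- function(probes) {
  if (nrow(probes) == 0L)
    return(list(probes = probes,
                report = data.frame(sequence = character(), n = integer(),
                                    probe_ids = character(), event_ids = character())))
  sp <- split(seq_len(nrow(probes)), probes$sequence)
  dup <- sp[vapply(sp, length, integer(1)) > 1L]
  report <- data.frame(
    sequence = names(dup),
    n = vapply(dup, length, integer(1)),
    probe_ids = vapply(dup, function(i) paste(probes$probe_id[i], collapse = ","), character(1)),
    event_ids = vapply(dup, function(i) paste(probes$event_id[i], collapse = ","), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  keep_idx <- sort(vapply(sp, `[`, integer(1), 1L))
  out <- probes[keep_idx, , drop = FALSE]
  merged <- out$sequence %in% names(dup)
  if (any(merged)) {
    out$ambiguous[merged] <- TRUE
    joined <- function(col) vapply(sp[out$sequence[merged]], function(i)
      paste(sort(unique(unlist(strsplit(probes[[col]][i], ",")))), collapse = ","), character(1))
    out$event_ids_merged <- NA_character_
    out$event_ids_merged[merged] <- vapply(sp[out$sequence[merged]], function(i)
      paste(probes$event_id[i], collapse = ","), character(1))
    out$gene_symbols[merged] <- joined("gene_symbols")
    out$evidence[merged] <- joined("evidence")
    out$sources[merged] <- joined("sources")
  }
  rownames(out) <- NULL
  list(probes = out, report = report)
}
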