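# Construction of the non-redundant, quality-filtered, annotated splice-event
# database from gene models. A splice event is a unique intron keyed by
# (chrom, strand, intron_start, intron_end, kind).

#' Default canonical splice-site motif pairs
#'
#' The major GT-AG spliceosomal motif plus the minor GC-AG and AT-AC classes,
#' given in transcribed orientation as "donor-acceptor".
#' @export
CANONICAL_MOTIFS <- c("GT-AG", "GC-AG", "AT-AC")

#' Extract raw junction observations from gene models
#'
#' Emits one exon-exon observation per adjacent exon pair per transcript
#' (k exons give k-1 observations); optionally also exon-intron boundary
#' observations for intron retention. Each observation carries its intron
#' interval, source accession and the lengths of the flanking exonic anchors
#' (used later by the alignment-quality filter).
#'
#' @param models a `gene_models` data.frame.
#' @param include_exon_intron also emit exon-intron boundary observations,
#'   keyed by the intron interval with `kind = "exon_intron"`? Default off.
#' @return data.frame of observations, one row each, with columns
#'   `transcript_id`, `gene_symbol`, `chrom`, `strand`, `intron_start`,
#'   `intron_end`, `kind`, `source`, `up_anchor`, `down_anchor`.
#' @export
extract_junctions <- function(models, include_exon_intron = FALSE) {
  empty <- data.frame(transcript_id = character(), gene_symbol = character(),
                      chrom = character(), strand = character(),
                      intron_start = integer(), intron_end = integer(),
                      kind = character(), source = character(),
                      up_anchor = integer(), down_anchor = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(models) == 0L) return(empty)
  obs <- lapply(split(models, models$transcript_id), function(e) {
    e <- e[order(e$start), ]
    k <- nrow(e)
    if (k < 2L) return(NULL)
    ee <- data.frame(
      transcript_id = e$transcript_id[1], gene_symbol = e$gene_symbol[1],
      chrom = e$chrom[1], strand = e$strand[1],
      intron_start = e$end[-k], intron_end = e$start[-1],
      kind = "exon_exon", source = e$source[1],
      up_anchor = (e$end - e$start)[-k], down_anchor = (e$end - e$start)[-1],
      stringsAsFactors = FALSE)
    if (!include_exon_intron) return(ee)
    # boundary observations: same intron interval, kind marks retention probes
    ei <- ee; ei$kind <- "exon_intron"
    rbind(ee, ei)
  })
  out <- do.call(rbind, c(obs, list(empty)))
  rownames(out) <- NULL
  out
}

#' Drop observations whose exonic anchors cannot hold a full probe flank
#'
#' The alignment-quality filter: observations whose flanking exon on either
#' side is shorter than the probe flank length cannot yield a junction probe
#' and are removed (misalignment artifacts in real data typically produce
#' such truncated anchors).
#'
#' @param observations output of [extract_junctions()].
#' @param flank_length minimum anchor exon length in bases (probe flank F).
#' @return filtered observations; attribute `n_dropped` records removals.
#' @export
filter_anchors <- function(observations, flank_length = 28L) {
  keep <- observations$up_anchor >= flank_length & observations$down_anchor >= flank_length
  out <- observations[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Collapse junction observations to a non-redundant splice-event set
#'
#' Uniqueness is defined by the intron start and end coordinates (plus
#' chromosome, strand and kind). Evidence accessions, gene symbols and source
#' classes are merged across observations; event ids are assigned serially
#' after sorting by (chrom, intron_start, intron_end, strand, kind), so the
#' result is independent of input order.
#'
#' @param observations output of [extract_junctions()] / [filter_anchors()].
#' @param id_prefix prefix for serial event ids.
#' @return splice-event data.frame with columns `event_id`, `chrom`, `strand`,
#'   `intron_start`, `intron_end`, `kind`, `n_evidence`, `max_up_anchor`,
#'   `max_down_anchor` and comma-joined `evidence`, `gene_symbols`, `sources`.
#' @export
deduplicate_junctions <- function(observations, id_prefix = "SE") {
  empty <- data.frame(event_id = character(), chrom = character(), strand = character(),
                      intron_start = integer(), intron_end = integer(), kind = character(),
                      donor = character(), acceptor = character(),
                      n_evidence = integer(), evidence = character(),
                      gene_symbols = character(), sources = character(),
                      max_up_anchor = integer(), max_down_anchor = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(observations) == 0L) return(empty)
  key <- paste(observations$chrom, observations$strand,
               observations$intron_start, observations$intron_end,
               observations$kind, sep = "\r")
  sp <- split(seq_len(nrow(observations)), key)
  ev <- do.call(rbind, lapply(sp, function(idx) {
    o <- observations[idx, ]
    data.frame(
      chrom = o$chrom[1], strand = o$strand[1],
      intron_start = o$intron_start[1], intron_end = o$intron_end[1],
      kind = o$kind[1], donor = NA_character_, acceptor = NA_character_,
      n_evidence = length(unique(o$transcript_id)),
      evidence = paste(sort(unique(o$transcript_id)), collapse = ","),
      gene_symbols = paste(sort(unique(o$gene_symbol)), collapse = ","),
      sources = paste(sort(unique(o$source)), collapse = ","),
      max_up_anchor = max(o$up_anchor), max_down_anchor = max(o$down_anchor),
      stringsAsFactors = FALSE)
  }))
  ev <- ev[order(ev$chrom, ev$intron_start, ev$intron_end, ev$strand, ev$kind), , drop = FALSE]
  ev <- cbind(event_id = sprintf("%s%06d", id_prefix, seq_len(nrow(ev))), ev,
              stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  ev
}

#' Annotate donor/acceptor dinucleotide motifs from the genome
#'
#' Motifs are reported in transcribed orientation: on '+' the donor is the
#' first two intronic bases and the acceptor the last two; on '-' both are
#' taken from the reverse complement, so a plus-strand `CT..AC` intron reads
#' `GT..AG`. Introns shorter than 4 bases cannot carry both motifs and are
#' dropped with a warning.
#'
#' @param events splice-event data.frame.
#' @param genome named DNAStringSet from [read_genome()].
#' @return events with `donor` and `acceptor` filled.
#' @export
annotate_motifs <- function(events, genome) {
  if (nrow(events) == 0L) return(events)
  short <- (events$intron_end - events$intron_start) < 4L
  if (any(short)) {
    warnf("dropping %d event(s) with intron < 4 bases (no room for motifs)", sum(short))
    events <- events[!short, , drop = FALSE]
  }
  if (nrow(events) == 0L) return(events)
  bad_chrom <- setdiff(unique(events$chrom), names(genome))
  if (length(bad_chrom)) stopf("chromosome(s) not in genome: %s", paste(bad_chrom, collapse = ","))
  lens <- Biostrings::width(genome)[match(events$chrom, names(genome))]
  if (any(events$intron_end > lens) || any(events$intron_start < 0L))
    stopf("intron interval outside chromosome bounds")
  five <- vapply(seq_len(nrow(events)), function(i) {
    as.character(Biostrings::subseq(genome[[events$chrom[i]]],
                                    start = events$intron_start[i] + 1L, width = 2L))
  }, character(1))
  three <- vapply(seq_len(nrow(events)), function(i) {
    as.character(Biostrings::subseq(genome[[events$chrom[i]]],
                                    start = events$intron_end[i] - 1L, width = 2L))
  }, character(1))
  minus <- events$strand == "-"
  events$donor <- ifelse(minus, revcomp(three), five)
  events$acceptor <- ifelse(minus, revcomp(five), three)
  rownames(events) <- NULL
  events
}

#' Motif/evidence quality filter
#'
#' Keeps an event iff its donor-acceptor pair is canonical OR it is supported
#' by multiple independent sequences — multi-evidence events are kept
#' regardless of motif.
#'
#' @param events motif-annotated splice events.
#' @param canonical character vector of allowed "donor-acceptor" pairs.
#' @param min_multi_evidence evidence count at which the motif requirement is
#'   waived.
#' @return filtered events; attribute `n_dropped` records removals.
#' @export
quality_filter <- function(events, canonical = CANONICAL_MOTIFS, min_multi_evidence = 2L) {
  if (nrow(events) == 0L) return(events)
  if (anyNA(events$donor)) stopf("events must be motif-annotated before quality_filter()")
  pair <- paste0(events$donor, "-", events$acceptor)
  keep <- pair %in% canonical | events$n_evidence >= min_multi_evidence
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Build the splice-event database from gene models in one call
#'
#' Chains [extract_junctions()], the anchor (alignment-quality) filter,
#' [deduplicate_junctions()], [annotate_motifs()] and [quality_filter()].
#'
#' @inheritParams extract_junctions
#' @inheritParams annotate_motifs
#' @inheritParams quality_filter
#' @param flank_length probe flank F in bases; anchors shorter than this are
#'   dropped before deduplication.
#' @return the filtered, annotated splice-event data.frame; attributes
#'   `n_observations`, `n_anchor_dropped`, `n_motif_dropped` carry stage
#'   counts.
#' @export
build_junction_db <- function(models, genome, flank_length = 28L,
                              canonical = CANONICAL_MOTIFS, min_multi_evidence = 2L,
                              include_exon_intron = FALSE) {
  obs <- extract_junctions(models, include_exon_intron = include_exon_intron)
  filt <- filter_anchors(obs, flank_length = flank_length)
  ev <- deduplicate_junctions(filt)
  ev <- annotate_motifs(ev, genome)
  out <- quality_filter(ev, canonical = canonical, min_multi_evidence = min_multi_evidence)
  attr(out, "n_observations") <- nrow(obs)
  attr(out, "n_anchor_dropped") <- attr(filt, "n_dropped")
  attr(out, "n_motif_dropped") <- attr(out, "n_dropped")
  out
}
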