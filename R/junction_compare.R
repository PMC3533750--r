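# Normalize junction calls from any source to intron-coordinate keys and
# compute cross-sample / cross-method intersections.

#' Construct a junction set
#'
#' A labelled set of junction keys `(chrom, strand, intron_start,
#' intron_end)` in 0-based half-open coordinates.
#'
#' @param label sample or method name.
#' @param chrom,strand,intron_start,intron_end parallel vectors.
#' @return object of class `junction_set`: list with `label` and unique
#'   `keys` (character `chrom:strand:start-end`).
#' @export
junction_set <- function(label, chrom, strand, intron_start, intron_end) {
  if (any(intron_end <= intron_start)) stopf("intron_end must exceed intron_start")
  keys <- unique(paste0(chrom, ":", strand, ":", intron_start, "-", intron_end))
  structure(list(label = label, keys = keys), class = "junction_set")
}

#' Junction set from a splice-event table
#' @param events splice-event data.frame (see [deduplicate_junctions()]).
#' @param label set label.
#' @return a `junction_set`.
#' @export
events_to_junction_set <- function(events, label = "db") {
  junction_set(label, events$chrom, events$strand,
               events$intron_start, events$intron_end)
}

#' Normalize external junction calls to intron-coordinate keys
#'
#' Converts junction records from another caller to this package's internal
#' convention: `block_coords` records (two exonic anchor blocks with the
#' intron as the gap, BED12-style) are collapsed to intron intervals;
#' `one_inclusive` coordinates are shifted to 0-based half-open. Records
#' whose blocks imply a non-positive intron are dropped and counted.
#'
#' @param path junction BED path.
#' @param convention `"zero_half_open"` (BED) or `"one_inclusive"`.
#' @param anchor_style `"block_coords"` (anchors + gap) or `"intron_coords"`
#'   (the feature interval IS the intron).
#' @param label set label.
#' @return a `junction_set`; attribute `n_dropped` counts invalid records.
#' @export
normalize_external_junctions <- function(path, convention = c("zero_half_open", "one_inclusive"),
                                         anchor_style = c("block_coords", "intron_coords"),
                                         label = basename(path)) {
  convention <- match.arg(convention)
  anchor_style <- match.arg(anchor_style)
  if (length(readLines(path, n = 1L)) == 0L) {
    out <- structure(list(label = label, keys = character(0)), class = "junction_set")
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  gr <- rtracklayer::import(path, format = "bed")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  if (anchor_style == "block_coords") {
    bl <- rtracklayer::blocks(gr)
    if (any(S4Vectors::elementNROWS(bl) != 2L))
      stopf("block_coords records must have exactly 2 blocks")
    b1 <- unlist(bl)[c(TRUE, FALSE)]; b2 <- unlist(bl)[c(FALSE, TRUE)]
    s <- GenomicRanges::end(b1)        # 0-based intron start
    e <- GenomicRanges::start(b2) - 1L # 0-based half-open intron end
  } else {
    s <- GenomicRanges::start(gr) - 1L  # back to the file's start column
    e <- GenomicRanges::end(gr)
    if (convention == "one_inclusive") {
      # file start column was 1-based inclusive, not BED 0-based
      s <- s - 1L
    }
  }
  keep <- e > s
  out <- junction_set(label, chrom[keep], strand[keep], s[keep], e[keep])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Intersection of junction sets
#' @param sets list of `junction_set` objects (at least one).
#' @return character vector of keys common to all sets.
#' @export
intersect_junctions <- function(sets) {
  if (!length(sets)) stopf("need at least one junction set")
  Reduce(intersect, lapply(sets, `[[`, "keys"))
}

#' Cumulative intersection curve over an ordered list of junction sets
#'
#' Sizes of the running intersections as sets are added one by one:
#' `|S1|, |S1 ∩ S2|, ..., |S1 ∩ ... ∩ Sn|`; monotone non-increasing.
#'
#' @param sets ordered list of `junction_set` objects.
#' @return integer vector of running intersection sizes.
#' @export
cumulative_intersection_curve <- function(sets) {
  if (!length(sets)) stopf("need at least one junction set")
  acc <- sets[[1]]$keys
  out <- integer(length(sets))
  out[1] <- length(acc)
  for (i in seq_along(sets)[-1]) {
    acc <- intersect(acc, sets[[i]]$keys)
    out[i] <- length(acc)
  }
  out
}

#' Pairwise overlap matrix of junction sets
#' @param sets list of `junction_set` objects.
#' @return integer matrix of pairwise intersection sizes, labelled.
#' @export
junction_overlap_matrix <- function(sets) {
  labs <- vapply(sets, `[[`, character(1), "label")
  n <- length(sets)
  m <- matrix(0L, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n)) for (j in seq_len(n))
    m[i, j] <- length(intersect(sets[[i]]$keys, sets[[j]]$keys))
  m
}
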