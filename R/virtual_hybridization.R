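# In-silico hybridization: place each read (and its reverse complement) on
# every probe at every junction-spanning offset under a Hamming mismatch
# budget, no indels. Production path is seed-and-verify (pigeonhole: a hit
# with <= k mismatches over k+1 disjoint read segments contains an exact
# segment); the brute-force scanner is an independent reference used in
# validation.

# Junction-spanning offsets (0-based) for a read of length r on a probe of
# length l with the junction after position l/2.
spanning_offsets <- function(r, l) {
  f <- l %/% 2L
  lo <- max(0L, f - r + 1L)
  hi <- min(l - r, f - 1L)
  if (hi < lo) integer(0) else lo:hi
}

# Hamming mismatches between read chars and probe chars at offset (0-based);
# N mismatches everything, including N.
mm_at <- function(rchars, pchars, off) {
  pc <- pchars[(off + 1L):(off + length(rchars))]
  sum(rchars != pc | rchars == "N" | pc == "N")
}

# Candidate placements for a batch of equal-length reads against the probe
# set, both strands, verified to <= k mismatches. Returns a data.frame
# (read, probe, offset, strand, mismatches). `reads` is a character vector.
scan_candidates <- function(reads, probe_seqs, k) {
  r <- unique(nchar(reads))
  stopifnot(length(r) == 1L)
  n_probes <- length(probe_seqs)
  pchars <- strsplit(probe_seqs, "")
  offs <- lapply(nchar(probe_seqs), spanning_offsets, r = r)
  empty <- data.frame(read = integer(), probe = integer(), offset = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  if (n_probes == 0L || !length(reads)) return(empty)

  seg <- r %/% (k + 1L)
  if (seg < 6L) {
    # mismatch budget too dense for useful seeds: verify every placement
    out <- vector("list", length(reads) * 2L)
    z <- 0L
    rc_reads <- revcomp(reads)
    for (i in seq_along(reads)) {
      for (str in c("+", "-")) {
        rchars <- strsplit(if (str == "+") reads[i] else rc_reads[i], "")[[1]]
        for (p in seq_len(n_probes)) {
          for (o in offs[[p]]) {
            mm <- mm_at(rchars, pchars[[p]], o)
            if (mm <= k) {
              z <- z + 1L
              out[[z]] <- data.frame(read = i, probe = p, offset = o, strand = str,
                                     mismatches = mm, stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
    return(if (z) do.call(rbind, out[seq_len(z)]) else empty)
  }

  # index: key "segment_index:probe_substring" -> placements holding it
  n_off <- vapply(offs, length, integer(1))
  probe_col <- rep(seq_len(n_probes), n_off * (k + 1L))
  off_col <- unlist(lapply(offs, function(o) rep(o, each = k + 1L)), use.names = FALSE)
  seg_col <- rep_len(0:k, length(probe_col))
  key_col <- paste0(seg_col, ":",
                    substring(probe_seqs[probe_col],
                              off_col + seg_col * seg + 1L,
                              off_col + seg_col * seg + seg))
  index <- split(seq_along(key_col), key_col)

  rc_reads <- revcomp(reads)
  query_one <- function(seqs, strand_label) {
    starts <- (0:k) * seg + 1L
    qkeys <- paste0(rep(0:k, each = length(seqs)), ":",
                    substring(rep(seqs, k + 1L), rep(starts, each = length(seqs)),
                              rep(starts + seg - 1L, each = length(seqs))))
    qread <- rep(seq_along(seqs), k + 1L)
    hit_lists <- index[qkeys]
    n_hits <- vapply(hit_lists, function(x) if (is.null(x)) 0L else length(x), integer(1))
    if (sum(n_hits) == 0L) return(empty)
    cand <- data.frame(read = rep(qread, n_hits),
                       idx = unlist(hit_lists, use.names = FALSE))
    cand <- unique(data.frame(read = cand$read,
                              probe = probe_col[cand$idx],
                              offset = off_col[cand$idx]))
    rch <- strsplit(seqs, "")
    mm <- mapply(function(rd, p, o) mm_at(rch[[rd]], pchars[[p]], o),
                 cand$read, cand$probe, cand$offset)
    keep <- mm <= k
    if (!any(keep)) return(empty)
    data.frame(read = cand$read[keep], probe = cand$probe[keep],
               offset = cand$offset[keep], strand = strand_label,
               mismatches = as.integer(mm[keep]), stringsAsFactors = FALSE)
  }
  out <- rbind(query_one(reads, "+"), query_one(rc_reads, "-"))
  out[order(out$read, out$probe, out$offset, out$strand), , drop = FALSE]
}

#' Map one read onto the probe set
#'
#' Returns every junction-spanning placement of the read (or its reverse
#' complement) on any probe with Hamming distance at most `k`; no indels.
#' `N` counts as a mismatch against every base. Placements must cross the
#' probe midpoint, so reads longer than the probe produce no hits.
#'
#' @param read a single read sequence (character).
#' @param probes probe data.frame (needs `probe_id`, `sequence`) or a
#'   character vector of probe sequences.
#' @param k mismatch budget.
#' @param min_read_length reads shorter than this are rejected with an error
#'   (use twice the geometry's minimum overhang to refuse reads that cannot
#'   establish it).
#' @return data.frame of hits: `probe_id`, `offset` (0-based start on the
#'   probe), `strand` (`+` read as given, `-` reverse complement), and
#'   `mismatches`.
#' @export
map_read <- function(read, probes, k = 2L, min_read_length = 2L) {
  stopifnot(length(read) == 1L)
  if (nchar(read) < min_read_length)
    stopf("read of length %d is shorter than the minimum %d", nchar(read), min_read_length)
  seqs <- if (is.data.frame(probes)) probes$sequence else probes
  ids <- if (is.data.frame(probes)) probes$probe_id else
    if (!is.null(names(probes))) names(probes) else as.character(seq_along(probes))
  hits <- scan_candidates(read, seqs, as.integer(k))
  data.frame(probe_id = ids[hits$probe], offset = hits$offset,
             strand = hits$strand, mismatches = hits$mismatches,
             stringsAsFactors = FALSE)
}

#' Brute-force reference mapper
#'
#' Independent sliding-window Hamming scan over every probe, every
#' junction-spanning offset, both strands — same contract as [map_read()]
#' but implemented without seeding or indexing. Intended for validation;
#' quadratic and slow.
#'
#' @inheritParams map_read
#' @return same shape as [map_read()].
#' @export
map_read_bruteforce <- function(read, probes, k = 2L) {
  seqs <- if (is.data.frame(probes)) probes$sequence else probes
  ids <- if (is.data.frame(probes)) probes$probe_id else
    if (!is.null(names(probes))) names(probes) else as.character(seq_along(probes))
  r <- nchar(read)
  codes <- list("+" = utf8ToInt(read),
                "-" = utf8ToInt(as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))))
  n_code <- utf8ToInt("N")
  rows <- list(); z <- 0L
  for (p in seq_along(seqs)) {
    pcode <- utf8ToInt(seqs[p])
    for (o in spanning_offsets(r, nchar(seqs[p]))) {
      win <- pcode[(o + 1L):(o + r)]
      for (str in c("+", "-")) {
        rc <- codes[[str]]
        mm <- sum(rc != win | rc == n_code | win == n_code)
        if (mm <= k) {
          z <- z + 1L
          rows[[z]] <- data.frame(probe_id = ids[p], offset = o, strand = str,
                                  mismatches = as.integer(mm), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!z) return(data.frame(probe_id = character(), offset = integer(),
                            strand = character(), mismatches = integer(),
                            stringsAsFactors = FALSE))
  out <- do.call(rbind, rows[seq_len(z)])
  out[order(match(out$probe_id, ids), out$offset, out$strand), , drop = FALSE]
}

#' Hybridize a read set to the probe database
#'
#' Maps every read with [map_read()] semantics and adjudicates uniqueness at
#' the probe level: a read is uniquely mapped iff it has at least one hit and
#' all its hits fall on a single non-ambiguous probe (multiple placements on
#' the same probe still count as unique). Unique reads contribute one count
#' to their probe; reads hitting several probes — or only ambiguous probes —
#' are multimapped; reads with no hit are unmapped.
#'
#' @param reads DNAStringSet or named character vector of reads.
#' @param probes collapsed probe data.frame (see
#'   [collapse_ambiguous_probes()]); an `ambiguous` column is honored if
#'   present.
#' @param k mismatch budget.
#' @param min_read_length reads shorter than this are dropped with a warning
#'   before mapping.
#' @param keep_hits retain the best placement (fewest mismatches, then
#'   smallest offset, `+` before `-`) of every uniquely mapped read in the
#'   result (needed for base-level coverage profiles)?
#' @return object of class `hybridization_result`: list with `counts` (named
#'   integer over all probe ids), `total_unique`, `multimapped`, `unmapped`,
#'   `total_reads`, `probe_checksum` and optionally `hits`.
#' @export
hybridize <- function(reads, probes, k = 2L, min_read_length = 16L, keep_hits = FALSE) {
  if (methods::is(reads, "DNAStringSet")) {
    nm <- names(reads)
    reads <- as.character(reads)
    names(reads) <- nm
  }
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  total_reads <- length(reads)
  short <- nchar(reads) < min_read_length
  if (any(short)) {
    warnf("dropping %d read(s) shorter than %d bases", sum(short), min_read_length)
    reads <- reads[!short]
  }
  counts <- stats::setNames(integer(nrow(probes)), probes$probe_id)
  ambiguous <- if ("ambiguous" %in% names(probes)) probes$ambiguous else
    rep(FALSE, nrow(probes))
  multimapped <- 0L; unmapped <- sum(short)
  hit_rows <- list()
  k <- as.integer(k)
  for (len in unique(nchar(reads))) {
    sel <- which(nchar(reads) == len)
    hits <- scan_candidates(unname(reads[sel]), probes$sequence, k)
    per_read <- split(hits, factor(hits$read, levels = seq_along(sel)))
    for (i in seq_along(sel)) {
      h <- per_read[[i]]
      if (is.null(h) || nrow(h) == 0L) { unmapped <- unmapped + 1L; next }
      ps <- unique(h$probe)
      if (length(ps) > 1L || ambiguous[ps]) { multimapped <- multimapped + 1L; next }
      counts[ps] <- counts[ps] + 1L
      if (keep_hits) {
        best <- h[order(h$mismatches, h$offset, h$strand), ][1L, ]
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          read_id = names(reads)[sel[i]], probe_id = probes$probe_id[ps],
          offset = best$offset, strand = best$strand,
          mismatches = best$mismatches, read_length = len,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- list(counts = counts, total_unique = sum(counts),
              multimapped = multimapped, unmapped = unmapped,
              total_reads = total_reads,
              probe_checksum = content_checksum(probes$sequence))
  if (keep_hits) res$hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(read_id = character(), probe_id = character(), offset = integer(),
               strand = character(), mismatches = integer(), read_length = integer(),
               stringsAsFactors = FALSE)
  class(res) <- "hybridization_result"
  res
}

#' @export
print.hybridization_result <- function(x, ...) {
  cat(sprintf("hybridization: %d reads; %d unique, %d multimapped, %d unmapped; %d probes\n",
              x$total_reads, x$total_unique, x$multimapped, x$unmapped, length(x$counts)))
  invisible(x)
}
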