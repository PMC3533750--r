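# Differential splice-event calling across matched condition/control
# samples, the gene-expression confound filter, and hierarchical clustering
# of samples on the signature.

#' Test one event for differential expression between conditions
#'
#' Two-sample location test on `log2(RPKM + epsilon)`: paired t when samples
#' are matched by individual (vectors aligned by individual), Welch's t
#' otherwise. The log2 fold change is
#' `log2((mean(condition)+epsilon) / (mean(control)+epsilon))`.
#'
#' @param rpkm_condition numeric vector of condition (e.g. tumor) RPKMs.
#' @param rpkm_control numeric vector of control RPKMs; in paired mode the
#'   same individual order as `rpkm_condition`.
#' @param paired paired t-test on within-individual differences?
#' @param epsilon pseudocount (RPKM units) stabilizing logs of zero counts.
#' @return list with `p_value`, `log2_fold_change`, `mean_condition`,
#'   `mean_control`, `testable`.
#' @export
test_event <- function(rpkm_condition, rpkm_control, paired = TRUE, epsilon = 1) {
  if (length(rpkm_condition) < 2L || length(rpkm_control) < 2L)
    stopf("need at least 2 observations per group")
  if (paired && length(rpkm_condition) != length(rpkm_control))
    stopf("paired test needs individual-aligned vectors of equal length")
  m1 <- mean(rpkm_condition); m0 <- mean(rpkm_control)
  lfc <- log2((m1 + epsilon) / (m0 + epsilon))
  if (all(rpkm_condition == 0) && all(rpkm_control == 0))
    return(list(p_value = 1, log2_fold_change = 0, mean_condition = 0,
                mean_control = 0, testable = FALSE))
  x <- log2(rpkm_condition + epsilon)
  y <- log2(rpkm_control + epsilon)
  p <- tryCatch(
    stats::t.test(x, y, paired = paired, var.equal = FALSE)$p.value,
    error = function(e) {
      # degenerate variance: constant data within the test
      if (isTRUE(all.equal(mean(x), mean(y)))) 1 else .Machine$double.xmin
    })
  if (is.nan(p)) p <- 1
  list(p_value = p, log2_fold_change = lfc, mean_condition = m1,
       mean_control = m0, testable = TRUE)
}

#' Per-event differential statistics across the whole table
#'
#' Runs [test_event()] for every event in an [build_mega_table()] table,
#' using the sample sheet to split condition vs control and (in paired mode)
#' align samples by individual. Raw p-values drive the signature thresholds;
#' Benjamini-Hochberg q-values are reported alongside for reference.
#'
#' @param tab an `event_count_table`.
#' @param sample_sheet data.frame from [read_sample_sheet()].
#' @param condition condition level tested against the other level.
#' @param paired paired test (matched individuals)?
#' @param epsilon pseudocount in RPKM units.
#' @return data.frame of class `event_stats`: `event_id`, `gene_symbols`,
#'   `p_value`, `q_value`, `log2_fold_change`, `mean_rpkm_condition`,
#'   `mean_rpkm_control`, `testable`.
#' @export
event_stats <- function(tab, sample_sheet, condition = "tumor", paired = TRUE,
                        epsilon = 1) {
  stats_for_matrix(tab$rpkm, sample_sheet, condition = condition,
                   paired = paired, epsilon = epsilon,
                   gene_symbols = tab$events$gene_symbols)
}

# Shared engine for event- and gene-level testing on an RPKM matrix.
stats_for_matrix <- function(rpkm_mat, sample_sheet, condition = "tumor",
                             paired = TRUE, epsilon = 1, gene_symbols = NULL) {
  if (!all(sample_sheet$sample_id %in% colnames(rpkm_mat)))
    stopf("sample sheet lists samples absent from the table")
  cond <- sample_sheet[sample_sheet$condition == condition, ]
  ctrl <- sample_sheet[sample_sheet$condition != condition, ]
  if (paired) {
    shared <- intersect(cond$individual_id, ctrl$individual_id)
    cond <- cond[match(shared, cond$individual_id), ]
    ctrl <- ctrl[match(shared, ctrl$individual_id), ]
  }
  res <- lapply(seq_len(nrow(rpkm_mat)), function(i) {
    test_event(rpkm_mat[i, cond$sample_id], rpkm_mat[i, ctrl$sample_id],
               paired = paired, epsilon = epsilon)
  })
  out <- data.frame(
    event_id = rownames(rpkm_mat),
    gene_symbols = if (is.null(gene_symbols)) rownames(rpkm_mat) else gene_symbols,
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    log2_fold_change = vapply(res, `[[`, numeric(1), "log2_fold_change"),
    mean_rpkm_condition = vapply(res, `[[`, numeric(1), "mean_condition"),
    mean_rpkm_control = vapply(res, `[[`, numeric(1), "mean_control"),
    testable = vapply(res, `[[`, logical(1), "testable"),
    stringsAsFactors = FALSE)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  class(out) <- c("event_stats", "data.frame")
  out
}

#' Gene-level differential expression statistics
#'
#' Same machinery as [event_stats()] applied to a gene RPKM matrix from
#' [gene_expression()].
#'
#' @param gene_rpkm genes-by-samples RPKM matrix.
#' @inheritParams event_stats
#' @return `event_stats`-shaped data.frame keyed by gene symbol.
#' @export
gene_stats <- function(gene_rpkm, sample_sheet, condition = "tumor",
                       paired = TRUE, epsilon = 1) {
  stats_for_matrix(gene_rpkm, sample_sheet, condition = condition,
                   paired = paired, epsilon = epsilon)
}

#' Select the differential splice-event signature
#'
#' Events with raw p-value below `p_max` and absolute linear fold change
#' above `fc_min` (so `|log2FC| > log2(fc_min)`).
#'
#' @param stats an `event_stats` data.frame.
#' @param p_max raw p-value cutoff.
#' @param fc_min minimum fold change on the linear scale.
#' @return subset of `stats` forming the signature.
#' @export
call_signature <- function(stats, p_max = 1e-4, fc_min = 1.5) {
  sel <- stats$testable & stats$p_value < p_max &
    abs(stats$log2_fold_change) > log2(fc_min)
  out <- stats[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove signature events explained by gene-level differential expression
#'
#' A splice event whose host gene is itself differentially expressed between
#' the conditions (gene p-value below `gene_alpha` for ANY of the event's
#' genes) is attributed to overall gene expression change rather than a
#' splicing change, and removed. Events whose gene cannot be resolved in the
#' gene table are kept and flagged `gene_unknown`.
#'
#' @param signature output of [call_signature()].
#' @param gene_statistics output of [gene_stats()].
#' @param gene_alpha gene-level p-value cutoff.
#' @return list with `kept`, `removed` (both `event_stats`-shaped, with
#'   `gene_p_value` and `gene_unknown` columns) and counts `n_kept`,
#'   `n_removed`.
#' @export
confound_filter <- function(signature, gene_statistics, gene_alpha = 0.01) {
  gp <- stats::setNames(gene_statistics$p_value, gene_statistics$event_id)
  per_event <- lapply(strsplit(signature$gene_symbols, ","), function(gs) gp[gs])
  signature$gene_p_value <- vapply(per_event, function(p)
    if (all(is.na(p))) NA_real_ else min(p, na.rm = TRUE), numeric(1))
  signature$gene_unknown <- is.na(signature$gene_p_value)
  confounded <- !signature$gene_unknown & signature$gene_p_value < gene_alpha
  kept <- signature[!confounded, , drop = FALSE]
  removed <- signature[confounded, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed,
       n_kept = nrow(kept), n_removed = nrow(removed))
}

#' Hierarchically cluster samples on a signature RPKM submatrix
#'
#' Agglomerative clustering of sample profiles of `log2(RPKM + epsilon)`;
#' default correlation distance (1 - Pearson) with average linkage, the
#' standard choice for expression signatures.
#'
#' @param rpkm_mat events-by-samples RPKM matrix (signature rows only).
#' @param epsilon pseudocount in RPKM units.
#' @param distance `"correlation"` or any [stats::dist()] method.
#' @param linkage linkage method for [stats::hclust()].
#' @param cut_k optional number of clusters to cut the tree into.
#' @return object of class `sample_clustering`: list with `hclust`, `order`
#'   (leaf order), `clusters` (named assignment when `cut_k` given).
#' @export
cluster_samples <- function(rpkm_mat, epsilon = 1, distance = "correlation",
                            linkage = "average", cut_k = NULL) {
  if (ncol(rpkm_mat) < 2L) stopf("need at least 2 samples to cluster")
  m <- log2(rpkm_mat + epsilon)
  if (distance == "correlation") {
    cc <- suppressWarnings(stats::cor(m))
    cc[is.na(cc)] <- 0   # zero-variance profile: uninformative, maximal distance
    d <- stats::as.dist(1 - cc)
  } else {
    d <- stats::dist(t(m), method = distance)
  }
  if (all(d == 0)) warnf("all pairwise distances are zero; degenerate tree")
  hc <- stats::hclust(d, method = linkage)
  out <- list(hclust = hc, order = hc$labels[hc$order],
              clusters = if (!is.null(cut_k)) stats::cutree(hc, k = cut_k))
  class(out) <- "sample_clustering"
  out
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("sample clustering of", length(x$order), "samples; leaf order:",
      paste(x$order, collapse = " "), "\n")
  invisible(x)
}

#' Newick rendering of a sample clustering
#'
#' Nested-parenthesis tree with branch lengths, via [ape::as.phylo()].
#'
#' @param clustering a `sample_clustering`.
#' @param path optional file to write to.
#' @return the newick string, invisibly when written to file.
#' @export
clustering_newick <- function(clustering, path = NULL) {
  tr <- ape::as.phylo(clustering$hclust)
  nwk <- ape::write.tree(tr)
  if (!is.null(path)) { writeLines(nwk, path); return(invisible(nwk)) }
  nwk
}

#' Purity of a clustering against known sample labels
#'
#' Fraction of samples whose cluster's majority label matches their own:
#' `sum_k max_label |cluster_k ∩ label| / n`.
#'
#' @param clusters named cluster assignment (e.g. `clusters` from
#'   [cluster_samples()] with `cut_k`).
#' @param labels named true condition labels over the same samples.
#' @return purity in (0, 1].
#' @export
cluster_purity <- function(clusters, labels) {
  labels <- labels[names(clusters)]
  sum(vapply(split(labels, clusters), function(l) max(table(l)), numeric(1))) /
    length(clusters)
}

#' Volcano-plot coordinates for an event-stats table
#'
#' @param stats `event_stats` data.frame.
#' @return data.frame `event_id`, `log2_fold_change`, `neg_log10_p`.
#' @export
volcano_data <- function(stats) {
  data.frame(event_id = stats$event_id,
             log2_fold_change = stats$log2_fold_change,
             neg_log10_p = -log10(stats$p_value),
             stringsAsFactors = FALSE)
}
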