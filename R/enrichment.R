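#' Flag query intervals overlapping a reference set
#'
#' A query interval is flagged when it shares at least one base with any
#' reference interval on the same chromosome (half-open arithmetic;
#' `min_bp` raises the required overlap width).
#'
#' @param query,reference [peak_set()] objects (or data frames with
#'   `chrom`, `start`, `end`, `id`; unsorted input is sorted with a
#'   warning).
#' @param min_bp minimum shared width in bases (default 1).
#' @return List of class `overlap_result`: `flag` (named logical per query
#'   interval), `n_query`, `n_overlapping`, `fraction`.
#' @export
overlaps <- function(query, reference, min_bp = 1) {
  query <- as_sorted_peaks(query)
  reference <- as_sorted_peaks(reference)
  flag <- setNames(rep(FALSE, nrow(query)), query$id)
  for (ch in intersect(unique(query$chrom), unique(reference$chrom))) {
    qi <- which(query$chrom == ch)
    ri <- which(reference$chrom == ch)
    q <- IRanges::IRanges(query$start[qi] + 1L, query$end[qi])
    r <- IRanges::IRanges(reference$start[ri] + 1L, reference$end[ri])
    flag[qi] <- IRanges::countOverlaps(q, r, minoverlap = min_bp) > 0
  }
  structure(list(flag = flag, n_query = nrow(query),
                 n_overlapping = sum(flag),
                 fraction = if (nrow(query)) mean(flag) else NaN),
            class = "overlap_result")
}

as_sorted_peaks <- function(x) {
  if (inherits(x, "peak_set")) return(x)
  x <- as.data.frame(x)
  if (is.null(x$id)) x$id <- paste0(x$chrom, ":", x$start, "-", x$end)
  if (is.unsorted(order(x$chrom, x$start))) {
    warning("unsorted intervals; sorting")
  }
  peak_set(x$chrom, x$start, x$end, x$id)
}

#' Fraction of a cluster's elements overlapping a reference set
#'
#' @param model a [two_stage_cluster()] model.
#' @param peaks the [peak_set()] holding the clustered elements' intervals.
#' @param reference a [peak_set()] (e.g. regions opened on pioneer-factor
#'   overexpression, or ChIP peaks).
#' @param cluster_id merged cluster id.
#' @return The overlap fraction (scalar in `[0, 1]`).
#' @export
cluster_overlap_fraction <- function(model, peaks, reference, cluster_id) {
  ids <- names(model$merged)[model$merged == cluster_id]
  if (!length(ids)) stop("cluster ", cluster_id, " is empty or unknown")
  sub <- peaks[peaks$id %in% ids, , drop = FALSE]
  class(sub) <- c("peak_set", "data.frame")
  overlaps(sub, reference)$fraction
}

#' Per-cluster hypergeometric overlap enrichment
#'
#' For each merged cluster, tests whether its elements overlap the ChIP
#' set more often than expected from the universe of all clustered
#' elements: upper-tail hypergeometric p for drawing `k` overlapping
#' elements in a sample of `n` from a universe of `N` containing `K`
#' overlapping, with Benjamini-Hochberg adjustment across clusters. The
#' fold is `(k/n) / (K/N)`.
#'
#' @param model a [two_stage_cluster()] model.
#' @param peaks [peak_set()] of the clustered elements.
#' @param chip reference [peak_set()].
#' @return Data frame of class `enrichment_result` with one row per
#'   cluster: `cluster`, `label`, `k`, `n`, `K`, `N`, `fold`, `pvalue`,
#'   `qvalue`.
#' @export
cluster_enrichment <- function(model, peaks, chip) {
  ids <- names(model$merged)
  uni <- peaks[peaks$id %in% ids, , drop = FALSE]
  class(uni) <- c("peak_set", "data.frame")
  ov <- overlaps(uni, chip)$flag
  N <- length(ids); K <- sum(ov[ids])
  rows <- lapply(seq_len(model$k_final), function(g) {
    members <- names(model$merged)[model$merged == g]
    n <- length(members); k <- sum(ov[members])
    fold <- if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
    p <- if (n > 0) phyper(k - 1, K, N - K, n, lower.tail = FALSE) else NA_real_
    data.frame(cluster = g, k = k, n = n, K = K, N = N, fold = fold,
               pvalue = p)
  })
  out <- do.call(rbind, rows)
  out$qvalue <- p.adjust(out$pvalue, method = "BH")
  out$label <- if (!is.null(model$labels)) model$labels else NA_character_
  out <- out[, c("cluster", "label", "k", "n", "K", "N", "fold",
                 "pvalue", "qvalue")]
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Mean signal per cluster and sample
#'
#' Arithmetic mean of a per-element signal matrix within each merged
#' cluster, the numeric backbone of cluster-by-sample coverage heatmaps.
#' `NA` signal propagates; the number of missing values per cluster is
#' attached as attribute `"n_missing"`. Cluster rows follow the semantic
#' display order used by [order_elements()].
#'
#' @param values numeric matrix, element x sample (rownames are element
#'   ids covering the clustered elements).
#' @param model a [two_stage_cluster()] model.
#' @return Matrix cluster x sample of means.
#' @export
mean_signal_matrix <- function(values, model) {
  ids <- names(model$merged)
  miss <- setdiff(ids, rownames(values))
  if (length(miss)) stop("signal matrix missing element(s): ",
                         paste(head(miss, 5), collapse = ", "))
  v <- values[ids, , drop = FALSE]
  labels <- if (!is.null(model$labels)) model$labels
            else as.character(seq_len(model$k_final))
  ord <- order(semantic_label_rank(labels))
  out <- do.call(rbind, lapply(ord, function(g)
    colMeans(v[model$merged == g, , drop = FALSE])))
  rownames(out) <- paste0("cluster", ord,
                          ifelse(is.na(labels[ord]), "",
                                 paste0("_", labels[ord])))
  nm <- vapply(ord, function(g)
    sum(is.na(v[model$merged == g, , drop = FALSE])), 0L)
  attr(out, "n_missing") <- setNames(nm, rownames(out))
  attr(out, "cluster_order") <- ord
  out
}
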