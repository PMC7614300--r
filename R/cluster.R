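#' Build per-condition dynamics profiles
#'
#' Averages normalized accessibility over the replicates of each condition,
#' then z-scores each element across conditions so clustering captures the
#' shape of the dynamics rather than the amplitude. Zero-variance elements
#' cannot be z-scored and are dropped with a message.
#'
#' @param norm a [vst()] `normalized_matrix`.
#' @param samples a [sample_table()].
#' @param elements element ids to profile (e.g. the union of
#'   [select_differential()] calls); default all.
#' @param scale z-score rows (default `TRUE`).
#' @return Matrix element x condition of class `profile_matrix`, with the
#'   unscaled condition means in attribute `"condition_means"` and dropped
#'   ids in attribute `"dropped"`.
#' @export
build_profiles <- function(norm, samples, elements = rownames(norm$values),
                           scale = TRUE) {
  if (!length(elements)) stop("empty element selection")
  miss <- setdiff(elements, rownames(norm$values))
  if (length(miss)) stop("unknown element id(s): ",
                         paste(head(miss, 5), collapse = ", "))
  v <- norm$values[elements, , drop = FALSE]
  cid <- condition_id(samples)
  conds <- unique(cid)
  means <- sapply(conds, function(cn)
    rowMeans(v[, samples$sample_id[cid == cn], drop = FALSE]))
  means <- matrix(means, nrow = length(elements),
                  dimnames = list(elements, conds))
  sds <- apply(means, 1L, sd)
  dropped <- rownames(means)[sds == 0]
  if (length(dropped)) {
    message(length(dropped), " zero-variance element(s) dropped from profiles")
    means <- means[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  out <- if (scale) (means - rowMeans(means)) / sds else means
  attr(out, "condition_means") <- means
  attr(out, "dropped") <- dropped
  class(out) <- c("profile_matrix", class(out))
  out
}

# k-means with restarts. Initial centers are drawn from the canonically
# sorted distinct profiles and iterated with Lloyd batch updates, so the
# fitted partition does not depend on the row order of the input
# (over-parameterized k also falls back gracefully on duplicate-heavy data).
stage1_kmeans <- function(profiles, k1, nstart = 10) {
  uniq <- unique(profiles)
  uniq <- uniq[do.call(order, as.data.frame(uniq)), , drop = FALSE]
  k_eff <- min(k1, nrow(uniq))
  if (k_eff < k1)
    warning("only ", nrow(uniq), " distinct profiles; using k1 = ", k_eff)
  best <- NULL
  for (i in seq_len(if (k_eff < k1) 1L else nstart)) {
    cen <- uniq[sample.int(nrow(uniq), k_eff), , drop = FALSE]
    km <- tryCatch(
      suppressWarnings(kmeans(profiles, centers = cen, iter.max = 200,
                              algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss))
      best <- km
  }
  if (is.null(best))
    best <- suppressWarnings(kmeans(profiles, centers = k_eff,
                                    iter.max = 200, algorithm = "Lloyd"))
  # compact away empty clusters (possible under Lloyd updates)
  sizes <- tabulate(best$cluster, nbins = nrow(best$centers))
  if (any(sizes == 0)) {
    keep <- which(sizes > 0)
    best$centers <- best$centers[keep, , drop = FALSE]
    best$cluster <- match(best$cluster, keep)
  }
  best
}

#' Two-stage clustering of element dynamics
#'
#' Stage 1 over-partitions the profiles with k-means (`k1` centers, fixed
#' seed, multiple restarts); stage 2 merges centers of very similar
#' dynamics by average-linkage hierarchical clustering under correlation
#' distance (1 - Pearson), cutting the tree at `k_final` groups. The merged
#' assignment is the composition of the two, so the stage-1 partition
#' always refines the merged one.
#'
#' @param profiles a [build_profiles()] matrix.
#' @param k1 stage-1 center count (default 30).
#' @param k_final merged cluster count (default 9).
#' @param seed RNG seed; the procedure is deterministic given it.
#' @param distance stage-2 centroid distance, `"correlation"` (default) or
#'   `"euclidean"`.
#' @param linkage stage-2 linkage passed to [stats::hclust()];
#'   default `"average"`.
#' @return An object of class `cluster_model`: list with `stage1` and
#'   `merged` (named integer assignments), `stage1_to_merged`, `centroids`
#'   (`k_final` x condition, z-scored profile means), `k_final`, `seed`.
#' @export
two_stage_cluster <- function(profiles, k1 = 30, k_final = 9, seed = 1,
                              distance = c("correlation", "euclidean"),
                              linkage = "average") {
  distance <- match.arg(distance)
  if (k_final > k1) stop("k_final must not exceed k1")
  if (k1 > nrow(profiles)) stop("k1 exceeds the number of elements")
  set.seed(seed)
  km <- stage1_kmeans(profiles, k1)
  centers <- km$centers
  k_eff <- nrow(centers)
  if (k_final > k_eff)
    stop("k_final exceeds the ", k_eff, " distinct stage-1 centers")
  if (k_eff == k_final) {
    grp <- seq_len(k_eff)
  } else {
    dmat <- if (distance == "correlation") {
      cmat <- suppressWarnings(cor(t(centers)))
      cmat[!is.finite(cmat)] <- 0
      as.dist(1 - cmat)
    } else dist(centers)
    grp <- cutree(hclust(dmat, method = linkage), k = k_final)
  }
  # renumber merged clusters by order of first appearance for determinism
  grp <- match(grp, unique(grp))
  stage1 <- setNames(km$cluster, rownames(profiles))
  merged <- setNames(grp[km$cluster], rownames(profiles))
  centroids <- do.call(rbind, lapply(seq_len(max(grp)), function(g)
    colMeans(profiles[merged == g, , drop = FALSE])))
  rownames(centroids) <- seq_len(max(grp))
  structure(list(stage1 = stage1, merged = merged, stage1_to_merged = grp,
                 centroids = centroids, k_final = max(grp), seed = seed),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("cluster_model:", length(x$stage1), "elements,",
      length(unique(x$stage1)), "stage-1 clusters ->", x$k_final,
      "merged clusters\n")
  if (!is.null(x$labels))
    cat("labels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Principal component analysis of the most variable elements
#'
#' Ranks elements by variance across samples, keeps the `top_n` most
#' variable, centers per element, and computes sample-space PCs.
#'
#' @param norm a [vst()] `normalized_matrix`.
#' @param top_n number of elements to keep (default 30000); when it exceeds
#'   the matrix, all elements are used with a warning.
#' @return List with `coordinates` (sample x PC), `variance_explained`
#'   (fraction per PC, sums to 1 over all PCs), `elements_used`.
#' @export
pca_accessibility <- function(norm, top_n = 30000) {
  v <- norm$values
  if (ncol(v) < 2) stop("PCA needs at least 2 samples")
  if (top_n > nrow(v)) {
    warning("top_n exceeds the number of elements; using all ", nrow(v))
    top_n <- nrow(v)
  }
  vars <- apply(v, 1L, var)
  keep <- order(vars, decreasing = TRUE)[seq_len(top_n)]
  p <- prcomp(t(v[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(coordinates = p$x, variance_explained = ve,
       elements_used = rownames(v)[keep])
}

# Binarize a z-scored centroid into open/closed conditions. A condition is
# open when its z-score is at least the midpoint of the centroid's range;
# centroids with a range below min_range are flat (nothing open). The
# midpoint rule is scale-aware: broad patterns (open in most conditions)
# have small positive z in the open state and strongly negative z in the
# few closed ones, so a fixed cutoff would miss them.
centroid_open <- function(z, min_range = 0.5) {
  if (diff(range(z)) < min_range) return(rep(FALSE, length(z)))
  z >= (max(z) + min(z)) / 2
}

#' Assign semantic labels to merged clusters
#'
#' Rule-based tags from the z-scored centroids. Conditions with centroid
#' z-score `>= high_cut` form the "strongly high" set; if that set is
#' empty the midpoint-binarized open set (see the package vignette) is
#' used, which catches broad patterns whose z-scores are compressed.
#' A cluster is labeled `"NMP"` when its high conditions are all NMP
#' conditions; `"<cell_type>-specific"` when they belong to a single
#' neural cell type and every other neural condition sits at or below
#' zero, `"<cell_type>-enriched"` when a single type is high but other
#' types are intermediate; `"pan-neural"` when no NMP condition is high
#' and every neural type is open at the midpoint binarization; `"other"`
#' otherwise (including flat centroids).
#'
#' @param model a [two_stage_cluster()] model.
#' @param samples a [sample_table()] (supplies the condition metadata).
#' @param high_cut z-score above which a condition counts as strongly high
#'   (default 0.5).
#' @return The model with a `labels` character vector (one per merged
#'   cluster) added.
#' @export
label_clusters <- function(model, samples, high_cut = 0.5) {
  cid <- condition_id(samples)
  meta <- unique(data.frame(cond = cid, cell_type = samples$cell_type,
                            day = samples$day, stringsAsFactors = FALSE))
  cent <- model$centroids
  meta <- meta[match(colnames(cent), meta$cond), ]
  neural_types <- setdiff(unique(meta$cell_type), "NMP")
  labels <- character(nrow(cent))
  for (g in seq_len(nrow(cent))) {
    z <- cent[g, ]
    open <- centroid_open(z)
    high <- which(z >= high_cut)
    if (!length(high)) high <- which(open)
    if (!length(high)) { labels[g] <- "other"; next }
    hct <- unique(meta$cell_type[high])
    nmp_high <- "NMP" %in% hct
    if (all(hct == "NMP")) { labels[g] <- "NMP"; next }
    hct_neural <- setdiff(hct, "NMP")
    if (!nmp_high && length(hct_neural) == 1) {
      other_z <- z[meta$cell_type != hct_neural & meta$cell_type != "NMP"]
      labels[g] <- if (!length(other_z) || max(other_z) <= 0)
        paste0(hct_neural, "-specific") else paste0(hct_neural, "-enriched")
      next
    }
    if (!nmp_high &&
        all(vapply(neural_types, function(ct)
          any(open[meta$cell_type == ct]), TRUE))) {
      labels[g] <- "pan-neural"; next
    }
    labels[g] <- "other"
  }
  model$labels <- labels
  model
}

# Display rank of merged clusters: semantic class first (NMP, pan-neural,
# specific, enriched, other), ties broken by cluster id.
semantic_label_rank <- function(labels) {
  base <- ifelse(labels == "NMP", 1,
          ifelse(labels == "pan-neural", 2,
          ifelse(grepl("-specific$", labels), 3,
          ifelse(grepl("-enriched$", labels), 4, 5))))
  order(order(base, seq_along(labels)))
}

#' Order elements for heatmap display
#'
#' Clusters are ordered by semantic label (NMP, pan-neural, specific,
#' enriched, other; ties by label then cluster id); within each cluster,
#' elements are sorted by descending mean accessibility (mean of the
#' unscaled condition means), ties broken by element id.
#'
#' @param model a labeled [two_stage_cluster()] model.
#' @param profiles the [build_profiles()] matrix the model was fitted on.
#' @return Character vector of element ids in display order.
#' @export
order_elements <- function(model, profiles) {
  cm <- attr(profiles, "condition_means")
  if (is.null(cm)) cm <- profiles
  avg <- rowMeans(cm)
  labels <- model$labels
  if (is.null(labels)) labels <- as.character(seq_len(model$k_final))
  cl_rank <- semantic_label_rank(labels)
  ids <- names(model$merged)
  ord <- order(cl_rank[model$merged[ids]], -avg[ids], ids)
  ids[ord]
}

#' Clustering stability across seeds
#'
#' Reruns [two_stage_cluster()] for each seed and returns the mean pairwise
#' adjusted Rand index of the merged assignments.
#'
#' @param profiles a [build_profiles()] matrix.
#' @param k1,k_final as in [two_stage_cluster()].
#' @param seeds integer vector of >= 2 seeds.
#' @return List with `mean_ari` and the pairwise `ari` values.
#' @export
cluster_stability <- function(profiles, k1 = 30, k_final = 9,
                              seeds = 1:5) {
  if (length(seeds) < 2) stop("need at least 2 seeds")
  assigns <- lapply(seeds, function(s)
    two_stage_cluster(profiles, k1, k_final, seed = s)$merged)
  pairs <- utils::combn(length(seeds), 2)
  ari <- apply(pairs, 2L, function(p)
    mclust::adjustedRandIndex(assigns[[p[1]]], assigns[[p[2]]]))
  list(mean_ari = mean(ari), ari = ari)
}

#' Classify the regulatory regime of each cell type
#'
#' For every neural cell type, computes the fraction of the differential
#' elements accessible in that type (i.e. belonging to clusters whose
#' centroid is high in at least one of the type's conditions) that sit in
#' clusters labeled specific or enriched for the type ("NMP" counts as the
#' NMP-specific label). A fraction above `tau` indicates the cell type
#' maintains a private accessibility program (`differential_accessibility`
#' regime); otherwise its identity must be encoded by differential TF
#' binding on shared elements (`differential_binding`).
#'
#' @param model a labeled [two_stage_cluster()] model.
#' @param samples a [sample_table()].
#' @param tau specificity-fraction threshold (default 0.15; a simulator-
#'   calibrated artifact default, not a biological constant).
#' @return Data frame of class `regime_report`: `cell_type`, `regime`,
#'   `specificity_fraction`, `n_specific`, `n_accessible`.
#' @export
classify_regime <- function(model, samples, tau = 0.15) {
  if (is.null(model$labels))
    stop("run label_clusters() before classify_regime()")
  cid <- condition_id(samples)
  meta <- unique(data.frame(cond = cid, cell_type = samples$cell_type,
                            stringsAsFactors = FALSE))
  cent <- model$centroids
  meta <- meta[match(colnames(cent), meta$cond), ]
  sizes <- tabulate(model$merged, nbins = model$k_final)
  open_mat <- t(apply(cent, 1L, centroid_open))
  types <- unique(samples$cell_type)
  rows <- lapply(types, function(ct) {
    acc_cl <- which(apply(open_mat[, meta$cell_type == ct, drop = FALSE], 1L,
                          any))
    spec_lab <- c(paste0(ct, "-specific"), paste0(ct, "-enriched"),
                  if (ct == "NMP") "NMP")
    spec_cl <- which(model$labels %in% spec_lab)
    n_acc <- sum(sizes[acc_cl])
    n_spec <- sum(sizes[intersect(acc_cl, spec_cl)])
    frac <- if (n_acc > 0) n_spec / n_acc else 0
    if (n_acc == 0)
      warning("no differential elements accessible in ", ct)
    data.frame(cell_type = ct,
               regime = if (frac > tau) "differential_accessibility"
                        else "differential_binding",
               specificity_fraction = frac, n_specific = n_spec,
               n_accessible = n_acc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("regime_report", "data.frame")
  out
}

#' Write cluster assignments as TSV
#' @param model a labeled `cluster_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(model, path) {
  lab <- if (!is.null(model$labels)) model$labels[model$merged]
         else NA_character_
  write.table(data.frame(element_id = names(model$merged),
                         stage1 = model$stage1, merged = model$merged,
                         label = lab, stringsAsFactors = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
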