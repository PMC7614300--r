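make_norm <- function(v) structure(list(values = v, transform = "vst"),
                                   class = "normalized_matrix")

tiny_samples <- function(conds = 4, reps = 2) {
  sample_table(data.frame(
    sample_id = sprintf("c%d_r%d", rep(seq_len(conds), each = reps),
                        rep(seq_len(reps), conds)),
    cell_type = sprintf("t%d", rep(seq_len(conds), each = reps)),
    sag_nM = 0, day = 5, replicate = rep(seq_len(reps), conds)))
}

test_that("profiles average replicates then z-score per element", {
  st <- tiny_samples(conds = 3, reps = 2)
  v <- matrix(0, 3, 6, dimnames = list(c("e1", "e2", "e3"), st$sample_id))
  v["e1", ] <- c(2, 4, 10, 12, 20, 22)   # condition means 3, 11, 21
  v["e2", ] <- 7                          # constant: dropped
  v["e3", ] <- c(5, 5, 1, 1, 3, 3)
  expect_message(prof <- build_profiles(make_norm(v), st), "zero-variance")
  expect_equal(rownames(prof), c("e1", "e3"))
  cm <- attr(prof, "condition_means")
  expect_equal(unname(cm["e1", ]), c(3, 11, 21))
  expect_equal(unname(rowMeans(prof)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(prof, 1, sd)), c(1, 1), tolerance = 1e-12)
  expect_error(build_profiles(make_norm(v), st, character(0)), "empty")
})

test_that("two-stage clustering recovers exact planted partitions", {
  # 9 orthogonal patterns, 100 elements each, no noise
  set.seed(1)
  pat <- diag(9)
  v <- pat[rep(1:9, each = 100), ]
  rownames(v) <- sprintf("e%03d", 1:900)
  colnames(v) <- sprintf("cond%d", 1:9)
  prof <- (v - rowMeans(v)) / apply(v, 1, sd)
  expect_warning(model <- two_stage_cluster(prof, k1 = 30, k_final = 9,
                                            seed = 2),
                 "distinct")
  truth <- rep(1:9, each = 100)
  expect_equal(mclust::adjustedRandIndex(model$merged, truth), 1)
  # duplicate rows always co-cluster
  expect_equal(length(unique(model$merged[1:100])), 1L)
})

test_that("stage-1 partition refines the merged partition deterministically", {
  cs <- clustered_simulation(seed = 51, n_elements = 540)
  model <- cs$model
  # every stage-1 cluster maps into exactly one merged cluster
  expect_true(all(tapply(model$merged, model$stage1,
                         function(x) length(unique(x))) == 1L))
  expect_equal(model$merged,
               setNames(model$stage1_to_merged[model$stage1],
                        names(model$stage1)))
  # deterministic given the seed
  again <- two_stage_cluster(cs$profiles, 30, 9, seed = model$seed)
  expect_identical(again$merged, model$merged)
  # permutation invariance of the resulting partition
  perm <- sample(nrow(cs$profiles))
  shuffled <- two_stage_cluster(cs$profiles[perm, ], 30, 9,
                                seed = model$seed)
  expect_equal(mclust::adjustedRandIndex(
    shuffled$merged[names(model$merged)], model$merged), 1)

  expect_error(two_stage_cluster(cs$profiles, k1 = 5, k_final = 9), "k_final")
  expect_error(two_stage_cluster(cs$profiles, k1 = nrow(cs$profiles) + 1),
               "k1")
  # k1 = k_final makes stage 2 the identity partition of centers
  small <- two_stage_cluster(cs$profiles, k1 = 9, k_final = 9, seed = 3)
  expect_equal(sort(unique(small$stage1_to_merged)), 1:9)
  expect_equal(length(unique(paste(small$stage1, small$merged))), 9L)
})

test_that("planted 9-pattern data is recovered with high ARI and stability", {
  cs <- clustered_simulation(seed = 53, n_elements = 900)
  ari <- mclust::adjustedRandIndex(cs$model$merged, cs$truth_pattern)
  expect_gte(ari, 0.9)
  stab <- cluster_stability(cs$profiles, seeds = 1:3)
  expect_gte(stab$mean_ari, 0.95)
  # identical assignments give ARI exactly 1
  expect_equal(mclust::adjustedRandIndex(cs$model$merged, cs$model$merged), 1)
  # independent random labelings have ARI near 0
  set.seed(5)
  a <- sample(1:9, 5000, replace = TRUE)
  b <- sample(1:9, 5000, replace = TRUE)
  expect_lt(abs(mclust::adjustedRandIndex(a, b)), 0.02)
})

test_that("element ordering sorts by mean accessibility within clusters", {
  prof <- matrix(rnorm(40), 10, 4,
                 dimnames = list(sprintf("e%02d", 1:10), paste0("c", 1:4)))
  cm <- matrix(c(5, 3, rep(1, 8)), 10, 4,
               dimnames = dimnames(prof))
  cm[3, ] <- 1; cm[4, ] <- 1                    # ties broken by id
  attr(prof, "condition_means") <- cm
  model <- list(merged = setNames(rep(1:2, each = 5), rownames(prof)),
                k_final = 2, labels = c("other", "NMP"))
  ord <- order_elements(model, prof)
  # cluster 2 (NMP) ranks before cluster 1 (other)
  expect_equal(ord[1:5], sprintf("e%02d", 6:10))
  # within cluster 1: e01 (mean 5) then e02 (mean 3), then ties by id
  expect_equal(ord[6:10], c("e01", "e02", "e03", "e04", "e05"))
  # oracle: brute-force sort
  avg <- rowMeans(cm)
  rank_of <- c(other = 5, NMP = 1)[model$labels]
  want <- rownames(prof)[order(rank_of[model$merged], -avg,
                               rownames(prof))]
  expect_equal(ord, want)
})

test_that("PCA matches an independent eigendecomposition", {
  set.seed(7)
  v <- matrix(rnorm(300), 50, 6,
              dimnames = list(sprintf("e%02d", 1:50), sprintf("s%d", 1:6)))
  p <- pca_accessibility(make_norm(v), top_n = 50)
  centered <- sweep(t(v), 2, rowMeans(v))
  ev <- eigen(cov(centered))
  # variance explained matches eigenvalues
  expect_equal(p$variance_explained,
               ev$values[seq_along(p$variance_explained)] / sum(ev$values),
               tolerance = 1e-8)
  # coordinates match projections up to per-PC sign
  proj <- centered %*% ev$vectors
  for (k in seq_len(ncol(p$coordinates))) {
    d <- min(max(abs(p$coordinates[, k] - proj[, k])),
             max(abs(p$coordinates[, k] + proj[, k])))
    expect_lt(d, 1e-8)
  }
  # reconstruction from all PCs equals the centered input
  rec <- p$coordinates %*% t(prcomp(t(v))$rotation)
  expect_equal(rec, centered, tolerance = 1e-8, ignore_attr = TRUE)

  # duplicated sample groups: PC1 separates, coordinates equal within group
  v2 <- cbind(v[, c(1, 1, 1)], v[, c(2, 2, 2)] + 5)
  colnames(v2) <- sprintf("s%d", 1:6)
  p2 <- pca_accessibility(make_norm(v2), top_n = 50)
  expect_equal(p2$coordinates[1, 1], p2$coordinates[2, 1])
  expect_gt(abs(p2$coordinates[1, 1] - p2$coordinates[4, 1]), 1)

  # top_n = 1: coordinates proportional to that element's centered values
  vars <- apply(v, 1, var)
  top <- names(which.max(vars))
  p1 <- pca_accessibility(make_norm(v), top_n = 1)
  expect_equal(abs(as.numeric(p1$coordinates[, 1])),
               abs(v[top, ] - mean(v[top, ])), ignore_attr = TRUE)

  expect_warning(pca_accessibility(make_norm(v), top_n = 500), "all")
  expect_error(pca_accessibility(make_norm(v[, 1, drop = FALSE])), "2 samples")
})

test_that("label rules fire on canonical centroid shapes", {
  cfg <- sim_config(seed = 1, n_elements = 9)
  sim <- simulate_accessibility(cfg)
  conds <- unique(condition_id(sim$samples))
  meta <- unique(data.frame(cond = conds,
                            ct = sub("_.*", "", conds)))
  mk <- function(z) matrix(z, 1, length(conds),
                           dimnames = list("1", conds))
  lab1 <- function(z) {
    m <- list(centroids = mk(z), merged = setNames(1L, "e"), k_final = 1L)
    label_clusters(m, sim$samples)$labels
  }
  is_p3 <- meta$ct == "p3"; is_nmp <- meta$ct == "NMP"
  expect_equal(lab1(ifelse(is_p3, 1, -0.5)), "p3-specific")
  expect_equal(lab1(ifelse(is_p3, 1, ifelse(is_nmp, -1, 0.2))), "p3-enriched")
  expect_equal(lab1(ifelse(is_nmp, -1, 1)), "pan-neural")
  expect_equal(lab1(ifelse(is_nmp, 3, -0.3)), "NMP")
  expect_equal(lab1(rep(0, length(conds))), "other")
})

test_that("planted regimes are recovered end to end", {
  cs <- clustered_simulation(seed = 59, n_elements = 720)
  reg <- classify_regime(cs$model, cs$sim$samples)
  r <- setNames(reg$regime, reg$cell_type)
  expect_equal(unname(r["p3"]), "differential_accessibility")
  expect_true(all(r[c("p0-1", "p2", "pMN")] == "differential_binding"))
  expect_true(all(reg$specificity_fraction >= 0 &
                    reg$specificity_fraction <= 1))
})
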