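#' Build the pairwise comparison plan
#'
#' Enumerates exactly (i) every unordered pair of cell types sampled on the
#' same day and (ii) every unordered pair of days sampled for the same cell
#' type, the standard all-by-all design for cell-type-resolved
#' accessibility. Labels are deterministic (`"<A>_vs_<B>@d<day>"` and
#' `"<cell_type>@d<d1>_vs_d<d2>"`) and ordered within-day first.
#'
#' @param samples a [sample_table()].
#' @return A data frame of class `comparison_plan` with columns `label`,
#'   `type` (`"within_day"`/`"within_type"`) and list-columns `group_A`,
#'   `group_B` of sample ids.
#' @export
build_plan <- function(samples) {
  stopifnot(inherits(samples, "data.frame"))
  plan <- list()
  for (d in sort(unique(samples$day))) {
    cts <- sort(unique(samples$cell_type[samples$day == d]))
    if (length(cts) < 2) next
    for (i in seq_len(length(cts) - 1)) for (j in (i + 1):length(cts)) {
      ga <- samples$sample_id[samples$day == d & samples$cell_type == cts[i]]
      gb <- samples$sample_id[samples$day == d & samples$cell_type == cts[j]]
      plan[[length(plan) + 1L]] <- list(
        label = paste0(cts[i], "_vs_", cts[j], "@d", d),
        type = "within_day", group_A = ga, group_B = gb)
    }
  }
  for (ct in sort(unique(samples$cell_type))) {
    ds <- sort(unique(samples$day[samples$cell_type == ct]))
    if (length(ds) < 2) next
    for (i in seq_len(length(ds) - 1)) for (j in (i + 1):length(ds)) {
      ga <- samples$sample_id[samples$cell_type == ct & samples$day == ds[i]]
      gb <- samples$sample_id[samples$cell_type == ct & samples$day == ds[j]]
      plan[[length(plan) + 1L]] <- list(
        label = paste0(ct, "@d", ds[i], "_vs_d", ds[j]),
        type = "within_type", group_A = ga, group_B = gb)
    }
  }
  out <- data.frame(label = vapply(plan, `[[`, "", "label"),
                    type = vapply(plan, `[[`, "", "type"),
                    stringsAsFactors = FALSE)
  out$group_A <- lapply(plan, `[[`, "group_A")
  out$group_B <- lapply(plan, `[[`, "group_B")
  class(out) <- c("comparison_plan", "data.frame")
  out
}

#' Moderated method-of-moments dispersion estimates
#'
#' Per-element negative-binomial dispersion `alpha`
#' (`variance = mu + alpha * mu^2`) estimated on size-factor-normalized
#' counts. The raw per-element estimate is
#' `(s2 - m * mean(1/sf)) / m^2`, where `s2` is the pooled within-group
#' variance, `m` the mean normalized count and the `mean(1/sf)` term
#' accounts for the shot-noise inflation of normalized counts. With few
#' replicates the raw estimate is very noisy, so it is shrunk toward a
#' matrix-wide central value `sum(s2 - m/sf) / sum(m^2)` with `prior_df`
#' pseudo-degrees of freedom, in the spirit of empirical-Bayes dispersion
#' moderation; [wald_test()] then uses a t reference with
#' `residual df + prior_df` degrees of freedom. `prior_df = 0` gives the
#' raw (floored) per-element estimator.
#'
#' @param counts a [count_matrix()] or integer matrix.
#' @param factors per-sample size factors.
#' @param groups list of two character vectors of sample ids (the compared
#'   groups), each with >= 2 samples.
#' @param prior_df moderation strength; default 50.
#' @param alpha_floor lower bound for the estimates; default `1e-8`.
#' @return Named numeric vector of dispersions with attributes
#'   `resid_df`, `prior_df` and `central`.
#' @export
estimate_dispersion <- function(counts, factors, groups, prior_df = 50,
                                alpha_floor = 1e-8) {
  v <- if (inherits(counts, "count_matrix")) counts$values else as.matrix(counts)
  stopifnot(length(groups) == 2)
  if (any(lengths(groups) < 2))
    stop("need >= 2 replicates per group to estimate dispersion")
  sel <- c(groups[[1]], groups[[2]])
  x <- sweep(v[, sel, drop = FALSE], 2L, factors[sel], "/")
  idx <- list(seq_along(groups[[1]]),
              length(groups[[1]]) + seq_along(groups[[2]]))
  # group-wise moment excess: evaluating the NB variance model at each
  # group's own mean avoids the convexity bias a pooled mean would add for
  # genuinely differential elements
  excess <- 0; denom <- 0
  for (g in idx) {
    xg <- x[, g, drop = FALSE]
    mg <- rowMeans(xg)
    df_g <- ncol(xg) - 1L
    s2g <- rowSums((xg - mg)^2) / df_g
    inv_sf_g <- mean(1 / factors[sel[g]])
    excess <- excess + df_g * (s2g - mg * inv_sf_g)
    # mg^2 overestimates mu^2 by the sampling variance of the group mean;
    # debias so the central dispersion is not pulled low
    denom <- denom + df_g * pmax(mg^2 - s2g / ncol(xg), 0)
  }
  d <- length(sel) - 2L
  m <- rowMeans(x)
  central <- max(sum(excess) / sum(denom), alpha_floor)
  a_raw <- pmax(ifelse(denom > 0, excess / denom, alpha_floor), alpha_floor)
  a <- if (prior_df > 0)
    pmax((prior_df * central + d * a_raw) / (prior_df + d), alpha_floor)
  else a_raw
  structure(setNames(a, rownames(v)), resid_df = d, prior_df = prior_df,
            central = central)
}

#' Negative-binomial Wald test for one pairwise comparison
#'
#' A transparent, desk-scale substitute for a full GLM-based differential
#' test. The effect is `log2FC = log2(mB + c) - log2(mA + c)` on group
#' means of normalized counts, with pseudo-fraction
#' `c = 0.5 / median(scaled depth)`; its standard error comes from the
#' NB delta method, `var(log2 mG) = (mG/sfbar + alpha*mG^2) / (nG * mG^2 *
#' ln(2)^2)`. The Wald statistic is referred to a t distribution with
#' `residual + prior` degrees of freedom when the dispersions carry
#' moderation attributes (see [estimate_dispersion()]), otherwise to the
#' normal. P-values are Benjamini-Hochberg adjusted within the comparison;
#' `baseMean` is the mean normalized count over the compared samples.
#'
#' @param counts a [count_matrix()] or integer matrix.
#' @param factors per-sample size factors.
#' @param group_A,group_B character vectors of sample ids (>= 2 each).
#' @param dispersions per-element `alpha`, e.g. from
#'   [estimate_dispersion()]; a scalar is recycled.
#' @param label comparison label stored in the result.
#' @return Data frame of class `da_result` with columns `element_id`,
#'   `baseMean`, `log2FoldChange`, `se`, `pvalue`, `padj`, `comparison`.
#' @export
wald_test <- function(counts, factors, group_A, group_B, dispersions,
                      label = "A_vs_B") {
  v <- if (inherits(counts, "count_matrix")) counts$values else as.matrix(counts)
  if (length(group_A) < 2 || length(group_B) < 2)
    stop("single-replicate group: supply >= 2 replicates per group ",
         "(or pool dispersions across conditions)")
  if (length(intersect(group_A, group_B)))
    stop("groups must be disjoint")
  a <- rep_len(dispersions, nrow(v))
  xA <- sweep(v[, group_A, drop = FALSE], 2L, factors[group_A], "/")
  xB <- sweep(v[, group_B, drop = FALSE], 2L, factors[group_B], "/")
  mA <- rowMeans(xA); mB <- rowMeans(xB)
  nA <- length(group_A); nB <- length(group_B)
  cc <- 0.5 / median(colSums(v[, c(group_A, group_B), drop = FALSE]) /
                       factors[c(group_A, group_B)] /
                       nrow(v))
  cc <- max(cc, 1e-8)
  lfc <- log2(mB + cc) - log2(mA + cc)
  inv_sfA <- mean(1 / factors[group_A]); inv_sfB <- mean(1 / factors[group_B])
  mpA <- pmax(mA, cc); mpB <- pmax(mB, cc)
  se2 <- ((mpA * inv_sfA + a * mpA^2) / (nA * mpA^2) +
          (mpB * inv_sfB + a * mpB^2) / (nB * mpB^2)) / log(2)^2
  se <- sqrt(se2)
  z <- lfc / se
  df <- if (!is.null(attr(dispersions, "prior_df")) &&
            attr(dispersions, "prior_df") > 0)
    attr(dispersions, "resid_df") + attr(dispersions, "prior_df") else Inf
  p <- if (is.finite(df)) 2 * pt(-abs(z), df = df) else 2 * pnorm(-abs(z))
  res <- data.frame(element_id = rownames(v),
                    baseMean = rowMeans(cbind(xA, xB)),
                    log2FoldChange = lfc, se = se, pvalue = p,
                    padj = p.adjust(p, method = "BH"),
                    comparison = label, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("da_result", "data.frame")
  res
}

#' Run the Wald test over a whole comparison plan
#'
#' Convenience driver: estimates dispersions and tests each comparison of a
#' [build_plan()] plan.
#'
#' @param counts a [count_matrix()].
#' @param factors per-sample size factors.
#' @param plan a `comparison_plan`.
#' @param prior_df dispersion moderation, see [estimate_dispersion()].
#' @return Named list of `da_result` data frames, one per comparison.
#' @export
run_plan <- function(counts, factors, plan, prior_df = 50) {
  out <- lapply(seq_len(nrow(plan)), function(i) {
    grp <- list(plan$group_A[[i]], plan$group_B[[i]])
    disp <- estimate_dispersion(counts, factors, grp, prior_df = prior_df)
    wald_test(counts, factors, grp[[1]], grp[[2]], disp,
              label = plan$label[i])
  })
  setNames(out, plan$label)
}

#' Select differentially accessible elements
#'
#' Applies the standard three-part rule with strict inequalities:
#' `padj < padj_max`, `|log2FoldChange| > lfc_min`,
#' `baseMean > basemean_min`.
#'
#' @param results a `da_result` data frame from [wald_test()].
#' @param lfc_min log2 fold-change cutoff (default 2).
#' @param padj_max adjusted p-value cutoff (default 0.01).
#' @param basemean_min base-mean cutoff (default 100).
#' @return Character vector of selected element ids.
#' @export
select_differential <- function(results, lfc_min = 2, padj_max = 0.01,
                                basemean_min = 100) {
  if (!nrow(results)) return(character(0))
  keep <- !is.na(results$padj) & results$padj < padj_max &
    abs(results$log2FoldChange) > lfc_min & results$baseMean > basemean_min
  results$element_id[keep]
}

#' Count differential elements per comparison
#'
#' Summary counts in the style of a differential-region bar graph. Note the
#' default fold-change cutoff here is on the linear fold change
#' (`|FC| > 2`, i.e. `|log2FC| > 1`), the convention of such summaries,
#' whereas element selection for clustering uses `|log2FC| > 2`.
#'
#' @param results_list named list of `da_result` data frames.
#' @param fc_min linear fold-change cutoff (default 2).
#' @param padj_max adjusted p cutoff (default 0.01).
#' @param basemean_min base-mean cutoff (default 100).
#' @return Data frame with columns `comparison` and `n_differential`.
#' @export
count_differential <- function(results_list, fc_min = 2, padj_max = 0.01,
                               basemean_min = 100) {
  n <- vapply(results_list, function(r)
    length(select_differential(r, lfc_min = log2(fc_min),
                               padj_max = padj_max,
                               basemean_min = basemean_min)), 0L)
  data.frame(comparison = names(results_list), n_differential = n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write differential results as TSV
#' @param results a `da_result` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_da_results <- function(results, path) {
  if (inherits(results, "da_result")) results <- list(results)
  write.table(do.call(rbind, results), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
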