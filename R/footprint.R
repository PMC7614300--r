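#' Position weight matrix constructor
#'
#' @param mat 4 x L numeric matrix (rows A, C, G, T); counts are
#'   normalized to column probabilities.
#' @param name motif name.
#' @return List of class `pwm` with elements `mat` and `name`.
#' @export
pwm <- function(mat, name = "motif") {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 4) stop("PWM must have length >= 4")
  cs <- colSums(mat)
  if (any(cs <= 0)) stop("PWM column(s) sum to zero")
  mat <- sweep(mat, 2L, cs, "/")
  rownames(mat) <- c("A", "C", "G", "T")
  structure(list(mat = mat, name = name), class = "pwm")
}

reverse_complement_pwm <- function(mat) {
  mat[4:1, ncol(mat):1, drop = FALSE]
}

#' Read motifs from a JASPAR-style PFM file
#'
#' Accepts the JASPAR text dialect: a `>name` header followed by four rows,
#' either bare numbers or `A [ 1 2 3 ]` style. Counts and probabilities are
#' both accepted; columns are normalized to probabilities.
#'
#' @param path file path.
#' @return Named list of [pwm()] objects.
#' @export
read_pfm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no '>' motif headers found in ", path)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    name <- sub("^>\\s*", "", lines[heads[i]])
    name <- strsplit(name, "\\s+")[[1]][1]
    body <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) != 4)
      stop("motif '", name, "': expected 4 matrix rows, found ", length(body))
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*\\[?", "", l)
      l <- gsub("\\]\\s*$", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1)
      stop("motif '", name, "': ragged matrix rows")
    out[[name]] <- pwm(do.call(rbind, rows), name = name)
  }
  out
}

#' Write motifs in JASPAR PFM text format
#' @param motifs list of [pwm()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pfm <- function(motifs, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (m in motifs) {
    writeLines(paste0(">", m$name), con)
    for (b in 1:4)
      writeLines(paste0(rownames(m$mat)[b], " [ ",
                        paste(formatC(m$mat[b, ], format = "g"),
                              collapse = " "), " ]"), con)
  }
  invisible(path)
}

#' Footprint depletion score of an insertion profile
#'
#' Transposase insertions at a bound motif are depleted in the motif center
#' relative to the flanks. The score is
#' `log2((mean flank + c) / (mean center + c))` with pseudocount `c`;
#' positive values indicate protection (a footprint). The center is the
#' middle `center_width` positions of the window; the flanks are the
#' `flank_width` positions at each end.
#'
#' @param insertion_profile non-negative per-position insertion counts.
#' @param center_width width of the central window.
#' @param flank_width width of each flank.
#' @param pseudocount default 1.
#' @return Scalar score.
#' @export
footprint_score <- function(insertion_profile, center_width = 10,
                            flank_width = 10, pseudocount = 1) {
  n <- length(insertion_profile)
  if (n < center_width + 2 * flank_width)
    stop("window (", n, ") shorter than center + 2 * flank")
  if (any(insertion_profile < 0)) stop("insertion counts must be >= 0")
  mid <- (n - center_width) %/% 2
  center <- insertion_profile[(mid + 1):(mid + center_width)]
  flank <- c(insertion_profile[1:flank_width],
             insertion_profile[(n - flank_width + 1):n])
  log2((mean(flank) + pseudocount) / (mean(center) + pseudocount))
}

#' Differential footprint scores between two conditions
#'
#' Per-motif score difference `delta = score_B - score_A`, standardized
#' against the background of all motifs in the same comparison with a
#' robust z (`(delta - median) / (1.4826 * MAD)`), and a two-sided normal
#' p-value. Scores are already log-like, so differences play the role of
#' fold changes.
#'
#' @param table motif x condition footprint score matrix.
#' @param cond_A,cond_B condition column names.
#' @return Data frame `motif`, `delta`, `z`, `pvalue`.
#' @export
differential_footprints <- function(table, cond_A, cond_B) {
  if (!all(c(cond_A, cond_B) %in% colnames(table)))
    stop("condition(s) not in footprint table")
  if (nrow(table) < 10)
    stop("need >= 10 motifs to form a background distribution")
  delta <- table[, cond_B] - table[, cond_A]
  scale <- mad(delta)
  if (scale == 0)                  # degenerate MAD (>= 50% identical deltas):
    scale <- 1.2533 * mean(abs(delta - median(delta)))
  if (scale == 0) scale <- Inf     # all deltas equal: z = 0, p = 1
  z <- (delta - median(delta)) / scale
  data.frame(motif = rownames(table), delta = delta, z = z,
             pvalue = 2 * pnorm(-abs(z)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select the most variable motifs across comparisons
#'
#' Per comparison, takes the union of the top `top_pct` percent of motifs
#' by `|delta|` and the `top_pct` percent smallest p-values (boundary by
#' ceiling count, ties broken by value then motif name), then the union
#' over comparisons.
#'
#' @param diff_list list of [differential_footprints()] results.
#' @param top_pct percentage (default 5).
#' @return Character vector of selected motif names (sorted).
#' @export
select_variable_motifs <- function(diff_list, top_pct = 5) {
  if (!length(diff_list)) stop("need results for at least one comparison")
  if (inherits(diff_list, "data.frame")) diff_list <- list(diff_list)
  sel <- character(0)
  for (d in diff_list) {
    n_take <- ceiling(top_pct / 100 * nrow(d))
    by_delta <- d$motif[order(-abs(d$delta), d$motif)][seq_len(n_take)]
    by_p <- d$motif[order(d$pvalue, d$motif)][seq_len(n_take)]
    sel <- union(sel, union(by_delta, by_p))
  }
  sort(sel)
}

# Best ungapped alignment similarity between two PWMs: max over offsets and
# the reverse complement of the mean column-wise Pearson correlation,
# requiring >= min_cols aligned columns.
pwm_similarity <- function(a, b, min_cols = 4) {
  score_off <- function(x, y) {
    lx <- ncol(x); ly <- ncol(y)
    best <- -1
    for (off in -(ly - min_cols):(lx - min_cols)) {
      ix <- max(1, 1 + off):min(lx, ly + off)
      iy <- ix - off
      if (length(ix) < min_cols) next
      cors <- vapply(seq_along(ix), function(k) {
        cx <- x[, ix[k]]; cy <- y[, iy[k]]
        if (sd(cx) == 0 || sd(cy) == 0) return(1 * (sd(cx) == sd(cy)))
        cor(cx, cy)
      }, 0)
      best <- max(best, mean(cors))
    }
    best
  }
  max(score_off(a$mat, b$mat),
      score_off(a$mat, reverse_complement_pwm(b$mat)))
}

#' Group motifs into archetypes by PWM similarity
#'
#' Pairwise similarity is the best ungapped-alignment mean column
#' correlation over all offsets and the reverse complement (minimum 4
#' aligned columns); motifs are merged by average-linkage hierarchical
#' clustering of `1 - similarity`, cutting the tree at
#' `1 - similarity_min`. Used when no published archetype mapping is
#' supplied; a published two-column mapping should win when available.
#'
#' @param motifs list of [pwm()] objects.
#' @param similarity_min merge threshold (default 0.8).
#' @return List with `motif_to_archetype` (named character) and
#'   `archetype_members` (list of motif names per archetype).
#' @export
cluster_archetypes <- function(motifs, similarity_min = 0.8) {
  if (!length(motifs)) stop("need at least one motif")
  nm <- vapply(motifs, function(m) m$name, "")
  n <- length(motifs)
  if (n == 1) {
    grp <- 1L
  } else {
    sim <- matrix(1, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      sim[i, j] <- sim[j, i] <- pwm_similarity(motifs[[i]], motifs[[j]])
    hc <- hclust(as.dist(1 - sim), method = "average")
    grp <- cutree(hc, h = 1 - similarity_min)
  }
  arch <- paste0("archetype", match(grp, unique(grp)))
  members <- split(nm, arch)
  list(motif_to_archetype = setNames(arch, nm),
       archetype_members = members[unique(arch)])
}

#' Aggregate motif footprint scores into archetype scores
#'
#' Archetype score per condition is the mean of its member motifs' scores;
#' archetypes are ranked by score variance across the designated condition
#' subset.
#'
#' @param table motif x condition footprint matrix.
#' @param map archetype map (list with `motif_to_archetype`), e.g. from
#'   [cluster_archetypes()] or a simulated/published mapping.
#' @param conditions condition subset used for the variability ranking;
#'   default all columns.
#' @return Archetype x condition matrix, rows ordered by decreasing
#'   variability, with the variances in attribute `"variability"`.
#' @export
archetype_scores <- function(table, map, conditions = colnames(table)) {
  m2a <- map$motif_to_archetype
  unmapped <- setdiff(rownames(table), names(m2a))
  if (length(unmapped))
    stop("unmapped motif(s): ", paste(head(unmapped, 5), collapse = ", "))
  arch <- m2a[rownames(table)]
  out <- rowsum(table, group = arch) / as.vector(table(arch)[sort(unique(arch))])
  vab <- apply(out[, conditions, drop = FALSE], 1L, var)
  out <- out[order(-vab), , drop = FALSE]
  attr(out, "variability") <- sort(vab, decreasing = TRUE)
  out
}

#' Rank candidate driver TFs by footprint-RNA correlation
#'
#' For each archetype, correlates every associated TF gene's expression
#' with the archetype footprint score across the shared conditions, and
#' ranks genes by decreasing Pearson r (ties by gene name). Genes missing
#' from the RNA matrix are reported and skipped; zero-variance genes get
#' `NA` correlation and rank last.
#'
#' @param arch_scores archetype x condition matrix
#'   ([archetype_scores()]).
#' @param rna gene x condition expression matrix.
#' @param membership list mapping archetype id to member gene names.
#' @param conditions condition subset (default: all shared conditions).
#' @return Data frame of class `candidate_tf`: `archetype`, `gene`,
#'   `pearson_r`, `rank`.
#' @export
rank_candidate_tfs <- function(arch_scores, rna, membership,
                               conditions = NULL) {
  shared <- intersect(colnames(arch_scores), colnames(rna))
  if (!is.null(conditions)) shared <- intersect(shared, conditions)
  if (length(shared) < 3)
    stop("need >= 3 shared conditions for correlation")
  rows <- list()
  for (a in intersect(rownames(arch_scores), names(membership))) {
    genes <- membership[[a]]
    missing <- setdiff(genes, rownames(rna))
    if (length(missing))
      message("archetype ", a, ": gene(s) absent from RNA matrix: ",
              paste(missing, collapse = ", "))
    genes <- setdiff(genes, missing)
    if (!length(genes)) next
    s <- arch_scores[a, shared]
    r <- vapply(genes, function(g) {
      e <- rna[g, shared]
      if (sd(e) == 0 || sd(s) == 0) NA_real_ else cor(e, s)
    }, 0)
    ord <- order(!is.finite(r), -r, genes)   # NAs last, then desc r
    rows[[a]] <- data.frame(archetype = a, gene = genes[ord],
                            pearson_r = r[ord],
                            rank = seq_along(genes),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("candidate_tf", "data.frame")
  out
}
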