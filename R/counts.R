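#' Construct a fragment count matrix
#'
#' @param values integer matrix, elements x samples, with row and column
#'   names (element ids / sample ids).
#' @param library_total optional per-sample total fragment counts (named or
#'   in column order); must be at least the column sums.
#' @return An object of class `count_matrix`: a list with `values` and
#'   `library_total`.
#' @export
count_matrix <- function(values, library_total = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("count matrix needs element ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("row and column labels must be unique")
  if (any(values < 0) || any(values != round(values)))
    stop("counts must be non-negative integers")
  storage.mode(values) <- "integer"
  if (!is.null(library_total)) {
    if (!is.null(names(library_total)))
      library_total <- library_total[colnames(values)]
    if (length(library_total) != ncol(values))
      stop("library_total must have one entry per sample")
    if (any(colSums(values) > library_total))
      stop("library_total smaller than in-peak column sum for sample(s): ",
           paste(colnames(values)[colSums(values) > library_total], collapse = ", "))
  }
  structure(list(values = values, library_total = library_total),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$values), "elements x", ncol(x$values),
      "samples\n")
  invisible(x)
}

#' Construct a sample metadata table
#'
#' @param df data frame with columns `sample_id`, `cell_type`, `sag_nM`,
#'   `day`, `replicate`; `sample_id` must be unique.
#' @return A data frame of class `sample_table`.
#' @export
sample_table <- function(df) {
  need <- c("sample_id", "cell_type", "sag_nM", "day", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("sample_id values must be unique")
  df <- as.data.frame(df)
  df$sample_id <- as.character(df$sample_id)
  df$cell_type <- as.character(df$cell_type)
  rownames(df) <- NULL
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Condition identifier for each sample
#'
#' A condition is the `(cell_type, day, sag_nM)` triple; replicates of a
#' condition share its id.
#'
#' @param samples a [sample_table()].
#' @return Character vector of condition ids, one per sample row.
#' @export
condition_id <- function(samples) {
  paste(samples$cell_type, paste0("d", samples$day),
        paste0("sag", samples$sag_nM), sep = "_")
}

#' Read a count table
#'
#' Tab-separated file with a header; the columns `id`, `chrom`, `start`,
#' `end` (any present are used as annotation, `id` required) followed by one
#' integer column per sample.
#'
#' @param path file path.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  meta <- intersect(c("id", "chrom", "start", "end"), names(df))
  if (!"id" %in% meta) stop("count table must contain an 'id' column")
  vals <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  if (any(vals != round(vals), na.rm = TRUE))
    stop("non-integer count(s) in rows: ",
         paste(head(which(rowSums(vals != round(vals)) > 0), 5), collapse = ", "))
  rownames(vals) <- df$id
  count_matrix(vals)
}

#' Write a count table
#' @param counts a [count_matrix()].
#' @param path output path.
#' @param peaks optional [peak_set()] supplying chrom/start/end annotation.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, peaks = NULL) {
  df <- data.frame(id = rownames(counts$values), stringsAsFactors = FALSE)
  if (!is.null(peaks)) {
    m <- match(df$id, peaks$id)
    df$chrom <- peaks$chrom[m]; df$start <- peaks$start[m]; df$end <- peaks$end[m]
  }
  df <- cbind(df, as.data.frame(counts$values, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#' @param path tab-separated file with the [sample_table()] columns.
#' @return A [sample_table()].
#' @export
read_samples <- function(path) {
  sample_table(read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE))
}

#' Write a sample metadata table
#' @param samples a [sample_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  write.table(as.data.frame(samples), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Median-of-ratios size factors
#'
#' The standard library-size estimator for count matrices: per sample, the
#' median ratio of counts to the per-element geometric mean, computed over
#' elements with nonzero counts in all samples.
#'
#' @param counts a [count_matrix()] or integer matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  v <- if (inherits(counts, "count_matrix")) counts$values else as.matrix(counts)
  all_pos <- rowSums(v == 0) == 0
  if (!any(all_pos))
    stop("no element with nonzero counts in every sample; ",
         "size factors undefined (consider a pseudo-reference fallback)")
  lv <- log(v[all_pos, , drop = FALSE])
  log_geo <- rowMeans(lv)
  sf <- apply(lv, 2L, function(col) exp(median(col - log_geo)))
  setNames(sf, colnames(v))
}

#' Variance-stabilizing transform of counts
#'
#' Applies `log2(count / size_factor + pseudocount)`: a simple monotone
#' transform that equalizes the contribution of high- and low-count
#' elements to clustering and PCA.
#'
#' @param counts a [count_matrix()] or integer matrix.
#' @param factors positive per-sample size factors, e.g. [size_factors()].
#' @param pseudocount added inside the log; default 1, so a zero count at
#'   size factor 1 maps to 0.
#' @return An object of class `normalized_matrix`: list with `values`,
#'   `size_factors` and `transform = "vst"`.
#' @export
vst <- function(counts, factors, pseudocount = 1) {
  v <- if (inherits(counts, "count_matrix")) counts$values else as.matrix(counts)
  if (length(factors) != ncol(v)) stop("one size factor per sample required")
  if (any(factors <= 0)) stop("size factors must be positive")
  out <- log2(sweep(v, 2L, factors, "/") + pseudocount)
  structure(list(values = out, size_factors = factors, transform = "vst"),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix (", x$transform, "): ", nrow(x$values),
      " elements x ", ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' Fraction of reads in peaks (FRiP)
#'
#' @param counts a [count_matrix()] with `library_total` set.
#' @return Named numeric vector of per-sample fractions in `[0, 1]`.
#' @export
frip <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  if (is.null(counts$library_total))
    stop("frip() requires library_total")
  tot <- counts$library_total
  if (any(tot == 0))
    stop("zero-depth sample(s): ",
         paste(colnames(counts$values)[tot == 0], collapse = ", "))
  cs <- colSums(counts$values)
  if (any(cs > tot))
    stop("in-peak counts exceed library_total for sample(s): ",
         paste(colnames(counts$values)[cs > tot], collapse = ", "))
  setNames(cs / tot, colnames(counts$values))
}

#' Pairwise sample correlation (R-squared)
#'
#' Squared Pearson correlation between all sample pairs of a normalized
#' matrix, optionally restricted to promoter or distal elements.
#'
#' @param norm a [vst()] `normalized_matrix`.
#' @param subset `"all"`, `"promoter"` or `"distal"`.
#' @param labels per-element promoter/distal labels from [annotate_tss()];
#'   required unless `subset = "all"`.
#' @return Symmetric sample x sample matrix of R-squared values with unit
#'   diagonal. Zero-variance samples give `NA` entries with a warning.
#' @export
sample_correlation <- function(norm, subset = c("all", "promoter", "distal"),
                               labels = NULL) {
  subset <- match.arg(subset)
  v <- norm$values
  if (subset != "all") {
    if (is.null(labels)) stop("labels required for subset = ", subset)
    v <- v[names(labels)[labels == subset], , drop = FALSE]
  }
  if (nrow(v) < 2) stop("need at least 2 elements in subset '", subset, "'")
  sds <- apply(v, 2L, sd)
  r <- suppressWarnings(cor(v))
  if (any(sds == 0)) {
    warning("zero-variance sample(s): ",
            paste(colnames(v)[sds == 0], collapse = ", "),
            "; correlations set to NA")
    r[sds == 0, ] <- NA; r[, sds == 0] <- NA
  }
  r2 <- r^2
  diag(r2) <- 1
  r2
}
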