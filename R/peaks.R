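#' Construct a peak set
#'
#' A `peak_set` holds genomic elements as BED-convention intervals:
#' 0-based, half-open `[start, end)`. Intervals are sorted by
#' `(chrom, start)` on construction and element ids must be unique.
#' An optional element x sample matrix of peak-calling q-values can be
#' attached; it is consumed by [filter_consensus()].
#'
#' @param chrom character vector of contig names.
#' @param start,end integer vectors; `0 <= start < end` (half-open).
#' @param id optional unique element ids; generated as
#'   `"<chrom>:<start>-<end>"` when missing.
#' @param qval optional numeric matrix of per-sample q-values with one row
#'   per interval (rownames are matched to `id` when present).
#' @return A data frame of class `peak_set` with columns
#'   `chrom`, `start`, `end`, `id`, carrying the q-value matrix as
#'   attribute `"qval"`.
#' @export
peak_set <- function(chrom, start, end, id = NULL, qval = NULL) {
  n <- length(chrom)
  if (length(start) != n || length(end) != n)
    stop("chrom, start and end must have equal length")
  start <- as.integer(start)
  end <- as.integer(end)
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stop("invalid interval(s) at row(s) ", paste(head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  if (is.null(id))
    id <- paste0(chrom, ":", start, "-", end)
  id <- as.character(id)
  if (anyDuplicated(id))
    stop("duplicate element id(s): ",
         paste(head(unique(id[duplicated(id)]), 5), collapse = ", "))
  ord <- order(chrom, start, end)
  df <- data.frame(chrom = as.character(chrom)[ord], start = start[ord],
                   end = end[ord], id = id[ord], stringsAsFactors = FALSE)
  rownames(df) <- NULL
  if (!is.null(qval)) {
    qval <- as.matrix(qval)
    if (nrow(qval) != n)
      stop("qval must have one row per interval")
    if (!is.null(rownames(qval))) {
      if (!setequal(rownames(qval), df$id))
        stop("qval rownames do not match interval ids")
      qval <- qval[df$id, , drop = FALSE]
    } else {
      qval <- qval[ord, , drop = FALSE]
      rownames(qval) <- df$id
    }
  }
  attr(df, "qval") <- qval
  class(df) <- c("peak_set", "data.frame")
  df
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set with", nrow(x), "intervals on",
      length(unique(x$chrom)), "contig(s)")
  if (!is.null(attr(x, "qval")))
    cat(";", ncol(attr(x, "qval")), "q-value sample(s)")
  cat("\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

qval_matrix <- function(peaks) attr(peaks, "qval")

#' Read a BED file of peaks
#'
#' Accepts BED3 and wider (BED6/narrowPeak-style) files; columns beyond the
#' first four are ignored. Malformed rows are reported with their line
#' numbers.
#'
#' @param path file path.
#' @return A [peak_set()].
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(peak_set(character(), integer(), integer()))
  fields <- strsplit(lines, "\t| +")
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED line(s) with fewer than 3 fields: line ",
         paste(head(which(nf < 3), 5), collapse = ", "))
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stop("malformed BED interval at line(s): ",
         paste(head(bad, 5), collapse = ", "))
  id <- ifelse(nf >= 4, vapply(fields, `[`, "", 4L), NA_character_)
  if (anyNA(id) || anyDuplicated(id)) id <- NULL
  peak_set(chrom, start, end, id)
}

#' Write a peak set as BED4
#' @param peaks a [peak_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  write.table(as.data.frame(peaks)[, c("chrom", "start", "end", "id")],
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter consensus peaks on per-sample q-values
#'
#' Keeps the intervals whose q-value is strictly below `q_max` in at least
#' one sample, the standard consensus filter applied after per-sample MACS
#' peak calling.
#'
#' @param peaks a [peak_set()] with an attached q-value matrix.
#' @param q_max q-value cutoff (strict inequality); default `1e-5`.
#' @return The filtered `peak_set` (q-value matrix subset accordingly).
#' @export
filter_consensus <- function(peaks, q_max = 1e-5) {
  qv <- qval_matrix(peaks)
  if (is.null(qv))
    stop("filter_consensus() requires a per-sample q-value matrix ",
         "(attach it via peak_set(qval = ...))")
  keep <- apply(qv, 1L, function(r) any(r < q_max, na.rm = TRUE))
  keep_ids <- rownames(qv)[keep]
  sel <- peaks$id %in% keep_ids
  out <- peaks[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qval") <- qv[out$id, , drop = FALSE]
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Label elements as promoter or distal relative to TSSs
#'
#' An element is `"promoter"` if it overlaps the window extending
#' `window_bp` bases on both sides of any TSS position (the TSS itself
#' counts as one base, so `window_bp = 0` tests overlap with the single
#' TSS base), and `"distal"` otherwise. All arithmetic is half-open.
#'
#' @param peaks a [peak_set()].
#' @param tss data frame with columns `chrom` and `position`
#'   (0-based base coordinate); a `strand` column is accepted and ignored.
#' @param window_bp non-negative integer window half-width; default 500.
#' @return Character vector (`"promoter"`/`"distal"`), named by element id.
#' @export
annotate_tss <- function(peaks, tss, window_bp = 500) {
  stopifnot(window_bp >= 0)
  lab <- setNames(rep("distal", nrow(peaks)), peaks$id)
  if (!nrow(peaks) || !NROW(tss)) return(lab)
  tss <- as.data.frame(tss)
  for (ch in unique(peaks$chrom)) {
    pi <- which(peaks$chrom == ch)
    ti <- which(tss$chrom == ch)
    if (!length(ti)) next
    # half-open [p - w, p + w + 1) window, converted to closed 1-based
    q <- IRanges::IRanges(start = peaks$start[pi] + 1L, end = peaks$end[pi])
    w <- IRanges::IRanges(start = tss$position[ti] - window_bp + 1L,
                          end = tss$position[ti] + window_bp + 1L)
    hit <- IRanges::countOverlaps(q, w) > 0
    lab[pi[hit]] <- "promoter"
  }
  lab
}
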