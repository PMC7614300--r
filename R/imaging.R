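#' Segment nuclei from a DAPI channel
#'
#' Gaussian smoothing, global Otsu thresholding, 8-connected component
#' labeling, and an area filter. Constant images have no Otsu threshold
#' and yield zero nuclei with a warning.
#'
#' @param dapi 2-D intensity matrix.
#' @param smooth_sigma Gaussian sigma in pixels (default 2; 0 disables).
#' @param min_area,max_area inclusive nucleus area bounds in pixels.
#' @return List with `labels` (integer label matrix, 0 = background) and
#'   `records`: data frame `label`, `row`, `col` (centroid), `area_px`.
#' @export
segment_nuclei <- function(dapi, smooth_sigma = 2, min_area = 30,
                           max_area = 1e4) {
  if (!length(dapi)) stop("empty image")
  if (diff(range(dapi)) == 0) {
    warning("constant image: Otsu threshold undefined, no nuclei")
    return(list(labels = matrix(0L, nrow(dapi), ncol(dapi)),
                records = empty_records()))
  }
  img <- dapi / max(dapi)
  if (smooth_sigma > 0)
    img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = smooth_sigma))
  thr <- EBImage::otsu(EBImage::Image(img), range = range(img), levels = 256)
  mask <- img > thr
  lab <- label_components_8(mask)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area & areas <= max_area)
  relab <- integer(length(areas))
  relab[keep] <- seq_along(keep)
  lab[lab > 0] <- relab[lab[lab > 0]]
  records <- if (length(keep)) {
    idx <- which(lab > 0, arr.ind = TRUE)
    l <- lab[lab > 0]
    data.frame(label = seq_along(keep),
               row = as.vector(tapply(idx[, 1], l, mean)),
               col = as.vector(tapply(idx[, 2], l, mean)),
               area_px = as.vector(table(l)))
  } else empty_records()
  list(labels = lab, records = records)
}

empty_records <- function() {
  data.frame(label = integer(0), row = numeric(0), col = numeric(0),
             area_px = integer(0))
}

# 8-connected labeling: 4-connected pass (EBImage::bwlabel), then merge
# labels that touch diagonally via union-find.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n < 2) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  for (dd in list(c(1, 1), c(1, -1))) {
    a <- lab[seq_len(nr - 1), if (dd[2] == 1) seq_len(nc - 1) else 2:nc]
    b <- lab[2:nr, if (dd[2] == 1) 2:nc else seq_len(nc - 1)]
    touch <- which(a > 0 & b > 0 & a != b)
    for (t in touch) {
      ra <- find(a[t]); rb <- find(b[t])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  lab[lab > 0] <- match(root, sort(unique(root)))[lab[lab > 0]]
  lab
}

#' Per-nucleus mean channel intensities
#'
#' @param labels integer label matrix from [segment_nuclei()].
#' @param stack image stack (list with named `channels` matrices of the
#'   same shape).
#' @return The segmentation records with one `mean_<channel>` column per
#'   channel.
#' @export
measure_intensities <- function(labels, stack) {
  seg_labels <- if (is.list(labels)) labels$labels else labels
  records <- if (is.list(labels) && !is.null(labels$records)) labels$records
             else NULL
  for (ch in names(stack$channels))
    if (!identical(dim(stack$channels[[ch]]), dim(seg_labels)))
      stop("channel '", ch, "' shape differs from label image")
  if (is.null(records)) {
    ids <- sort(setdiff(unique(as.vector(seg_labels)), 0L))
    records <- data.frame(label = ids)
  }
  inside <- seg_labels > 0
  l <- seg_labels[inside]
  for (ch in names(stack$channels)) {
    v <- stack$channels[[ch]][inside]
    m <- tapply(v, l, mean)
    records[[paste0("mean_", ch)]] <- as.vector(m[as.character(records$label)])
  }
  records
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Find an intensity threshold
#'
#' Otsu's method on the empirical histogram (256 bins) of per-nucleus
#' intensities, or an empirical quantile.
#'
#' @param values numeric vector (e.g. per-nucleus mean intensities).
#' @param method `"otsu"` or `"quantile"`.
#' @param q quantile level when `method = "quantile"`.
#' @return Scalar threshold.
#' @export
find_threshold <- function(values, method = c("otsu", "quantile"), q = 0.5) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (method == "quantile") return(unname(quantile(values, q)))
  if (length(unique(values)) < 2)
    stop("Otsu needs >= 2 distinct values; consider method = 'quantile'")
  rng <- range(values)
  breaks <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(values, breaks, all.inside = TRUE), 256)
  mids <- (breaks[-1] + breaks[-257]) / 2
  w <- cumsum(h); m <- cumsum(h * mids)
  n <- w[256]; mt <- m[256]
  w0 <- w[-256]; m0 <- m[-256]
  between <- ifelse(w0 == 0 | w0 == n, -Inf,
                    (mt * w0 - m0 * n)^2 / (w0 * (n - w0)))
  breaks[which.max(between) + 1L]
}

#' Classify nuclei into p3 / V3 / other
#'
#' p3 cells express both SOX2 and NKX2.2; V3 neurons express NKX2.2 only;
#' everything else is "other". tdTomato positivity is thresholded
#' independently.
#'
#' @param records data frame from [measure_intensities()] with columns
#'   `mean_SOX2`, `mean_NKX2.2`, `mean_tdTomato`.
#' @param thresholds named list/vector with `SOX2`, `NKX2.2`, `tdTomato`.
#' @return `records` with `class` (p3/V3/other) and `tdtomato_positive`
#'   columns added.
#' @export
classify_cells <- function(records, thresholds) {
  need <- c("SOX2", "NKX2.2", "tdTomato")
  if (!all(need %in% names(thresholds)))
    stop("thresholds must name ", paste(need, collapse = ", "))
  cols <- paste0("mean_", need)
  miss <- setdiff(cols, names(records))
  if (length(miss)) stop("missing channel column(s): ",
                         paste(miss, collapse = ", "))
  sox <- records$mean_SOX2 > thresholds[["SOX2"]]
  nkx <- records$mean_NKX2.2 > thresholds[["NKX2.2"]]
  records$class <- ifelse(sox & nkx, "p3", ifelse(nkx, "V3", "other"))
  records$tdtomato_positive <- records$mean_tdTomato > thresholds[["tdTomato"]]
  records
}

#' Positional quality control of NKX2.2+ cells
#'
#' Antibody background can produce NKX2.2 signal far from the p3 domain;
#' NKX2.2-positive cells (class p3 or V3) farther than `max_distance_px`
#' from the domain center are flagged as failed and excluded from counts.
#' The default center is the component-wise median position of the
#' NKX2.2+ cells, which is robust to the few outlying background cells
#' themselves.
#'
#' @param cells classified records from [classify_cells()].
#' @param center optional `(row, col)` domain center; default as above.
#' @param max_distance_px distance cutoff in pixels.
#' @return `cells` with a logical `passed_position_qc` column.
#' @export
position_qc <- function(cells, max_distance_px, center = NULL) {
  nkx <- cells$class %in% c("p3", "V3")
  cells$passed_position_qc <- TRUE
  if (!any(nkx)) {
    warning("no NKX2.2+ cells; all pass positional QC")
    return(cells)
  }
  if (is.null(center))
    center <- c(median(cells$row[nkx]), median(cells$col[nkx]))
  d <- sqrt((cells$row - center[1])^2 + (cells$col - center[2])^2)
  cells$passed_position_qc <- !(nkx & d > max_distance_px)
  cells
}

#' Per-section counts of lineage-traced cells
#'
#' @param cells classified (and optionally QC-ed) records.
#' @param section_id identifier stored in the summary.
#' @return One-row data frame: `section_id`, `n_p3`, `n_v3`, `n_other`,
#'   `n_p3_tdtom`, `n_v3_tdtom` (QC-passing cells only).
#' @export
count_per_section <- function(cells, section_id = NA_character_) {
  if (!is.null(cells$passed_position_qc))
    cells <- cells[cells$passed_position_qc, , drop = FALSE]
  data.frame(section_id = section_id,
             n_p3 = sum(cells$class == "p3"),
             n_v3 = sum(cells$class == "V3"),
             n_other = sum(cells$class == "other"),
             n_p3_tdtom = sum(cells$class == "p3" & cells$tdtomato_positive),
             n_v3_tdtom = sum(cells$class == "V3" & cells$tdtomato_positive),
             stringsAsFactors = FALSE)
}

#' Quantify lineage tracing across simulated or real sections
#'
#' Full imaging pipeline: segment each section on DAPI, measure channel
#' intensities, pool per-nucleus intensities across sections to find
#' marker thresholds, classify, apply positional QC, and count per
#' section.
#'
#' @param stacks list of image stacks.
#' @param max_distance_px positional QC cutoff; `Inf` disables.
#' @param smooth_sigma,min_area,max_area passed to [segment_nuclei()].
#' @param threshold_method passed to [find_threshold()].
#' @return List with `cells` (all classified records, with `section_id`)
#'   and `summary` (per-section counts).
#' @export
quantify_sections <- function(stacks, max_distance_px = Inf,
                              smooth_sigma = 2, min_area = 30,
                              max_area = 1e4,
                              threshold_method = "otsu") {
  per <- lapply(stacks, function(st) {
    seg <- segment_nuclei(st$channels$DAPI, smooth_sigma, min_area, max_area)
    rec <- measure_intensities(seg, st)
    rec$section_id <- st$section_id
    rec
  })
  all_rec <- do.call(rbind, per)
  if (!nrow(all_rec))
    return(list(cells = all_rec,
                summary = do.call(rbind, lapply(stacks, function(st)
                  count_per_section(empty_records(), st$section_id)))))
  thr <- list(SOX2 = find_threshold(all_rec$mean_SOX2, threshold_method),
              `NKX2.2` = find_threshold(all_rec$mean_NKX2.2, threshold_method),
              tdTomato = find_threshold(all_rec$mean_tdTomato,
                                        threshold_method))
  cells <- lapply(per, function(rec) {
    cc <- classify_cells(rec, thr)
    if (is.finite(max_distance_px)) cc <- position_qc(cc, max_distance_px)
    cc
  })
  summary <- do.call(rbind, Map(function(cc, st)
    count_per_section(cc, st$section_id), cells, stacks))
  list(cells = do.call(rbind, cells), summary = summary,
       thresholds = thr)
}
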