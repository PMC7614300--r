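#' Simulate multi-channel lineage-tracing section images
#'
#' Renders each section as four channels (DAPI, SOX2, NKX2.2, tdTomato).
#' Nuclei are disks placed by rejection sampling inside a central domain,
#' with pairwise center distance greater than twice the radius plus a small
#' margin so segmentation is unambiguous at zero noise. Marker channels
#' follow the planted class: p3 nuclei are SOX2+NKX2.2+, V3 nuclei
#' NKX2.2-only, "other" nuclei SOX2-only or unmarked; a planted tdTomato
#' flag drives the lineage-trace channel. Optional "background" nuclei are
#' NKX2.2+ cells placed far outside the domain, emulating off-target
#' antibody binding that positional QC must remove. Gaussian noise of sd
#' `noise_sd` is added to every channel and clamped at zero.
#'
#' @param config a [sim_config()]; see the `image` argument of
#'   [sim_config()] for the parameters.
#' @return List with `stacks` (list of image stacks, each a list with
#'   `channels` = named list of matrices and `section_id`) and `truth`
#'   (data frame: `section_id`, `nucleus`, `row`, `col`, `class` in
#'   p3/V3/other/background, `tdtom`).
#' @export
simulate_sections <- function(config) {
  validate_config(config)
  img <- config$image
  set.seed(config$seed + 2L)
  sz <- img$size; rad <- img$radius_px
  min_d2 <- (2 * rad + img$sep_margin)^2
  center <- (sz + 1) / 2
  dom_r <- img$domain_frac * sz
  stacks <- vector("list", img$n_sections)
  truth <- NULL
  for (s in seq_len(img$n_sections)) {
    n_main <- img$n_nuclei
    n_bg <- img$n_background
    pts <- matrix(NA_real_, n_main + n_bg, 2)
    attempts <- 0L
    placed <- 0L
    while (placed < n_main + n_bg) {
      attempts <- attempts + 1L
      if (attempts > 500L * (n_main + n_bg))
        stop("could not place ", n_main + n_bg, " nuclei of radius ", rad,
             " in a ", sz, "px section; reduce n_nuclei or radius_px")
      if (placed < n_main) {                    # inside the central domain
        ang <- runif(1, 0, 2 * pi); rr <- dom_r * sqrt(runif(1))
        p <- center + rr * c(cos(ang), sin(ang))
      } else {                                  # background: far corners
        p <- runif(2, rad + 1, sz - rad)
        if (sqrt(sum((p - center)^2)) < 0.55 * sz) next
      }
      if (p[1] < rad + 1 || p[1] > sz - rad ||
          p[2] < rad + 1 || p[2] > sz - rad) next
      if (placed > 0) {
        d2 <- (pts[seq_len(placed), 1] - p[1])^2 +
              (pts[seq_len(placed), 2] - p[2])^2
        if (min(d2) <= min_d2) next
      }
      placed <- placed + 1L
      pts[placed, ] <- p
    }
    cls <- if (n_main > 0)
      sample(names(img$class_probs), n_main, replace = TRUE,
             prob = img$class_probs) else character(0)
    cls <- c(cls, rep("background", n_bg))
    tdtom <- runif(n_main + n_bg) < img$tdtom_prob
    tdtom[cls == "background"] <- FALSE
    sox2_on <- cls == "p3" | (cls == "other" & runif(n_main + n_bg) < 0.5)
    nkx_on <- cls %in% c("p3", "V3", "background")

    hi <- img$channel_high; lo <- img$channel_low
    ch <- list(DAPI = matrix(0, sz, sz), SOX2 = matrix(0, sz, sz),
               NKX2.2 = matrix(0, sz, sz), tdTomato = matrix(0, sz, sz))
    if (placed > 0) {
      for (i in seq_len(placed)) {
        rows <- max(1, floor(pts[i, 1] - rad)):min(sz, ceiling(pts[i, 1] + rad))
        cols <- max(1, floor(pts[i, 2] - rad)):min(sz, ceiling(pts[i, 2] + rad))
        d2 <- outer((rows - pts[i, 1])^2, (cols - pts[i, 2])^2, "+")
        disk <- d2 <= rad^2
        add <- function(mat, val) {
          mat[rows, cols][disk] <- val
          mat
        }
        ch$DAPI <- add(ch$DAPI, img$dapi_mean)
        ch$SOX2 <- add(ch$SOX2, if (sox2_on[i]) hi else lo)
        ch$NKX2.2 <- add(ch$NKX2.2, if (nkx_on[i]) hi else lo)
        ch$tdTomato <- add(ch$tdTomato, if (tdtom[i]) hi else lo)
      }
    }
    if (img$noise_sd > 0)
      ch <- lapply(ch, function(m)
        pmax(m + matrix(rnorm(sz * sz, sd = img$noise_sd), sz, sz), 0))
    sid <- sprintf("section_%02d", s)
    stacks[[s]] <- list(channels = ch, section_id = sid)
    if (placed > 0)
      truth <- rbind(truth, data.frame(
        section_id = sid, nucleus = seq_len(placed),
        row = pts[seq_len(placed), 1], col = pts[seq_len(placed), 2],
        class = cls, tdtom = tdtom, sox2_on = sox2_on,
        stringsAsFactors = FALSE))
  }
  list(stacks = stacks, truth = truth)
}

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' Channels are written in the fixed order DAPI, SOX2, NKX2.2, tdTomato,
#' scaled by 1/65535.
#'
#' @param stack an image stack from [simulate_sections()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  chans <- stack$channels[c("DAPI", "SOX2", "NKX2.2", "tdTomato")]
  tiff::writeTIFF(lapply(chans, function(m) pmin(m, 65535) / 65535),
                  path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_image_stack()]
#' @param path TIFF path.
#' @param section_id section identifier to attach.
#' @return An image stack (list with `channels`, `section_id`).
#' @export
read_image_stack <- function(path, section_id = basename(path)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 4)
    stop("expected 4 channel pages, found ", length(pages))
  ch <- lapply(pages, function(p) round(p * 65535, 6))
  names(ch) <- c("DAPI", "SOX2", "NKX2.2", "tdTomato")
  list(channels = ch, section_id = section_id)
}
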