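blank_stack <- function(sz = 64) {
  list(channels = list(DAPI = matrix(0, sz, sz), SOX2 = matrix(0, sz, sz),
                       NKX2.2 = matrix(0, sz, sz),
                       tdTomato = matrix(0, sz, sz)),
       section_id = "blank")
}

test_that("segmentation recovers well-separated planted disks exactly", {
  cfg <- sim_config(seed = 101, image = list(n_sections = 1, n_nuclei = 20,
                                             noise_sd = 0))
  ss <- simulate_sections(cfg)
  seg <- segment_nuclei(ss$stacks[[1]]$channels$DAPI)
  expect_equal(nrow(seg$records), 20L)
  # centroids within 1 px of the planted centers
  tr <- ss$truth
  d <- vapply(seq_len(nrow(seg$records)), function(i)
    min(sqrt((tr$row - seg$records$row[i])^2 +
               (tr$col - seg$records$col[i])^2)), 0)
  expect_lt(max(d), 1)

  expect_warning(seg0 <- segment_nuclei(matrix(5, 32, 32)), "constant")
  expect_equal(nrow(seg0$records), 0L)

  # a single disk below min_area is filtered out
  img <- matrix(0, 32, 32); img[15:17, 15:17] <- 100
  seg_small <- segment_nuclei(img, smooth_sigma = 0, min_area = 30)
  expect_equal(nrow(seg_small$records), 0L)
  seg_keep <- segment_nuclei(img, smooth_sigma = 0, min_area = 5)
  expect_equal(nrow(seg_keep$records), 1L)
})

test_that("eight-connectivity joins diagonal components", {
  m <- matrix(FALSE, 8, 8)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE          # touch only diagonally
  lab <- regland:::label_components_8(m)
  expect_equal(max(lab), 1L)
  m[6, 6] <- TRUE                            # separate component
  expect_equal(max(regland:::label_components_8(m)), 2L)
})

test_that("intensity measurement equals brute-force per-label means", {
  set.seed(103)
  lab <- matrix(0L, 20, 20)
  lab[2:5, 2:5] <- 1L; lab[10:14, 10:14] <- 2L
  ch1 <- matrix(7, 20, 20)
  ch2 <- matrix(rnorm(400), 20, 20)
  st <- list(channels = list(A = ch1, B = ch2), section_id = "s")
  rec <- measure_intensities(lab, st)
  expect_equal(rec$mean_A, c(7, 7))          # uniform channel
  for (g in 1:2)
    expect_equal(rec$mean_B[g], mean(ch2[lab == g]))
  st_bad <- list(channels = list(A = matrix(0, 5, 5)))
  expect_error(measure_intensities(lab, st_bad), "shape")
})

test_that("threshold finding separates bimodal intensities", {
  t1 <- find_threshold(c(1, 1, 1, 9, 9, 9), "otsu")
  expect_gt(t1, 1); expect_lt(t1, 9)
  expect_equal(find_threshold(1:9, "quantile", q = 0.5), 5)
  expect_error(find_threshold(rep(3, 10), "otsu"), "quantile")
  # Gaussian mixture: misclassification below 1%
  set.seed(107)
  lo <- rnorm(2000, 100, 20); hi <- rnorm(2000, 1000, 20)
  thr <- find_threshold(c(lo, hi), "otsu")
  err <- (sum(lo > thr) + sum(hi <= thr)) / 4000
  expect_lt(err, 0.01)
})

test_that("classification rules encode the marker logic", {
  rec <- data.frame(label = 1:4, row = 1, col = 1,
                    mean_SOX2 = c(100, 10, 100, 10),
                    mean_NKX2.2 = c(100, 100, 10, 10),
                    mean_tdTomato = c(100, 10, 100, 10))
  thr <- list(SOX2 = 50, `NKX2.2` = 50, tdTomato = 50)
  cc <- classify_cells(rec, thr)
  expect_equal(cc$class, c("p3", "V3", "other", "other"))
  expect_equal(cc$tdtomato_positive, c(TRUE, FALSE, TRUE, FALSE))
  expect_error(classify_cells(rec, list(SOX2 = 1)), "thresholds")
  # monotone: raising the SOX2 threshold never converts V3 to p3
  cc_hi <- classify_cells(rec, list(SOX2 = 150, `NKX2.2` = 50,
                                    tdTomato = 50))
  expect_false(any(cc$class == "V3" & cc_hi$class == "p3"))
  expect_equal(cc_hi$class[1], "V3")   # p3 downgraded, never the reverse
})

test_that("positional QC excludes exactly the planted far background cells", {
  cells <- data.frame(label = 1:5,
                      row = c(50, 52, 48, 50, 190),
                      col = c(50, 48, 52, 50, 190),
                      class = c("p3", "p3", "V3", "other", "V3"),
                      tdtomato_positive = FALSE)
  q <- position_qc(cells, max_distance_px = 30)
  expect_equal(q$passed_position_qc, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # non-NKX cells are never excluded by position
  far_other <- data.frame(label = 1, row = 500, col = 500, class = "other",
                          tdtomato_positive = FALSE)
  both <- position_qc(rbind(cells, far_other), max_distance_px = 30)
  expect_true(both$passed_position_qc[6])
  expect_warning(position_qc(data.frame(label = 1, row = 1, col = 1,
                                        class = "other",
                                        tdtomato_positive = FALSE), 10),
                 "no NKX2.2")
})

test_that("per-section counting respects QC and tdTomato flags", {
  cells <- data.frame(class = c("p3", "p3", "p3", "V3", "V3", "other"),
                      tdtomato_positive = c(TRUE, TRUE, FALSE, TRUE,
                                            FALSE, TRUE),
                      passed_position_qc = TRUE)
  s <- count_per_section(cells, "s1")
  expect_equal(c(s$n_p3_tdtom, s$n_v3_tdtom), c(2L, 1L))
  cells$passed_position_qc <- FALSE
  s0 <- count_per_section(cells, "s1")
  expect_equal(c(s0$n_p3_tdtom, s0$n_v3_tdtom), c(0L, 0L))
})

test_that("the imaging pipeline recovers planted sections exactly at zero noise", {
  cfg <- sim_config(seed = 109, image = list(n_sections = 3, n_nuclei = 18,
                                             noise_sd = 0, n_background = 2))
  ss <- simulate_sections(cfg)
  q <- quantify_sections(ss$stacks, max_distance_px = 0.42 * 192)
  tr <- ss$truth[ss$truth$class != "background", ]
  agg <- aggregate(cbind(p3 = class == "p3", v3 = class == "V3",
                         p3t = class == "p3" & tdtom,
                         v3t = class == "V3" & tdtom) ~ section_id, tr, sum)
  m <- merge(q$summary, agg)
  expect_equal(m$n_p3, m$p3)
  expect_equal(m$n_v3, m$v3)
  expect_equal(m$n_p3_tdtom, m$p3t)
  expect_equal(m$n_v3_tdtom, m$v3t)
  # the excluded cells are exactly the planted background nuclei
  excl <- q$cells[!q$cells$passed_position_qc, ]
  expect_equal(nrow(excl), sum(ss$truth$class == "background"))

  # empty section: no nuclei, empty truth
  cfg0 <- sim_config(seed = 109, image = list(n_sections = 1, n_nuclei = 0))
  ss0 <- simulate_sections(cfg0)
  expect_null(ss0$truth)
  expect_equal(max(ss0$stacks[[1]]$channels$DAPI), 0)
})

test_that("image stacks round-trip through 16-bit TIFF", {
  cfg <- sim_config(seed = 113, image = list(n_sections = 1, n_nuclei = 5,
                                             noise_sd = 0))
  st <- simulate_sections(cfg)$stacks[[1]]
  tmp <- tempfile(fileext = ".tif")
  write_image_stack(st, tmp)
  st2 <- read_image_stack(tmp, st$section_id)
  for (ch in names(st$channels))
    expect_equal(st2$channels[[ch]], st$channels[[ch]], tolerance = 1e-4,
                 ignore_attr = TRUE)
})
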