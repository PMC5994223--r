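make_disk <- function(img, r0, c0, rad, value = 1000) {
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img)))
    if ((r - r0)^2 + (c - c0)^2 <= rad^2) img[r, c] <- value
  img
}

noise_cal <- function(mu = 500, sd = 50, k = 3, seed = 99) {
  set.seed(seed)
  calibrate(matrix(rnorm(256 * 256, mu, sd), 256), k_sigma = k)
}

test_that("a constant nuclear channel yields zero nuclei with a warning", {
  expect_warning(ns <- segment_nuclei(matrix(0, 64, 64)), "constant")
  expect_equal(nrow(ns$nuclei), 0L)
})

test_that("two fused disks with a neck are split into two nuclei", {
  img <- matrix(0, 60, 60)
  img <- make_disk(img, 30, 22, 9)
  img <- make_disk(img, 30, 39, 9)   # centres 17 apart: overlapping disks
  ns <- segment_nuclei(img + 100, smoothing_sigma = 1)
  expect_equal(nrow(ns$nuclei), 2L)
  expect_lt(min(abs(ns$nuclei$col - 22)), 2)
  expect_lt(min(abs(ns$nuclei$col - 39)), 2)
})

test_that("simulated nuclei are recovered with sub-2px centroids", {
  fld <- simulate_field(small_params(seed = 31))
  ns <- segment_nuclei(fld$nuclear)
  tr <- fld$truth$nuclei
  expect_equal(nrow(ns$nuclei), nrow(tr))
  d <- vapply(seq_len(nrow(tr)), function(i)
    min(sqrt((ns$nuclei$row - tr$row[i])^2 + (ns$nuclei$col - tr$col[i])^2)),
    0)
  expect_lt(max(d), 2)
  # labels are consecutive and the mask matches the table
  expect_equal(sort(unique(as.vector(ns$label_mask[ns$label_mask > 0]))),
               seq_len(nrow(ns$nuclei)))
})

test_that("calibration reproduces the analytic mean + k*sd threshold", {
  cal <- noise_cal(mu = 100, sd = 10, k = 3)
  expect_lt(abs(cal$intensity_threshold - 130), 1)
  expect_equal(cal$intensity_threshold,
               cal$ko_background_mean + 3 * cal$ko_background_sd)
  # k = 0 collapses onto the background mean
  cal0 <- noise_cal(mu = 100, sd = 10, k = 0)
  expect_equal(cal0$intensity_threshold, cal0$ko_background_mean)
  # default diameter rule is a fixed 3 px
  expect_equal(cal$diameter_threshold_px, 3)
})

test_that("calibration requires a negative control", {
  expect_error(calibrate(list()), "negative control")
})

test_that("wt-derived diameter thresholding uses the observed dot diameter", {
  ko <- simulate_negative_control(small_params(seed = 41))
  wt <- simulate_field(small_params(seed = 42))
  cal <- calibrate(list(ko$signal), list(wt$signal),
                   diameter_mode = "wt-derived", wt_diameter_fraction = 0.5)
  expect_false(is.na(cal$wt_mean_dot_diameter))
  expect_equal(cal$diameter_threshold_px,
               max(1, floor(cal$wt_mean_dot_diameter * 0.5)))
  expect_error(calibrate(list(ko$signal), diameter_mode = "wt-derived"),
               "wild-type")
})

test_that("a blank signal channel yields no dots", {
  cal <- noise_cal()
  set.seed(1)
  blank <- matrix(rnorm(256 * 256, 500, 50), 256)
  expect_equal(nrow(detect_dots(blank, cal)), 0L)
})

test_that("the equivalent-diameter filter rejects small components only", {
  cal <- noise_cal()
  img <- matrix(0, 64, 64)
  img[10, 10] <- 5000                     # 1 px: eq diameter 1.13
  img <- make_disk(img, 40, 40, 1.6, 5000)  # area 9: eq diameter 3.39
  dots <- detect_dots(img, cal, median_radius = 0)
  expect_equal(nrow(dots), 1L)
  expect_gte(dots$eq_diameter, 3)
  expect_equal(unname(round(c(dots$row, dots$col))), c(40, 40))
})

test_that("raising the intensity threshold never increases the dot count", {
  fld <- simulate_field(small_params(seed = 44))
  ko <- simulate_negative_control(small_params(seed = 45))
  counts <- vapply(c(1, 2, 3, 5, 8), function(k) {
    cal <- calibrate(list(ko$signal), k_sigma = k)
    nrow(detect_dots(fld$signal, cal))
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("declumping splits fused dots at intensity saddles", {
  cal <- noise_cal()
  img <- matrix(0, 64, 64)
  # two Gaussian peaks 5 px apart: one fused component at this threshold
  for (ctr in list(c(30, 28), c(30, 33))) {
    w <- outer((1:64 - ctr[1])^2, (1:64 - ctr[2])^2, "+")
    img <- img + 6000 * exp(-w / (2 * 1.1^2))
  }
  fused <- detect_dots(img, cal, median_radius = 0)
  expect_equal(nrow(fused), 1L)
  split <- detect_dots(img, cal, median_radius = 0, declump = TRUE,
                       max_single_dot_area_px = 20)
  expect_equal(nrow(split), 2L)
})

test_that("dots are assigned to the closest nucleus with the documented tie rule", {
  lbm <- matrix(0L, 80, 80)
  lbm[10:16, 10:16] <- 2L
  lbm[10:16, 40:46] <- 7L
  ns <- structure(list(label_mask = lbm,
                       nuclei = data.frame(label = c(2L, 7L),
                                           row = c(13, 13), col = c(13, 43),
                                           area = 49, eq_diameter = 7.9)),
                  class = "nucleus_set")
  dots <- structure(data.frame(
    row = c(12, 13, 13, 75), col = c(12, 28, 30, 75),
    area = 10, eq_diameter = 3.5, mean_intensity = 1000,
    assigned_label = NA_integer_, distance_to_nucleus = NA_real_),
    class = c("dot_set", "data.frame"))
  out <- assign_dots(dots, ns, max_distance_px = 30)
  # inside nucleus 2: label 2, distance 0
  expect_equal(out$assigned_label[1], 2L)
  expect_equal(out$distance_to_nucleus[1], 0)
  # (13, 28): exactly equidistant between mask pixels of 2 and 7 -> lowest label
  expect_equal(out$assigned_label[2], 2L)
  # (13, 30): closer to nucleus 7
  expect_equal(out$assigned_label[3], 7L)
  # far dot beyond max distance stays unassigned but records its distance
  expect_true(is.na(out$assigned_label[4]))
  expect_gt(out$distance_to_nucleus[4], 30)
})

test_that("boundary-pixel assignment equals exhaustive per-pixel search", {
  for (s in c(51, 52)) {
    fld <- simulate_field(small_params(seed = s))
    ko <- simulate_negative_control(small_params(seed = s + 10))
    cal <- calibrate(list(ko$signal))
    ns <- segment_nuclei(fld$nuclear)
    dots <- detect_dots(fld$signal, cal)
    a <- assign_dots(dots, ns)
    b <- assign_dots(dots, ns, method = "bruteforce")
    expect_identical(a$assigned_label, b$assigned_label)
    expect_equal(a$distance_to_nucleus, b$distance_to_nucleus)
  }
})

test_that("assignment with zero nuclei warns and leaves dots unassigned", {
  suppressWarnings(ns <- segment_nuclei(matrix(0, 32, 32)))
  dots <- structure(data.frame(row = 5, col = 5, area = 10,
                               eq_diameter = 3.5, mean_intensity = 1,
                               assigned_label = NA_integer_,
                               distance_to_nucleus = NA_real_),
                    class = c("dot_set", "data.frame"))
  expect_warning(out <- assign_dots(dots, ns), "no nuclei")
  expect_true(is.na(out$assigned_label))
})

test_that("region metrics follow the documented arithmetic", {
  lbm <- matrix(0L, 50, 50)
  nuc <- data.frame(label = 1:10, row = 5 + 4 * (0:9), col = 25,
                    area = 1, eq_diameter = 1.1)
  for (i in 1:10) lbm[nuc$row[i], nuc$col[i]] <- i
  ns <- structure(list(label_mask = lbm, nuclei = nuc),
                  class = "nucleus_set")
  counts <- c(3, rep(0, 2), 1, rep(0, 6))
  rows <- unlist(mapply(function(lab, k) rep(nuc$row[lab], k),
                        1:10, counts))
  dots <- structure(data.frame(
    row = rows, col = 25, area = 10, eq_diameter = 3.5, mean_intensity = 1,
    assigned_label = rep(1:10, counts), distance_to_nucleus = 0),
    class = c("dot_set", "data.frame"))
  q <- quantify_region(dots, ns, field_area_mm2 = 0.5)
  expect_equal(q$metrics$pct_positive_cells, 20)
  expect_equal(q$metrics$mean_dots_per_positive_cell, 2)
  expect_equal(q$metrics$dots_per_area_mm2, 4 / 0.5)
  expect_equal(unname(q$histogram[c(1, 3)]), c(1L, 1L))
  expect_equal(sum(q$histogram), 2L)
  # conservation: per-cell counts + unassigned = detected
  expect_equal(sum(q$per_cell$dot_count), q$metrics$n_dots_assigned)

  # raising the positivity cutoff can only lower the positive percentage
  q2 <- quantify_region(dots, ns, 0.5, positive_min_dots = 2)
  expect_lte(q2$metrics$pct_positive_cells, q$metrics$pct_positive_cells)
  expect_equal(q2$metrics$pct_positive_cells, 10)
})

test_that("zero nuclei yields missing (not zero) cell metrics", {
  suppressWarnings(ns <- segment_nuclei(matrix(0, 32, 32)))
  dots <- structure(data.frame(row = 5, col = 5, area = 10,
                               eq_diameter = 3.5, mean_intensity = 1,
                               assigned_label = NA_integer_,
                               distance_to_nucleus = NA_real_),
                    class = c("dot_set", "data.frame"))
  expect_warning(q <- quantify_region(dots, ns, 0.1), "undefined")
  expect_true(is.na(q$metrics$pct_positive_cells))
  expect_true(is.na(q$metrics$mean_dots_per_positive_cell))
  expect_equal(q$metrics$dots_per_area_mm2, 10)
})

test_that("the histogram's last bin is open-ended", {
  lbm <- matrix(0L, 20, 20)
  lbm[5, 5] <- 1L
  ns <- structure(list(label_mask = lbm,
                       nuclei = data.frame(label = 1L, row = 5, col = 5,
                                           area = 1, eq_diameter = 1.1)),
                  class = "nucleus_set")
  dots <- structure(data.frame(row = rep(5, 9), col = 5, area = 10,
                               eq_diameter = 3.5, mean_intensity = 1,
                               assigned_label = 1L, distance_to_nucleus = 0),
                    class = c("dot_set", "data.frame"))
  q <- quantify_region(dots, ns, 0.1, histogram_max_bin = 5)
  expect_equal(unname(q$histogram["5"]), 1L)
  expect_equal(sum(q$histogram), 1L)
})

test_that("pipeline output is invariant under integer translation", {
  fld <- simulate_field(small_params(seed = 61))
  ko <- simulate_negative_control(small_params(seed = 62))
  cal <- calibrate(list(ko$signal))
  run_metrics <- function(nucch, sigch) {
    ns <- segment_nuclei(nucch)
    dots <- assign_dots(detect_dots(sigch, cal), ns)
    quantify_region(dots, ns, 1)$metrics
  }
  m0 <- run_metrics(fld$nuclear, fld$signal)
  # translate both channels down-right by (7, 11) into a padded canvas so
  # no content is lost at the borders
  shift <- function(m, dr, dc) {
    out <- matrix(median(m), nrow(m) + dr, ncol(m) + dc)
    out[(dr + 1):(nrow(m) + dr), (dc + 1):(ncol(m) + dc)] <- m
    out
  }
  m1 <- run_metrics(shift(fld$nuclear, 7, 11), shift(fld$signal, 7, 11))
  expect_equal(m1$n_nuclei, m0$n_nuclei)
  expect_equal(m1$n_dots_detected, m0$n_dots_detected)
  expect_equal(m1$pct_positive_cells, m0$pct_positive_cells)
  expect_equal(m1$mean_dots_per_positive_cell,
               m0$mean_dots_per_positive_cell)
})
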