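#' Parameters for the synthetic two-channel field simulator
#'
#' Defines the imaging conditions emulated by [simulate_field()]: a
#' DAPI-like nuclear channel (smoothed disks plus read noise) and a
#' FastRED-like signal channel with sparse diffraction-limited dots
#' concentrated in a cytoplasmic annulus around the nuclei of expressing
#' ("positive") cells, isolated background dots, and optional fused-clump
#' artifacts. Defaults describe a hippocampus-like wild-type section in
#' which roughly one cell in five expresses the target at a handful of
#' transcripts per cell.
#'
#' @param image_shape `(rows, cols)` in pixels.
#' @param pixel_size micrometres per pixel (default 0.325, a typical 20x
#'   camera sampling).
#' @param n_nuclei number of nuclei to place (rejection-sampled so that
#'   nuclei never overlap).
#' @param nucleus_radius `(min, max)` nucleus radius in pixels.
#' @param positive_fraction probability that a cell expresses the target.
#' @param dots_per_positive_cell list with `family` (`"poisson"` or
#'   `"gamma-poisson"`), `mean`, and for gamma-poisson a `dispersion`
#'   (variance = mean + dispersion * mean^2).
#' @param dot_peak_intensity `(mean, sd)` of the Gaussian peak amplitude of
#'   one dot, in intensity units above the local background.
#' @param psf_sigma point-spread-function sigma in pixels (dots are
#'   rendered as 2-D Gaussians; default 1.1 px).
#' @param background_level mean background (offset) intensity of both
#'   channels.
#' @param background_noise_sd additive Gaussian read-noise sd.
#' @param background_dot_rate expected number of isolated, nucleus-free
#'   false dots per square millimetre (the knockout-like background).
#' @param clump_prob probability that a positive cell's dots fuse into a
#'   single blob (all its dots collapsed onto one centre with sub-pixel
#'   jitter), emulating the signal-accumulation artifact of enzymatic
#'   amplification.
#' @param min_dot_separation_px dot centres are rejection-sampled to keep
#'   at least this distance apart. The default (7 px) is the
#'   component-level resolvability limit under the default optics: dots
#'   closer than this render as one fused above-threshold component (the
#'   summed Gaussian tails of nearby dots exceed the detection threshold
#'   at the saddle), i.e. a clump -- which the generator models explicitly
#'   through `clump_prob` instead of by accidental coincidence. Set to 0
#'   to allow arbitrary overlap.
#' @param annulus dot placement annulus around the owner nucleus centroid,
#'   as multiples of the nucleus radius (default `c(0.5, 1.8)`:
#'   perinuclear/cytoplasmic placement). Dots are additionally constrained
#'   to the owner's territory: the owner's nucleus must be the nearest by
#'   boundary distance (distance to centre minus radius), reflecting that
#'   in space-filling tissue the cytoplasm hosting a transcript belongs to
#'   the cell whose nucleus is closest.
#' @param nucleus_intensity mean added intensity of a nucleus disk in the
#'   nuclear channel.
#' @param bit_depth image bit depth; intensities are clipped (not wrapped)
#'   to `[0, 2^bit_depth - 1]`.
#' @param seed integer seed; the same seed reproduces the field exactly.
#' @return object of class `sim_params` (a validated list).
#' @export
sim_params <- function(image_shape = c(640L, 640L), pixel_size = 0.325,
                       n_nuclei = 200L, nucleus_radius = c(9, 12),
                       positive_fraction = 0.2,
                       dots_per_positive_cell = list(family = "poisson",
                                                     mean = 5,
                                                     dispersion = NULL),
                       dot_peak_intensity = c(mean = 1500, sd = 200),
                       psf_sigma = 1.1, background_level = 500,
                       background_noise_sd = 50, background_dot_rate = 75,
                       clump_prob = 0, min_dot_separation_px = 7,
                       annulus = c(0.5, 1.8), nucleus_intensity = 3000,
                       bit_depth = 16L, seed = NULL) {
  p <- list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
            n_nuclei = as.integer(n_nuclei), nucleus_radius = nucleus_radius,
            positive_fraction = positive_fraction,
            dots_per_positive_cell = dots_per_positive_cell,
            dot_peak_intensity = dot_peak_intensity, psf_sigma = psf_sigma,
            background_level = background_level,
            background_noise_sd = background_noise_sd,
            background_dot_rate = background_dot_rate,
            clump_prob = clump_prob,
            min_dot_separation_px = min_dot_separation_px,
            annulus = annulus, nucleus_intensity = nucleus_intensity,
            bit_depth = as.integer(bit_depth), seed = seed)
  stopifnot(length(p$image_shape) == 2L, all(p$image_shape >= 16L),
            p$pixel_size > 0, p$n_nuclei >= 0L,
            length(p$nucleus_radius) == 2L,
            p$nucleus_radius[1L] > 0, diff(p$nucleus_radius) >= 0,
            p$positive_fraction >= 0, p$positive_fraction <= 1,
            p$dots_per_positive_cell$family %in% c("poisson", "gamma-poisson"),
            p$dots_per_positive_cell$mean >= 0,
            p$dot_peak_intensity[["mean"]] >= 0, p$psf_sigma > 0,
            p$background_noise_sd >= 0, p$background_dot_rate >= 0,
            p$clump_prob >= 0, p$clump_prob <= 1,
            length(p$annulus) == 2L, p$annulus[1L] >= 0,
            diff(p$annulus) >= 0, p$bit_depth %in% c(8L, 16L))
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters:\n")
  cat(sprintf("  field %d x %d px (%.3f um/px, %.4f mm^2)\n",
              x$image_shape[1L], x$image_shape[2L], x$pixel_size,
              field_area_mm2(x)))
  cat(sprintf("  %d nuclei, radius %.1f-%.1f px; positive fraction %.2f\n",
              x$n_nuclei, x$nucleus_radius[1L], x$nucleus_radius[2L],
              x$positive_fraction))
  cat(sprintf("  dots/positive cell ~ %s(mean %.1f); background %.0f dots/mm^2; clump prob %.2f\n",
              x$dots_per_positive_cell$family, x$dots_per_positive_cell$mean,
              x$background_dot_rate, x$clump_prob))
  invisible(x)
}

#' Field area in square millimetres
#' @param params a [sim_params()] object (or any list with `image_shape`
#'   and `pixel_size`).
#' @return area in mm^2.
#' @export
field_area_mm2 <- function(params) {
  prod(params$image_shape) * (params$pixel_size / 1000)^2
}

# rejection-sample non-overlapping nucleus centres; coordinates 1-based
place_nuclei <- function(params) {
  n <- params$n_nuclei
  if (n == 0L)
    return(data.frame(label = integer(), row = numeric(), col = numeric(),
                      radius = numeric()))
  sh <- params$image_shape
  rows <- cols <- rads <- numeric(n)
  margin <- 2  # minimum clearance between nucleus borders, px
  placed <- 0L
  tries <- 0L
  max_tries <- 400L * n
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", n, " non-overlapping nuclei; ",
           "reduce n_nuclei or nucleus_radius, or enlarge the field")
    r <- stats::runif(1L, params$nucleus_radius[1L], params$nucleus_radius[2L])
    y <- stats::runif(1L, r + 1, sh[1L] - r)
    x <- stats::runif(1L, r + 1, sh[2L] - r)
    if (placed > 0L) {
      d2 <- (rows[seq_len(placed)] - y)^2 + (cols[seq_len(placed)] - x)^2
      if (any(d2 < (rads[seq_len(placed)] + r + margin)^2)) next
    }
    placed <- placed + 1L
    rows[placed] <- y; cols[placed] <- x; rads[placed] <- r
  }
  data.frame(label = seq_len(n), row = rows, col = cols, radius = rads)
}

draw_dot_counts <- function(k, spec) {
  if (k == 0L) return(integer(0L))
  if (spec$family == "poisson") {
    stats::rpois(k, spec$mean)
  } else {
    disp <- spec$dispersion
    if (is.null(disp) || disp <= 0)
      stop("gamma-poisson requires a positive dispersion")
    stats::rnbinom(k, mu = spec$mean, size = 1 / disp)
  }
}

# add a 2-D Gaussian of amplitude `amp` and sigma `sg` at (r0, c0)
add_gaussian_dot <- function(img, r0, c0, amp, sg) {
  w <- ceiling(4 * sg)
  rr <- max(1L, floor(r0 - w)):min(nrow(img), ceiling(r0 + w))
  cc <- max(1L, floor(c0 - w)):min(ncol(img), ceiling(c0 + w))
  if (length(rr) == 0L || length(cc) == 0L) return(img)
  g <- exp(-outer((rr - r0)^2, (cc - c0)^2, "+") / (2 * sg^2))
  img[rr, cc] <- img[rr, cc] + amp * g
  img
}

respects_separation <- function(r, c, rows, cols, minsep) {
  length(rows) == 0L || all((rows - r)^2 + (cols - c)^2 >= minsep^2)
}

#' Simulate a two-channel field with ground truth
#'
#' Generates a nuclear channel (non-overlapping smoothed disks plus Gaussian
#' read noise) and a signal channel (Gaussian-PSF dots placed in a
#' cytoplasmic annulus around the nuclei of positive cells, plus uniformly
#' scattered unowned background dots, plus noise), together with the exact
#' ground truth used to generate them. Intensities are clipped to the dtype
#' range (no wrap-around). With a fixed `seed` the output is bit-identical
#' across runs.
#'
#' @param params a [sim_params()] object.
#' @return list of class `sim_field` with elements
#'   \describe{
#'     \item{nuclear, signal}{numeric matrices (integer-valued intensities).}
#'     \item{truth}{class `ground_truth`: `nuclei` (label, row, col, radius),
#'       `per_cell_true_count` (named by label), `dots`
#'       (row, col, owner; `owner` is `NA` for background dots), and
#'       `positive` (logical per nucleus: was the cell drawn as expressing).}
#'     \item{params}{the parameters used.}
#'   }
#' @export
#' @examples
#' fld <- simulate_field(sim_params(image_shape = c(128, 128), n_nuclei = 12,
#'                                  seed = 1))
#' fld$truth$per_cell_true_count
simulate_field <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  sh <- params$image_shape

  nuc <- place_nuclei(params)
  n <- nrow(nuc)

  # --- expression truth ---------------------------------------------------
  positive <- stats::runif(n) < params$positive_fraction
  counts <- integer(n)
  counts[positive] <- draw_dot_counts(sum(positive),
                                      params$dots_per_positive_cell)

  minsep <- params$min_dot_separation_px
  dot_r <- numeric(0L); dot_c <- numeric(0L); dot_owner <- integer(0L)
  for (i in which(counts > 0L)) {
    for (d in seq_len(counts[i])) {
      ok <- FALSE
      for (try in seq_len(2000L)) {
        rad <- stats::runif(1L, params$annulus[1L], params$annulus[2L]) *
          nuc$radius[i]
        th <- stats::runif(1L, 0, 2 * pi)
        r0 <- nuc$row[i] + rad * sin(th)
        c0 <- nuc$col[i] + rad * cos(th)
        if (r0 < 1 || r0 > sh[1L] || c0 < 1 || c0 > sh[2L]) next
        # cytoplasmic territory: the owner must be the nearest nucleus by
        # boundary distance (additively weighted Voronoi)
        if (n > 1L &&
            which.min(sqrt((nuc$row - r0)^2 + (nuc$col - c0)^2) -
                        nuc$radius) != i) next
        if (minsep > 0 &&
            !respects_separation(r0, c0, dot_r, dot_c, minsep)) next
        ok <- TRUE; break
      }
      if (!ok)
        stop("could not place a dot satisfying min_dot_separation_px; ",
             "reduce dot density or the separation constraint")
      dot_r <- c(dot_r, r0); dot_c <- c(dot_c, c0)
      dot_owner <- c(dot_owner, nuc$label[i])
    }
  }

  # clump artifact: collapse a positive cell's dots onto one centre
  if (params$clump_prob > 0 && length(dot_owner) > 0L) {
    for (i in which(counts > 1L)) {
      if (stats::runif(1L) < params$clump_prob) {
        idx <- which(dot_owner == nuc$label[i])
        jit_r <- stats::runif(length(idx), -0.5, 0.5)
        jit_c <- stats::runif(length(idx), -0.5, 0.5)
        dot_r[idx] <- dot_r[idx][1L] + jit_r
        dot_c[idx] <- dot_c[idx][1L] + jit_c
      }
    }
  }

  # unowned background dots, spatially uniform
  n_bg <- stats::rpois(1L, params$background_dot_rate * field_area_mm2(params))
  bg_r <- numeric(0L); bg_c <- numeric(0L)
  for (d in seq_len(n_bg)) {
    ok <- FALSE
    for (try in seq_len(2000L)) {
      r0 <- stats::runif(1L, 1, sh[1L]); c0 <- stats::runif(1L, 1, sh[2L])
      if (minsep > 0 &&
          !respects_separation(r0, c0, c(dot_r, bg_r), c(dot_c, bg_c),
                               minsep)) next
      ok <- TRUE; break
    }
    if (!ok) stop("could not place a background dot under min_dot_separation_px")
    bg_r <- c(bg_r, r0); bg_c <- c(bg_c, c0)
  }

  dots <- data.frame(row = c(dot_r, bg_r), col = c(dot_c, bg_c),
                     owner = c(dot_owner, rep(NA_integer_, n_bg)))

  # --- render nuclear channel --------------------------------------------
  nuclear <- matrix(0, sh[1L], sh[2L])
  if (n > 0L) {
    bright <- stats::runif(n, 0.8, 1.2) * params$nucleus_intensity
    for (i in seq_len(n)) {
      r <- nuc$radius[i]
      rr <- max(1L, floor(nuc$row[i] - r)):min(sh[1L], ceiling(nuc$row[i] + r))
      cc <- max(1L, floor(nuc$col[i] - r)):min(sh[2L], ceiling(nuc$col[i] + r))
      disk <- outer((rr - nuc$row[i])^2, (cc - nuc$col[i])^2, "+") <= r^2
      nuclear[rr, cc] <- nuclear[rr, cc] + bright[i] * disk
    }
    nuclear <- as.matrix(EBImage::gblur(nuclear, sigma = 1))
  }
  nuclear <- nuclear + params$background_level +
    stats::rnorm(length(nuclear), 0, params$background_noise_sd)

  # --- render signal channel ---------------------------------------------
  signal <- matrix(0, sh[1L], sh[2L])
  if (nrow(dots) > 0L) {
    amp <- pmax(0, stats::rnorm(nrow(dots), params$dot_peak_intensity[["mean"]],
                                params$dot_peak_intensity[["sd"]]))
    for (d in seq_len(nrow(dots)))
      signal <- add_gaussian_dot(signal, dots$row[d], dots$col[d],
                                 amp[d], params$psf_sigma)
  }
  signal <- signal + params$background_level +
    stats::rnorm(length(signal), 0, params$background_noise_sd)

  top <- 2^params$bit_depth - 1
  nuclear <- round(pmin(pmax(nuclear, 0), top))
  signal <- round(pmin(pmax(signal, 0), top))

  per_cell <- stats::setNames(counts, as.character(nuc$label))
  truth <- structure(list(nuclei = nuc, per_cell_true_count = per_cell,
                          dots = dots, positive = positive),
                     class = "ground_truth")
  structure(list(nuclear = nuclear, signal = signal, truth = truth,
                 params = params),
            class = "sim_field")
}

#' Simulate a negative-control (knockout-like) field
#'
#' Convenience wrapper around [simulate_field()] forcing
#' `positive_fraction = 0`, so the signal channel contains only the isolated
#' unowned background dots characteristic of sections genetically lacking
#' the target: background that consists mainly of single dots per cell.
#'
#' @param params a [sim_params()] object; its `positive_fraction` is ignored.
#' @return a `sim_field`, as [simulate_field()].
#' @export
simulate_negative_control <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  params$positive_fraction <- 0
  simulate_field(params)
}

#' @export
print.sim_field <- function(x, ...) {
  tr <- x$truth
  cat(sprintf("Simulated field %d x %d px: %d nuclei, %d dots (%d owned, %d background)\n",
              nrow(x$nuclear), ncol(x$nuclear), nrow(tr$nuclei),
              nrow(tr$dots), sum(!is.na(tr$dots$owner)),
              sum(is.na(tr$dots$owner))))
  invisible(x)
}

#' Write a simulated field to disk
#'
#' Writes a two-page 16-bit grayscale TIFF (page 1 nuclear, page 2 signal),
#' the ground truth as JSON, and the per-cell true counts as CSV.
#'
#' @param field a `sim_field`.
#' @param dir output directory (created if needed).
#' @param name file stem, default `"field"`.
#' @return named character vector of the files written, invisibly.
#' @export
write_field <- function(field, dir, name = "field") {
  stopifnot(inherits(field, "sim_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  top <- 2^field$params$bit_depth - 1
  tif <- file.path(dir, paste0(name, ".tif"))
  tiff::writeTIFF(list(field$nuclear / top, field$signal / top), tif,
                  bits.per.sample = field$params$bit_depth)
  tr <- field$truth
  js <- file.path(dir, paste0(name, "_truth.json"))
  jsonlite::write_json(list(nuclei = tr$nuclei,
                            per_cell_true_count = as.list(tr$per_cell_true_count),
                            dots = tr$dots, positive = tr$positive),
                       js, auto_unbox = TRUE, digits = NA, na = "null")
  csv <- file.path(dir, paste0(name, "_per_cell_truth.csv"))
  utils::write.csv(data.frame(nucleus_label = tr$nuclei$label,
                              true_count = as.integer(tr$per_cell_true_count)),
                   csv, row.names = FALSE)
  invisible(c(tiff = tif, truth_json = js, per_cell_csv = csv))
}

#' Read a one- or two-page TIFF as intensity matrices
#'
#' @param path TIFF file.
#' @param bit_depth bit depth used to rescale the stored `[0, 1]` samples
#'   back to integer intensities (default 16).
#' @return list of numeric matrices, one per page.
#' @export
read_image_tiff <- function(path, bit_depth = 16L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) round(p * (2^bit_depth - 1)))
}
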