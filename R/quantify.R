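# 8-connected labelling built on EBImage's 4-connected bwlabel: merge label
# pairs that touch diagonally (union-find over the label graph).
label_components <- function(mask, connectivity = 8L) {
  lb <- as.matrix(EBImage::bwlabel(mask))
  if (connectivity == 4L || max(lb) < 2L) return(lb)
  nr <- nrow(lb); nc <- ncol(lb)
  pairs <- rbind(
    cbind(as.vector(lb[-nr, -nc]), as.vector(lb[-1L, -1L])),   # down-right
    cbind(as.vector(lb[-nr, -1L]), as.vector(lb[-1L, -nc])))   # down-left
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (nrow(pairs) == 0L) return(lb)
  parent <- seq_len(max(lb))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1L]); b <- find(pairs[k, 2L])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_along(parent), find, integer(1L))
  relab <- match(root, sort(unique(root)))
  out <- lb
  out[lb > 0L] <- relab[lb[lb > 0L]]
  out
}

component_stats <- function(label_mask, intensity = NULL) {
  idx <- which(label_mask > 0L)
  if (length(idx) == 0L)
    return(data.frame(label = integer(), row = numeric(), col = numeric(),
                      area = integer(), eq_diameter = numeric(),
                      mean_intensity = numeric()))
  lab <- label_mask[idx]
  rr <- (idx - 1L) %% nrow(label_mask) + 1L
  cc <- (idx - 1L) %/% nrow(label_mask) + 1L
  area <- tabulate(lab)
  keep <- which(area > 0L)
  df <- data.frame(
    label = keep,
    row = vapply(split(rr, lab), mean, 0)[as.character(keep)],
    col = vapply(split(cc, lab), mean, 0)[as.character(keep)],
    area = area[keep])
  df$eq_diameter <- 2 * sqrt(df$area / pi)
  df$mean_intensity <- if (is.null(intensity)) NA_real_ else
    vapply(split(intensity[idx], lab), mean, 0)[as.character(keep)]
  rownames(df) <- NULL
  df
}

#' Segment nuclei from a nuclear-stain channel
#'
#' Deterministic classical segmentation: Gaussian smoothing, global Otsu
#' threshold, hole filling, splitting of touching objects by watershed on
#' the distance transform, then an area filter. Intended for DAPI-like
#' images of well-separated, near-circular nuclei.
#'
#' @param img single-channel 2-D numeric matrix.
#' @param min_area_px,max_area_px retain objects with area (px) in this
#'   range.
#' @param smoothing_sigma Gaussian pre-smoothing sigma in px.
#' @param watershed_tolerance minimum distance-transform depth (px) between
#'   two objects for the watershed to split them; raises robustness against
#'   noise-induced oversplitting.
#' @return object of class `nucleus_set`: list with `label_mask` (integer
#'   matrix, 0 = background, labels consecutive from 1) and `nuclei`
#'   (data.frame: `label`, centroid `row`/`col`, `area`, `eq_diameter`).
#'   An empty or constant image yields zero nuclei with a warning.
#' @export
segment_nuclei <- function(img, min_area_px = 30, max_area_px = Inf,
                           smoothing_sigma = 2, watershed_tolerance = 1) {
  stopifnot(is.matrix(img))
  empty <- function() {
    structure(list(label_mask = matrix(0L, nrow(img), ncol(img)),
                   nuclei = component_stats(matrix(0L, 1L, 1L))),
              class = "nucleus_set")
  }
  rng <- range(img)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    warning("nuclear channel is constant; returning an empty nucleus set")
    return(empty())
  }
  x <- (img - rng[1L]) / diff(rng)
  if (smoothing_sigma > 0) x <- as.matrix(EBImage::gblur(x, smoothing_sigma))
  th <- EBImage::otsu(EBImage::Image(x))
  mask <- EBImage::fillHull(x > th)
  dm <- EBImage::distmap(mask)
  lb <- as.matrix(EBImage::watershed(dm, tolerance = watershed_tolerance,
                                     ext = 1L))
  st <- component_stats(lb)
  st <- st[st$area >= min_area_px & st$area <= max_area_px, , drop = FALSE]
  if (nrow(st) == 0L) {
    warning("no nuclei found")
    return(empty())
  }
  # relabel consecutively
  relab <- match(lb, c(0L, st$label)) - 1L
  relab[is.na(relab)] <- 0L
  lbm <- matrix(as.integer(relab), nrow(img), ncol(img))
  st$label <- seq_len(nrow(st))
  rownames(st) <- NULL
  structure(list(label_mask = lbm,
                 nuclei = st[, c("label", "row", "col", "area",
                                 "eq_diameter")]),
            class = "nucleus_set")
}

#' @export
print.nucleus_set <- function(x, ...) {
  cat(sprintf("Nucleus set: %d nuclei (mean area %.1f px)\n",
              nrow(x$nuclei),
              if (nrow(x$nuclei)) mean(x$nuclei$area) else NA))
  invisible(x)
}

#' Calibrate detection thresholds from negative-control images
#'
#' The detection intensity threshold is derived from the signal channel of
#' negative-control (knockout-like) sections, in which any residual signal
#' defines background: by default `threshold = mean + k_sigma * sd` over all
#' pooled control pixels (alternatively a background quantile). The dot
#' diameter threshold defaults to a fixed 3 px (equivalent-circle diameter);
#' when wild-type images are supplied, the mean dot diameter observed in
#' them is recorded, and with `diameter_mode = "wt-derived"` the diameter
#' threshold becomes `floor(wt_mean_dot_diameter * wt_diameter_fraction)`.
#'
#' @param ko_images list of negative-control signal-channel matrices
#'   (at least one; calibration requires a negative control).
#' @param wt_images optional list of wild-type signal-channel matrices.
#' @param k_sigma multiplier on the background sd (default 3).
#' @param fixed_diameter_px fixed diameter threshold in px (default 3).
#' @param diameter_mode `"fixed"` or `"wt-derived"`.
#' @param wt_diameter_fraction fraction of the wild-type mean dot diameter
#'   used in `"wt-derived"` mode (default 0.5).
#' @param background_stat `"whole-image"` (default; statistics over all
#'   control pixels) or `"quantile"` (threshold = the `quantile_p` quantile
#'   of control pixels).
#' @param quantile_p background quantile for `background_stat = "quantile"`.
#' @return object of class `calibration_result` with fields
#'   `intensity_threshold`, `diameter_threshold_px`, `ko_background_mean`,
#'   `ko_background_sd`, `wt_mean_dot_diameter`, `k_sigma`,
#'   `background_stat`, `diameter_mode`, `n_ko_images`, `n_wt_images`.
#' @export
calibrate <- function(ko_images, wt_images = NULL, k_sigma = 3,
                      fixed_diameter_px = 3,
                      diameter_mode = c("fixed", "wt-derived"),
                      wt_diameter_fraction = 0.5,
                      background_stat = c("whole-image", "quantile"),
                      quantile_p = 0.999) {
  diameter_mode <- match.arg(diameter_mode)
  background_stat <- match.arg(background_stat)
  if (is.matrix(ko_images)) ko_images <- list(ko_images)
  if (is.matrix(wt_images)) wt_images <- list(wt_images)
  if (length(ko_images) == 0L)
    stop("calibration requires a negative control: supply at least one KO image")
  stopifnot(k_sigma >= 0, fixed_diameter_px > 0)
  px <- unlist(lapply(ko_images, as.vector), use.names = FALSE)
  mu <- mean(px); sd0 <- stats::sd(px)
  thr <- if (background_stat == "whole-image") mu + k_sigma * sd0
         else unname(stats::quantile(px, quantile_p))
  wt_diam <- NA_real_
  if (length(wt_images) > 0L) {
    diams <- unlist(lapply(wt_images, function(w) {
      lb <- label_components(w > thr, 8L)
      component_stats(lb)$eq_diameter
    }))
    if (length(diams) > 0L) wt_diam <- mean(diams)
  }
  diam_thr <- fixed_diameter_px
  if (diameter_mode == "wt-derived") {
    if (is.na(wt_diam))
      stop("diameter_mode = 'wt-derived' needs wild-type images with detectable dots")
    diam_thr <- max(1, floor(wt_diam * wt_diameter_fraction))
  }
  structure(list(intensity_threshold = thr, diameter_threshold_px = diam_thr,
                 ko_background_mean = mu, ko_background_sd = sd0,
                 wt_mean_dot_diameter = wt_diam, k_sigma = k_sigma,
                 background_stat = background_stat,
                 diameter_mode = diameter_mode,
                 n_ko_images = length(ko_images),
                 n_wt_images = length(wt_images)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Calibration (negative-control derived):\n")
  cat(sprintf("  intensity threshold %.2f  [KO background %.2f +/- %.2f, k = %g, %s]\n",
              x$intensity_threshold, x$ko_background_mean,
              x$ko_background_sd, x$k_sigma, x$background_stat))
  cat(sprintf("  diameter threshold  %g px (%s)", x$diameter_threshold_px,
              x$diameter_mode))
  if (!is.na(x$wt_mean_dot_diameter))
    cat(sprintf("; WT mean dot diameter %.2f px", x$wt_mean_dot_diameter))
  cat("\n")
  invisible(x)
}

#' Detect dots in a signal channel
#'
#' Applies a small median prefilter (which suppresses isolated noise pixels
#' that would otherwise bridge nearby dots, while leaving the smooth dot
#' peaks untouched), binarizes at the calibrated intensity threshold,
#' labels connected components (8-connectivity by default) and retains
#' components whose equivalent-circle diameter `2 * sqrt(area / pi)` is at
#' least the calibrated diameter threshold. Component intensities are
#' reported from the unfiltered image. With `declump = TRUE`, components larger
#' than `max_single_dot_area_px` are split by a watershed on local intensity
#' maxima and each fragment is re-tested against the diameter threshold, so
#' fused signal accumulations are counted as their constituent dots.
#' Deterministic.
#'
#' @param signal numeric matrix (signal channel).
#' @param cal a [calibrate()] result.
#' @param connectivity 4 or 8 (default 8).
#' @param median_radius radius of the median prefilter in px (0 disables
#'   it; default 1, i.e. a 3 x 3 window).
#' @param declump split oversized components? Default `FALSE`.
#' @param max_single_dot_area_px area (px) above which a component is
#'   considered a clump when `declump = TRUE`. Default `4 * pi *
#'   (2 * psf_sigma)^2` is sensible for Gaussian dots; required when
#'   declumping.
#' @param watershed_tolerance intensity depth (same units as `signal`)
#'   required between two local maxima for the declumping watershed to
#'   split them.
#' @return data.frame of class `dot_set`: `row`, `col` (centroid), `area`,
#'   `eq_diameter`, `mean_intensity`, plus `assigned_label` and
#'   `distance_to_nucleus` initialised to `NA` (filled by [assign_dots()]).
#' @export
detect_dots <- function(signal, cal, connectivity = 8L, median_radius = 1L,
                        declump = FALSE, max_single_dot_area_px = NULL,
                        watershed_tolerance = NULL) {
  stopifnot(is.matrix(signal), inherits(cal, "calibration_result"),
            connectivity %in% c(4L, 8L), median_radius >= 0L)
  work <- signal
  if (median_radius > 0L) {
    top <- max(signal, 1)
    work <- as.matrix(EBImage::medianFilter(signal / top,
                                            size = median_radius)) * top
  }
  mask <- work > cal$intensity_threshold
  lb <- label_components(mask, connectivity)
  st <- component_stats(lb, signal)
  if (declump && nrow(st) > 0L) {
    if (is.null(max_single_dot_area_px))
      stop("declump = TRUE requires max_single_dot_area_px")
    if (is.null(watershed_tolerance))
      watershed_tolerance <- cal$ko_background_sd
    big <- st$label[st$area > max_single_dot_area_px]
    if (length(big) > 0L) {
      frags <- list()
      for (b in big) {
        sub <- matrix(0, nrow(signal), ncol(signal))
        inb <- lb == b
        sub[inb] <- work[inb] - cal$intensity_threshold
        wl <- as.matrix(EBImage::watershed(sub,
                                           tolerance = watershed_tolerance,
                                           ext = 1L))
        frags[[length(frags) + 1L]] <- component_stats(wl, signal)
      }
      st <- rbind(st[!(st$label %in% big), , drop = FALSE],
                  do.call(rbind, frags))
    }
  }
  st <- st[st$eq_diameter >= cal$diameter_threshold_px, , drop = FALSE]
  st$label <- NULL
  st$assigned_label <- rep(NA_integer_, nrow(st))
  st$distance_to_nucleus <- rep(NA_real_, nrow(st))
  rownames(st) <- NULL
  class(st) <- c("dot_set", "data.frame")
  st
}

# boundary pixels of each labelled object: any object pixel with a
# non-object 8-neighbour (or lying on the image edge). For a filled object
# the nearest object pixel to any exterior point is one of these.
boundary_pixels <- function(label_mask) {
  nr <- nrow(label_mask); nc <- ncol(label_mask)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- label_mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  is_bnd <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
    is_bnd <- is_bnd | (core > 0L & nb != core)
  }
  idx <- which(is_bnd)
  data.frame(row = (idx - 1L) %% nr + 1L, col = (idx - 1L) %/% nr + 1L,
             label = core[idx])
}

nearest_nucleus <- function(r, c, px, max_distance_px) {
  d2 <- (px$row - r)^2 + (px$col - c)^2
  dmin <- min(d2)
  cand <- px$label[d2 == dmin]        # exact ties -> lowest label
  d <- sqrt(dmin)
  if (d > max_distance_px) c(NA_real_, d) else c(min(cand), d)
}

#' Assign detected dots to the closest nucleus
#'
#' Each dot is assigned to the nucleus minimizing the Euclidean distance
#' from the dot centroid to the nucleus mask (0 when the centroid lies
#' inside the mask; otherwise the distance to the nearest mask pixel
#' centre). Dots farther than `max_distance_px` from every nucleus remain
#' unassigned; exact distance ties are broken by the lowest nucleus label.
#'
#' The default method searches only object boundary pixels, which is exact
#' for filled masks; `method = "bruteforce"` searches every mask pixel and
#' serves as the reference implementation.
#'
#' @param dots a [detect_dots()] result.
#' @param nuclei a [segment_nuclei()] result.
#' @param max_distance_px maximum assignment distance in px (default 30,
#'   about one cell diameter; an unlimited radius would attach far-field
#'   background dots to cells).
#' @param method `"boundary"` (default) or `"bruteforce"`.
#' @return `dots` with `assigned_label` and `distance_to_nucleus` filled
#'   (label `NA` for unassigned dots). Zero nuclei leaves all dots
#'   unassigned, with a warning.
#' @export
assign_dots <- function(dots, nuclei, max_distance_px = 30,
                        method = c("boundary", "bruteforce")) {
  method <- match.arg(method)
  stopifnot(inherits(nuclei, "nucleus_set"), max_distance_px >= 0)
  if (nrow(dots) == 0L) return(dots)
  lbm <- nuclei$label_mask
  if (nrow(nuclei$nuclei) == 0L) {
    warning("no nuclei: all dots left unassigned")
    dots$assigned_label <- NA_integer_
    dots$distance_to_nucleus <- NA_real_
    return(dots)
  }
  px <- if (method == "boundary") boundary_pixels(lbm) else {
    idx <- which(lbm > 0L)
    data.frame(row = (idx - 1L) %% nrow(lbm) + 1L,
               col = (idx - 1L) %/% nrow(lbm) + 1L, label = lbm[idx])
  }
  for (i in seq_len(nrow(dots))) {
    ri <- min(max(round(dots$row[i]), 1L), nrow(lbm))
    ci <- min(max(round(dots$col[i]), 1L), ncol(lbm))
    inside <- lbm[ri, ci]
    if (inside > 0L) {
      dots$assigned_label[i] <- inside
      dots$distance_to_nucleus[i] <- 0
    } else {
      nn <- nearest_nucleus(dots$row[i], dots$col[i], px, max_distance_px)
      dots$assigned_label[i] <- as.integer(nn[1L])
      dots$distance_to_nucleus[i] <- nn[2L]
    }
  }
  dots
}

#' Per-cell and per-region semi-quantitative metrics
#'
#' Computes the three region metrics of the single-pair probe workflow --
#' dots per area (all detected dots, assigned or not, over the field area),
#' percentage of positive cells (a cell is positive when it carries at
#' least `positive_min_dots` assigned dots), and mean dots per positive
#' cell -- together with the per-cell count table and the histogram of dots
#' per positive cell (bins 1..B, last bin open-ended).
#'
#' @param dots an [assign_dots()] result.
#' @param nuclei a [segment_nuclei()] result.
#' @param field_area_mm2 imaged area in mm^2 (full frame; see
#'   [field_area_mm2()]).
#' @param positive_min_dots minimum assigned dots for a cell to count as
#'   positive (default 1).
#' @param histogram_max_bin last histogram bin B; cells with >= B dots are
#'   pooled there (default 15).
#' @return object of class `cell_quant`: list with `per_cell` (data.frame
#'   `nucleus_label`, `dot_count`), `metrics` (list: `n_nuclei`,
#'   `n_dots_detected`, `n_dots_assigned`, `dots_per_area_mm2`,
#'   `pct_positive_cells`, `mean_dots_per_positive_cell`) and `histogram`
#'   (named integer vector over bins `1..B`). With zero nuclei the
#'   cell-level metrics are `NA` (undefined, not 0).
#' @export
quantify_region <- function(dots, nuclei, field_area_mm2,
                            positive_min_dots = 1L, histogram_max_bin = 15L) {
  stopifnot(inherits(nuclei, "nucleus_set"), field_area_mm2 > 0,
            positive_min_dots >= 1L, histogram_max_bin >= 1L)
  n_nuc <- nrow(nuclei$nuclei)
  n_dots <- nrow(dots)
  assigned <- dots$assigned_label[!is.na(dots$assigned_label)]
  per_cell <- data.frame(nucleus_label = nuclei$nuclei$label,
                         dot_count = integer(n_nuc))
  if (length(assigned) > 0L && n_nuc > 0L) {
    tb <- table(factor(assigned, levels = per_cell$nucleus_label))
    per_cell$dot_count <- as.integer(tb)
  }
  B <- histogram_max_bin
  if (n_nuc == 0L) {
    warning("zero nuclei: cell-level metrics are undefined")
    metrics <- list(n_nuclei = 0L, n_dots_detected = n_dots,
                    n_dots_assigned = length(assigned),
                    dots_per_area_mm2 = n_dots / field_area_mm2,
                    pct_positive_cells = NA_real_,
                    mean_dots_per_positive_cell = NA_real_)
    hist <- stats::setNames(integer(B), seq_len(B))
  } else {
    pos <- per_cell$dot_count >= positive_min_dots
    metrics <- list(
      n_nuclei = n_nuc, n_dots_detected = n_dots,
      n_dots_assigned = length(assigned),
      dots_per_area_mm2 = n_dots / field_area_mm2,
      pct_positive_cells = 100 * sum(pos) / n_nuc,
      mean_dots_per_positive_cell =
        if (any(pos)) mean(per_cell$dot_count[pos]) else NA_real_)
    cnt <- pmin(per_cell$dot_count[pos], B)
    hist <- stats::setNames(tabulate(cnt, nbins = B), seq_len(B))
  }
  structure(list(per_cell = per_cell, metrics = metrics, histogram = hist,
                 positive_min_dots = positive_min_dots,
                 field_area_mm2 = field_area_mm2),
            class = "cell_quant")
}

#' @export
print.cell_quant <- function(x, ...) {
  m <- x$metrics
  cat("Region quantification:\n")
  cat(sprintf("  nuclei: %d; dots detected: %d (assigned: %d)\n",
              m$n_nuclei, m$n_dots_detected, m$n_dots_assigned))
  cat(sprintf("  dots/area: %.1f per mm^2\n", m$dots_per_area_mm2))
  cat(sprintf("  positive cells (>= %d dot%s): %s%%\n", x$positive_min_dots,
              if (x$positive_min_dots > 1L) "s" else "",
              format(round(m$pct_positive_cells, 2))))
  cat(sprintf("  mean dots/positive cell: %s\n",
              format(round(m$mean_dots_per_positive_cell, 3))))
  invisible(x)
}

#' Histogram plot of dots per positive cell
#'
#' @param x a [quantify_region()] result.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.cell_quant <- function(x, ...) {
  graphics::barplot(x$histogram, xlab = "dots per positive cell",
                    ylab = "cells", ...)
  invisible(x)
}
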