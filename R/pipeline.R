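#' Default run configuration
#'
#' All tunable parameters of the quantification pipeline with their
#' defaults. Unknown keys in a user configuration are rejected rather than
#' silently ignored, and every output file records the configuration hash,
#' so two runs with equal hashes are byte-identical.
#'
#' @return named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    pixel_size = 0.325,          # um per pixel
    nuclear_channel = 1L,        # TIFF page of the nuclear stain
    signal_channel = 2L,         # TIFF page of the FastRED-like signal
    k_sigma = 3,
    diameter_mode = "fixed",     # or "wt-derived"
    fixed_diameter_px = 3,
    wt_diameter_fraction = 0.5,
    background_stat = "whole-image",
    min_nucleus_area_px = 30,
    max_nucleus_area_px = Inf,
    smoothing_sigma = 2,
    connectivity = 8L,
    declump = FALSE,
    max_single_dot_area_px = 60,
    max_distance_px = 30,
    positive_min_dots = 1L,
    histogram_max_bin = 15L,
    seed = NULL,
    out_dir = "."), class = "run_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg, call. = FALSE)
  chk(cfg$pixel_size > 0, "pixel_size must be > 0")
  chk(cfg$k_sigma >= 0, "k_sigma must be >= 0")
  chk(cfg$fixed_diameter_px > 0, "fixed_diameter_px must be > 0")
  chk(cfg$diameter_mode %in% c("fixed", "wt-derived"),
      "diameter_mode must be 'fixed' or 'wt-derived'")
  chk(cfg$background_stat %in% c("whole-image", "quantile"),
      "background_stat must be 'whole-image' or 'quantile'")
  chk(cfg$connectivity %in% c(4L, 8L), "connectivity must be 4 or 8")
  chk(cfg$max_distance_px >= 0, "max_distance_px must be >= 0")
  chk(cfg$positive_min_dots >= 1, "positive_min_dots must be >= 1")
  chk(cfg$histogram_max_bin >= 1, "histogram_max_bin must be >= 1")
  cfg
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file, fills unset keys with [default_config()] values,
#' validates ranges and rejects unknown keys by name. An empty file yields
#' the defaults.
#'
#' @param path YAML file.
#' @return validated `run_config` list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(user)) cfg[[k]] <- user[[k]]
  int_keys <- c("nuclear_channel", "signal_channel", "connectivity",
                "positive_min_dots", "histogram_max_bin")
  for (k in int_keys) cfg[[k]] <- as.integer(cfg[[k]])
  validate_config(cfg)
}

#' Save a run configuration as YAML
#'
#' @param cfg a `run_config` list.
#' @param path output file.
#' @export
save_config <- function(cfg, path) {
  out <- unclass(cfg)
  out <- out[!vapply(out, is.null, TRUE)]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Configuration hash
#'
#' MD5 of the canonical YAML serialization; identical configurations hash
#' identically, and every pipeline output records this value.
#'
#' @param cfg a `run_config` list.
#' @return 32-character hex string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

as_channels <- function(x, cfg) {
  # accept a sim_field, a list of matrices (pages), or a TIFF path
  if (inherits(x, "sim_field"))
    return(list(nuclear = x$nuclear, signal = x$signal))
  if (is.character(x)) x <- read_image_tiff(x)
  if (is.matrix(x)) return(list(nuclear = NULL, signal = x))
  list(nuclear = x[[cfg$nuclear_channel]], signal = x[[cfg$signal_channel]])
}

quantify_one <- function(channels, cal, cfg) {
  nuclei <- segment_nuclei(channels$nuclear,
                           min_area_px = cfg$min_nucleus_area_px,
                           max_area_px = cfg$max_nucleus_area_px,
                           smoothing_sigma = cfg$smoothing_sigma)
  dots <- detect_dots(channels$signal, cal, connectivity = cfg$connectivity,
                      declump = cfg$declump,
                      max_single_dot_area_px = cfg$max_single_dot_area_px)
  dots <- assign_dots(dots, nuclei, max_distance_px = cfg$max_distance_px)
  area <- prod(dim(channels$signal)) * (cfg$pixel_size / 1000)^2
  quant <- quantify_region(dots, nuclei, area,
                           positive_min_dots = cfg$positive_min_dots,
                           histogram_max_bin = cfg$histogram_max_bin)
  list(nuclei = nuclei, dots = dots, quant = quant)
}

write_with_header <- function(df, path, hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full quantification pipeline
#'
#' End-to-end composition: calibrate from the negative-control images,
#' then, for every sample image, segment nuclei, detect dots, assign them
#' to the closest nucleus and quantify. Writes a calibration JSON, one
#' per-cell CSV per image, and a region-summary CSV; every CSV carries the
#' configuration hash in a comment header, so reruns with an identical
#' configuration (and seed, if the inputs are simulated) are byte-identical.
#'
#' @param config a `run_config` (see [default_config()], [load_config()]).
#' @param ko_images negative-control inputs: list of `sim_field` objects,
#'   two-page image lists, or TIFF paths. At least one is required.
#' @param sample_images sample inputs, same forms, named list (names become
#'   image ids).
#' @param out_dir output directory; `NULL` (default `config$out_dir`) or
#'   `NA` to skip writing.
#' @return list of class `ish_run`: `calibration`, `results` (per image:
#'   `nuclei`, `dots`, `quant`), `summary` (data.frame of region metrics
#'   per image), `config`, `config_hash`, `files`.
#' @export
run_pipeline <- function(config, ko_images, sample_images, out_dir = NULL) {
  config <- validate_config(config)
  if (inherits(ko_images, "sim_field") || is.matrix(ko_images) ||
      is.character(ko_images)) ko_images <- list(ko_images)
  if (inherits(sample_images, "sim_field") || is.matrix(sample_images) ||
      is.character(sample_images)) sample_images <- list(sample_images)
  if (length(ko_images) == 0L)
    stop("stage calibrate: calibration requires a negative control")
  if (length(sample_images) == 0L)
    stop("stage quantify: at least one sample image is required")
  if (is.null(names(sample_images)) || any(!nzchar(names(sample_images))))
    names(sample_images) <- sprintf("sample%02d", seq_along(sample_images))

  ko_ch <- lapply(ko_images, as_channels, cfg = config)
  cal <- tryCatch(
    calibrate(lapply(ko_ch, `[[`, "signal"), k_sigma = config$k_sigma,
              fixed_diameter_px = config$fixed_diameter_px,
              diameter_mode = config$diameter_mode,
              wt_diameter_fraction = config$wt_diameter_fraction,
              background_stat = config$background_stat),
    error = function(e) stop("stage calibrate: ", conditionMessage(e),
                             call. = FALSE))

  results <- lapply(names(sample_images), function(id) {
    tryCatch(quantify_one(as_channels(sample_images[[id]], config), cal,
                          config),
             error = function(e) stop("stage quantify [", id, "]: ",
                                      conditionMessage(e), call. = FALSE))
  })
  names(results) <- names(sample_images)

  summary_df <- do.call(rbind, lapply(names(results), function(id) {
    m <- results[[id]]$quant$metrics
    data.frame(image_id = id, n_nuclei = m$n_nuclei,
               n_dots = m$n_dots_detected, n_assigned = m$n_dots_assigned,
               dots_per_area_mm2 = m$dots_per_area_mm2,
               pct_positive_cells = m$pct_positive_cells,
               mean_dots_per_positive_cell = m$mean_dots_per_positive_cell)
  }))

  hash <- config_hash(config)
  files <- character(0L)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (!is.na(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    calf <- file.path(out_dir, "calibration.json")
    jsonlite::write_json(c(unclass(cal), list(config_hash = hash)), calf,
                         auto_unbox = TRUE, digits = NA, na = "null")
    files <- calf
    for (id in names(results)) {
      pc <- results[[id]]$quant$per_cell
      cents <- results[[id]]$nuclei$nuclei
      df <- data.frame(image_id = id, nucleus_label = pc$nucleus_label,
                       centroid_row = cents$row, centroid_col = cents$col,
                       dot_count = pc$dot_count)
      f <- file.path(out_dir, paste0("per_cell_", id, ".csv"))
      write_with_header(df, f, hash)
      files <- c(files, f)
    }
    f <- file.path(out_dir, "region_summary.csv")
    write_with_header(summary_df, f, hash)
    files <- c(files, f)
  }
  structure(list(calibration = cal, results = results, summary = summary_df,
                 config = config, config_hash = hash, files = files),
            class = "ish_run")
}

#' @export
print.ish_run <- function(x, ...) {
  cat("Single-pair probe ISH quantification run\n")
  print(x$calibration)
  cat("Per-image summary:\n")
  print.data.frame(format(x$summary, digits = 4), right = FALSE)
  invisible(x)
}
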