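#' Read a multi-page TIFF as an image stack
#'
#' @param path Path to a TIFF file.
#' @param axis `"z"` for a focal stack, `"t"` for a time series.
#' @param pixel_size um per pixel (metadata; TIFF tags are not parsed).
#' @param spacing Plane spacing (um) or frame interval (s).
#' @return An [image_stack()].
#' @export
read_stack <- function(path, axis = c("z", "t"), pixel_size = 0.16,
                       spacing = 0.2) {
  axis <- match.arg(axis)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      abort(sprintf("Cannot read '%s' as TIFF: %s", path,
                                    conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])[1]
    abort(sprintf("Page %d of '%s' has inconsistent dimensions.", bad, path))
  }
  if (length(pages) == 1L)
    warn(sprintf("'%s' has a single page; returning a depth-1 stack.", path))
  image_stack(lapply(pages, function(p) matrix(as.numeric(p), dims[1, 1])),
              pixel_size = pixel_size, z_spacing = spacing, axis = axis)
}

#' Write an image stack (or single image) as 16-bit multi-page TIFF
#'
#' Values are rounded and clamped to `[0, 65535]`; the round trip through
#' [read_stack()] is bit-exact for data already in that integer range.
#'
#' @param stack An [image_stack()] or a single numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  planes <- if (inherits(stack, "image_stack"))
    lapply(seq_len(n_planes(stack)), function(i) get_plane(stack, i))
  else list(as.matrix(stack))
  pages <- lapply(planes, function(p)
    pmin(pmax(round(p), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Write a per-cell counts table as CSV
#'
#' UTF-8, header row, '.' decimal separator; lengths in um with 3 decimals.
#'
#' @param counts Tibble with at least `cell_id` and `n_spots`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  out <- as.data.frame(counts[, setdiff(names(counts), "pixels")])
  for (nm in grep("_um$", names(out), value = TRUE))
    out[[nm]] <- sprintf("%.3f", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write simulation ground truth (CSV + optics JSON sidecar)
#'
#' @param truth Tibble with `cell_id`, `true_count`, `length_um`.
#' @param optics An [optics_config()].
#' @param csv_path Output CSV path; the JSON sidecar takes the same path with
#'   extension `.json`.
#' @return `csv_path`, invisibly.
#' @export
write_ground_truth <- function(truth, optics, csv_path) {
  write_counts(truth, csv_path)
  json_path <- sub("\\.[^.]*$", ".json", csv_path)
  jsonlite::write_json(unclass(optics), json_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(csv_path)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the counting pipeline in one nested list:
#' optics, segmentation, spot detection, photobleaching, undercounting
#' simulation, the newborn length cutoff and the RNG seed.
#'
#' @return Nested list of class `halocount_config`.
#' @export
halocount_config <- function() {
  structure(list(
    optics = list(pixel_size = 0.16, z_spacing = 0.2, n_planes = 5),
    segmentation = list(min_area = 50, grad_k = 6, smooth_sigma = 1,
                        morph_radius = 2, exclusions = integer(0)),
    spots = list(window = 6, noise_size = 1, feature_size = 7,
                 threshold_k = 3, crop_shape = c(30, 35),
                 threshold_source = "raw"),
    photobleach = list(aperture_radius = 3, bg_annulus = c(5, 8),
                       min_step = NULL, penalty = 3),
    undercount = list(eps = 0.25, lambda_grid = seq(0.5, 15, by = 0.5),
                      n_cells_per_lambda = 10000, radius = 0.5,
                      length_range = c(1.5, 3.5)),
    newborn_max_length = 3.5,
    rng_seed = 1L
  ), class = "halocount_config")
}

#' Validate a pipeline configuration
#'
#' Checks every section against the defaults: unknown keys (at either level)
#' are rejected, and parameter values are validated before any stage runs.
#'
#' @param config Nested list as produced by [halocount_config()] or
#'   [read_config()]; missing entries are filled from the defaults.
#' @return The completed, validated config (class `halocount_config`).
#' @export
validate_config <- function(config) {
  def <- halocount_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    abort(paste0("Unknown config section(s): ", paste(unknown, collapse = ", ")))
  for (sec in names(config)) {
    if (is.list(def[[sec]]) && !is.null(names(def[[sec]]))) {
      bad <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(bad))
        abort(paste0("Unknown key(s) in '", sec, "': ",
                     paste(bad, collapse = ", ")))
      def[[sec]][names(config[[sec]])] <- config[[sec]]
    } else if (!is.null(config[[sec]])) {
      def[[sec]] <- config[[sec]]
    }
  }
  def$segmentation$exclusions <-
    as.integer(unlist(def$segmentation$exclusions))
  def$spots$crop_shape <- as.integer(unlist(def$spots$crop_shape))
  def$undercount$lambda_grid <- as.numeric(unlist(def$undercount$lambda_grid))
  def$photobleach$bg_annulus <- as.numeric(unlist(def$photobleach$bg_annulus))
  with(def, {
    if (optics$pixel_size <= 0) abort("optics.pixel_size must be > 0.")
    if (optics$n_planes < 1) abort("optics.n_planes must be >= 1.")
    if (segmentation$min_area < 1) abort("segmentation.min_area must be >= 1.")
    if (spots$window < 3) abort("spots.window must be >= 3.")
    if (spots$feature_size <= spots$noise_size)
      abort("spots.feature_size must exceed spots.noise_size.")
    if (undercount$eps < 0) abort("undercount.eps must be >= 0.")
    if (any(undercount$lambda_grid < 0))
      abort("undercount.lambda_grid must be >= 0.")
    if (newborn_max_length <= 0) abort("newborn_max_length must be > 0.")
  })
  class(def) <- "halocount_config"
  def
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file path.
#' @return For `read_config()`: the validated config.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config A config list.
#' @return For `write_config()`: `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(validate_config(config)), path)
  invisible(path)
}
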