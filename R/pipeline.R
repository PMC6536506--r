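#' Simulate a complete counting field with ground truth
#'
#' Generates everything the counting pipeline consumes for one field of view:
#' non-overlapping spherocylindrical cells, Poisson molecule copy numbers,
#' uniformly placed molecules (optionally constrained to a minimum projected
#' pairwise separation so every molecule is individually resolvable), the
#' rendered spot-channel z-stack, and the autofluorescence segmentation
#' image. When a separation constraint makes a drawn copy number
#' geometrically infeasible for a cell, that cell's count is redrawn (the
#' truth table always records what was actually placed).
#'
#' @param n_cells Number of cells.
#' @param lambda Poisson mean copy number per cell.
#' @param optics An [optics_config()].
#' @param field_size Field extent (x, y), um.
#' @param length_distribution,length_range,radius,min_gap Passed to
#'   [sample_cell_geometries()].
#' @param min_separation_2d Minimum projected pairwise molecule distance, um
#'   (0 = unconstrained).
#' @param separation_metric Metric for the separation constraint (see
#'   [sample_molecule_positions()]).
#' @param haze_level,autofluo_amplitude Rendering levels (counts).
#' @param max_count_redraws Redraws of an infeasible per-cell count.
#' @param rng_seed Optional integer seed.
#' @return List of class `sim_field`: `truth` (tibble cell_id, true_count,
#'   length_um), `geoms`, `positions` (field-frame matrix per cell), `stack`
#'   ([image_stack()]), `autofluo` (matrix), `optics`.
#' @export
simulate_counting_field <- function(n_cells, lambda,
                                    optics = optics_config(),
                                    field_size = c(40, 40),
                                    length_distribution = list("uniform",
                                                               min = 2.0,
                                                               max = 3.4),
                                    length_range = c(1.5, 3.5),
                                    radius = 0.5, min_gap = 1.6,
                                    min_separation_2d = 0,
                                    separation_metric = "euclidean",
                                    haze_level = 40,
                                    autofluo_amplitude = 100,
                                    max_count_redraws = 50,
                                    rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  geoms <- sample_cell_geometries(
    n_cells, length_distribution = length_distribution, radius = radius,
    field_size = field_size, min_gap = min_gap, length_range = length_range)
  counts <- integer(n_cells)
  positions <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    placed <- NULL
    for (try in seq_len(max_count_redraws)) {
      n <- rpois(1, lambda)
      placed <- tryCatch(
        sample_molecule_positions(geoms[[i]], n,
                                  min_separation_2d = min_separation_2d,
                                  metric = separation_metric,
                                  constraint_rotation = geoms[[i]]$orientation),
        error = function(e) NULL)
      if (!is.null(placed)) { counts[i] <- n; break }
    }
    if (is.null(placed))
      abort(sprintf("Cell %d: no feasible molecule count after %d redraws.",
                    i, max_count_redraws))
    positions[[i]] <- to_field_coordinates(geoms[[i]], placed)
  }
  all_pos <- do.call(rbind, positions)
  stack <- render_zstack(geoms, all_pos, optics, field_size = field_size,
                         haze_level = haze_level)
  autofluo <- render_autofluorescence(geoms, optics, field_size = field_size,
                                      amplitude = autofluo_amplitude)
  structure(list(
    truth = tibble(cell_id = seq_len(n_cells), true_count = counts,
                   length_um = vapply(geoms, function(g) g$total_length,
                                      numeric(1))),
    geoms = geoms, positions = positions, stack = stack,
    autofluo = autofluo, optics = optics, field_size = field_size),
    class = "sim_field")
}

#' Run the full counting pipeline on one field
#'
#' Segment the autofluorescence image, apply the newborn length filter,
#' count diffraction-limited spots per cell, and assemble a run report
#' (parameters, seed, config hash, per-stage tallies, and every dropped cell
#' with its reason).
#'
#' @param autofluo Autofluorescence image (matrix) used for segmentation.
#' @param stack Spot-channel [image_stack()].
#' @param config Pipeline configuration (see [halocount_config()]); validated
#'   before any stage runs.
#' @param field_id Label recorded in the output tables.
#' @return List of class `halocount_run`: `counts` tibble (field_id, cell_id,
#'   length_um, n_spots), `spots`, `regions` (post-filter), `report`.
#' @export
run_pipeline <- function(autofluo, stack, config = halocount_config(),
                         field_id = "field_1") {
  config <- validate_config(config)
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  seg <- config$segmentation
  regions <- segment_cells(autofluo,
                           pixel_size = config$optics$pixel_size,
                           min_area = seg$min_area, grad_k = seg$grad_k,
                           smooth_sigma = seg$smooth_sigma,
                           morph_radius = seg$morph_radius)
  excluded <- regions$cell_id[regions$cell_id %in% seg$exclusions]
  regions2 <- dplyr::filter(regions, !.data$cell_id %in% seg$exclusions)
  newborn <- filter_newborn(regions2, config$newborn_max_length)
  too_long <- dplyr::anti_join(regions2, newborn, by = "cell_id")
  sc <- spot_config(window = config$spots$window,
                    noise_size = config$spots$noise_size,
                    feature_size = config$spots$feature_size,
                    threshold_k = config$spots$threshold_k,
                    crop_shape = config$spots$crop_shape,
                    threshold_source = config$spots$threshold_source)
  cs <- count_spots(stack, newborn, sc)
  counts <- dplyr::mutate(cs$counts, field_id = field_id, .before = 1)
  dropped <- dplyr::bind_rows(
    tibble(cell_id = excluded, reason = "exclusion list"),
    tibble(cell_id = too_long$cell_id,
           reason = sprintf("length %.3f um >= newborn cutoff %.2f um",
                            too_long$length_um, config$newborn_max_length)))
  report <- list(
    field_id = field_id,
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    seed = config$rng_seed,
    package_version = as.character(utils::packageVersion("halocount")),
    n_segmented = nrow(regions),
    n_excluded = length(excluded),
    n_newborn = nrow(newborn),
    n_spots_total = sum(counts$n_spots),
    dropped = dropped)
  structure(list(counts = counts, spots = cs$spots, regions = newborn,
                 report = report),
            class = "halocount_run")
}

#' @export
print.halocount_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("<halocount_run> %s: %d segmented -> %d newborn cells, %d spots (mean %.2f/cell)\n",
              r$field_id, r$n_segmented, r$n_newborn, r$n_spots_total,
              if (r$n_newborn) r$n_spots_total / r$n_newborn else NA))
  invisible(x)
}

#' Write the outputs of a pipeline run
#'
#' Writes `counts.csv`, `spots.csv` and `report.json` (which embeds the
#' configuration and its hash, so a rerun with the same config and seed is
#' byte-identical) into `dir`.
#'
#' @param run A `halocount_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(run$counts, file.path(dir, "counts.csv"))
  write_counts(run$spots, file.path(dir, "spots.csv"))
  rep <- run$report
  rep$dropped <- as.data.frame(rep$dropped)
  jsonlite::write_json(rep, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
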