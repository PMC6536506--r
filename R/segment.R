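#' Compute geometric properties of a segmented cell region
#'
#' Properties follow the usual regionprops conventions, made explicit:
#' * `area_px`: number of mask pixels.
#' * `perimeter_px`: number of boundary pixels (mask pixels with at least one
#'   4-neighbour outside the mask or on the image edge).
#' * `centroid_row`, `centroid_col`: mean pixel indices (1-based).
#' * `length_um` / `width_um`: extent of pixel centers projected on the
#'   major / minor principal axis, plus one pixel, times `pixel_size` (so a
#'   single pixel has length = width = `pixel_size`). For an isotropic pixel
#'   distribution (e.g. a square) the image axes are used.
#'
#' @param mask Logical matrix (one connected region) or a two-column
#'   (row, col) pixel-index matrix.
#' @param pixel_size um per pixel.
#' @return One-row tibble with the fields above plus a `pixels` list-column
#'   holding the (row, col) index matrix.
#' @export
region_properties <- function(mask, pixel_size) {
  if (is.matrix(mask) && ncol(mask) == 2 && !is.logical(mask)) {
    px <- mask
  } else {
    px <- which(mask != 0, arr.ind = TRUE)
  }
  if (nrow(px) == 0) abort("Empty mask.")
  colnames(px) <- c("row", "col")
  area <- nrow(px)

  keys <- paste(px[, 1], px[, 2])
  on_edge <- function(dr, dc) !(paste(px[, 1] + dr, px[, 2] + dc) %in% keys)
  boundary <- on_edge(1, 0) | on_edge(-1, 0) | on_edge(0, 1) | on_edge(0, -1)
  perim <- sum(boundary)

  cr <- mean(px[, 1]); cc <- mean(px[, 2])
  if (area == 1) {
    len <- wid <- pixel_size
    ang <- 0
  } else {
    cv <- stats::cov(px[, c(2, 1)])  # (x, y) order
    if (abs(cv[1, 1] - cv[2, 2]) < 1e-9 && abs(cv[1, 2]) < 1e-9) {
      v1 <- c(1, 0); v2 <- c(0, 1)
    } else {
      ev <- eigen(cv, symmetric = TRUE)
      v1 <- ev$vectors[, 1]; v2 <- ev$vectors[, 2]
    }
    xy <- cbind(px[, 2], px[, 1])
    p1 <- xy %*% v1; p2 <- xy %*% v2
    len <- (diff(range(p1)) + 1) * pixel_size
    wid <- (diff(range(p2)) + 1) * pixel_size
    if (wid > len) { tmp <- len; len <- wid; wid <- tmp }
    ang <- atan2(v1[2], v1[1])
  }
  tibble(centroid_row = cr, centroid_col = cc, area_px = area,
         perimeter_px = perim, length_um = len, width_um = wid,
         orientation = ang, pixels = list(px))
}

.regions_from_labels <- function(lab, pixel_size, min_area = 0,
                                 drop_border = FALSE) {
  n <- max(lab)
  if (n == 0)
    return(.empty_cell_table())
  rows <- purrr::map(seq_len(n), function(k) {
    px <- which(lab == k, arr.ind = TRUE)
    if (nrow(px) < max(min_area, 1)) return(NULL)
    if (drop_border &&
        (any(px[, 1] %in% c(1L, nrow(lab))) ||
         any(px[, 2] %in% c(1L, ncol(lab))))) return(NULL)
    region_properties(px, pixel_size)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(.empty_cell_table())
  dplyr::mutate(out, cell_id = dplyr::row_number(), .before = 1)
}

.empty_cell_table <- function() {
  tibble(cell_id = integer(0), centroid_row = numeric(0),
         centroid_col = numeric(0), area_px = integer(0),
         perimeter_px = integer(0), length_um = numeric(0),
         width_um = numeric(0), orientation = numeric(0),
         pixels = list())
}

#' Segment cells in an autofluorescence image
#'
#' Cells are found from their elevated autofluorescence using an
#' edge-evidence scheme: the image is lightly smoothed (Gaussian, sigma 1 px),
#' the Sobel gradient magnitude is thresholded at a robust global level
#' (median + `grad_k` * MAD-based SD of the gradient image), and the binary
#' edge map is dilated, hole-filled, eroded back and labelled. Regions smaller
#' than `min_area` or touching the image border are removed. `exclusions`
#' drops the listed `cell_id`s from the result — a reproducible stand-in for
#' manual curation of mis-segmented cells.
#'
#' @param image 2D numeric matrix (autofluorescence channel).
#' @param pixel_size um per pixel.
#' @param min_area Minimum region area, pixels.
#' @param exclusions Optional integer vector of `cell_id`s to drop.
#' @param grad_k Robust gradient-threshold multiplier.
#' @param smooth_sigma Pre-smoothing Gaussian sigma, pixels.
#' @param morph_radius Disc radius for the dilate/erode steps, pixels.
#' @return Tibble of cell regions (see [region_properties()]); `cell_id`s are
#'   assigned before exclusions are applied, so excluded ids leave gaps.
#' @export
segment_cells <- function(image, pixel_size = 0.16, min_area = 50,
                          exclusions = NULL, grad_k = 6, smooth_sigma = 1,
                          morph_radius = 2) {
  if (length(dim(image)) != 2)
    abort("`image` must be a 2D matrix.")
  if (!all(is.finite(image))) abort("`image` must contain finite values.")
  img <- matrix(as.numeric(image), nrow(image), ncol(image))
  sm <- .as_matrix(EBImage::gblur(img, sigma = smooth_sigma))
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- .as_matrix(EBImage::filter2(sm, kx))
  gy <- .as_matrix(EBImage::filter2(sm, t(kx)))
  mag <- sqrt(gx^2 + gy^2)
  thr <- median(mag) + grad_k * mad(mag)
  bw <- mag > thr
  if (!any(bw)) return(.empty_cell_table())
  brush <- EBImage::makeBrush(2 * morph_radius + 1, shape = "disc")
  bw <- EBImage::dilate(bw, brush)
  bw <- EBImage::fillHull(bw)
  bw <- EBImage::erode(bw, brush)
  lab <- .as_matrix(EBImage::bwlabel(bw))
  out <- .regions_from_labels(lab, pixel_size, min_area = min_area,
                              drop_border = TRUE)
  if (!is.null(exclusions))
    out <- dplyr::filter(out, !.data$cell_id %in% exclusions)
  out
}

.as_matrix <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  m
}

#' Keep newborn cells only
#'
#' Recently divided ("newborn") cells are selected by conditioning on cell
#' size: only cells strictly shorter than `max_length` are kept, so that
#' per-cell molecule counts are not inflated by cells about to divide.
#'
#' @param regions Cell-region tibble (from [segment_cells()] or
#'   [region_properties()]).
#' @param max_length Length cutoff, um (default 3.5; strict `<`).
#' @return The filtered tibble (a subset of the input rows).
#' @export
filter_newborn <- function(regions, max_length = 3.5) {
  dplyr::filter(regions, .data$length_um < max_length)
}

#' Intensity-based cell segmentation for concentration quantification
#'
#' Used for measuring protein concentration as mean fluorescence per unit
#' area (rather than finding cells in a separate channel). The image is
#' background-corrected by subtracting a morphologically opened copy of
#' itself, smoothed with a Gaussian, and thresholded against a robust fit of
#' the "non-cell" intensity distribution (median + `k` * MAD-based SD of the
#' lower 80% of pixels). Each connected component is then trimmed of its
#' lowest-intensity `low_fraction` of pixels (which helps split touching
#' cells) and re-labelled.
#'
#' @param image 2D numeric matrix (fluorescence channel).
#' @param opening_radius Structuring-disc radius for the background opening,
#'   pixels; must exceed the cell width in pixels.
#' @param gaussian_sigma Smoothing sigma, pixels.
#' @param low_fraction Fraction of lowest-intensity pixels removed from each
#'   component, in `[0, 1)`.
#' @param k Threshold multiplier over the non-cell robust SD.
#' @param pixel_size um per pixel.
#' @param min_area Minimum region area after trimming, pixels.
#' @return Tibble of cell regions (see [region_properties()]).
#' @export
segment_by_intensity <- function(image, opening_radius = 15,
                                 gaussian_sigma = 1, low_fraction = 0.2,
                                 k = 5, pixel_size = 0.16, min_area = 5) {
  if (length(dim(image)) != 2) abort("`image` must be a 2D matrix.")
  if (low_fraction < 0 || low_fraction >= 1)
    abort("`low_fraction` must be in [0, 1).")
  img <- matrix(as.numeric(image), nrow(image), ncol(image))
  if (diff(range(img)) == 0) return(.empty_cell_table())
  brush <- EBImage::makeBrush(2 * opening_radius + 1, shape = "disc")
  bg <- .as_matrix(EBImage::opening(img, brush))
  sub <- img - bg
  sm <- .as_matrix(EBImage::gblur(sub, sigma = gaussian_sigma))
  low <- sm[sm <= quantile(sm, 0.8)]
  thr <- median(low) + k * mad(low)
  bw <- sm > thr
  if (!any(bw)) return(.empty_cell_table())
  lab <- .as_matrix(EBImage::bwlabel(bw))
  if (low_fraction > 0) {
    for (cid in seq_len(max(lab))) {
      px <- which(lab == cid)
      n_drop <- floor(low_fraction * length(px))
      if (n_drop > 0) {
        drop <- px[order(sm[px])][seq_len(n_drop)]
        lab[drop] <- 0L
      }
    }
    lab <- .as_matrix(EBImage::bwlabel(lab > 0))
  }
  .regions_from_labels(lab, pixel_size, min_area = min_area)
}

#' Mean intensity per unit area of a cell
#'
#' The arithmetic mean of the pixel values over the region mask — the
#' per-cell measure of protein concentration used with
#' [segment_by_intensity()].
#'
#' @param image 2D numeric matrix.
#' @param region One row of a cell-region tibble, or a (row, col) pixel-index
#'   matrix.
#' @return Mean counts per pixel (scalar).
#' @export
mean_intensity_per_area <- function(image, region) {
  px <- if (is.matrix(region)) region else region$pixels[[1]]
  if (any(px[, 1] < 1 | px[, 1] > nrow(image) |
          px[, 2] < 1 | px[, 2] > ncol(image)))
    abort("Region mask extends outside the image.")
  mean(image[px])
}
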