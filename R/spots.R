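#' Spot-detection configuration
#'
#' Parameters of the diffraction-limited spot caller. The crop and window
#' sizes follow the standard particle-counting recipe for small bacterial
#' cells: a 30 x 35 px crop around each cell centroid and a 6 x 6 px
#' local-maximum window.
#'
#' @param window Peak neighbourhood side, pixels (>= 3; even sizes use the
#'   asymmetric offset convention, see [find_peaks()]).
#' @param noise_size Band-pass high-frequency (noise) scale, pixels.
#' @param feature_size Band-pass low-frequency (object) scale, pixels; must
#'   exceed `noise_size`.
#' @param threshold_k Local-threshold multiplier over the robust noise SD.
#' @param crop_shape Integer (rows, cols) of the per-cell crop.
#' @param threshold_source `"raw"` (default): the threshold scale is the
#'   MAD-based SD of the raw crop, applied to the zero-baseline band-passed
#'   image; `"bandpass"`: median + k * MAD-SD of the unclipped band-passed
#'   crop itself.
#' @return A validated list of class `spot_config`.
#' @export
spot_config <- function(window = 6, noise_size = 1, feature_size = 7,
                        threshold_k = 3, crop_shape = c(30, 35),
                        threshold_source = c("raw", "bandpass")) {
  if (window < 3) abort("`window` must be >= 3.")
  if (!(feature_size > noise_size && noise_size >= 1))
    abort("Need feature_size > noise_size >= 1.")
  if (length(crop_shape) != 2 || any(crop_shape < 1))
    abort("`crop_shape` must be two positive integers.")
  structure(list(window = as.integer(window), noise_size = noise_size,
                 feature_size = feature_size, threshold_k = threshold_k,
                 crop_shape = as.integer(crop_shape),
                 threshold_source = match.arg(threshold_source)),
            class = "spot_config")
}

#' Maximum intensity projection of a z-stack
#'
#' Collapses a stack to its per-pixel maximum over planes. By default the
#' first plane is excluded because it carries most of the cellular
#' autofluorescence signal in this acquisition scheme.
#'
#' @param stack An [image_stack()].
#' @param skip_first Drop the first plane before projecting?
#' @return Numeric matrix `[row, col]`.
#' @export
max_projection <- function(stack, skip_first = TRUE) {
  d <- dim(stack$data)
  if (skip_first && d[1] < 2)
    abort("Stack must have >= 2 planes when `skip_first = TRUE`.")
  keep <- if (skip_first) 2:d[1] else 1:d[1]
  apply(stack$data[keep, , , drop = FALSE], c(2, 3), max)
}

#' Crop a fixed-shape window around a point
#'
#' Returns a crop of exactly `crop_shape` centred on `centroid` (the centroid
#' is rounded to the nearest pixel; the window extends
#' `floor(shape / 2)` before it). Near the image border the missing pixels
#' are padded with the median of the full image, which keeps the band-pass
#' filter free of edge artefacts. The returned offset maps crop coordinates
#' back to the full image: `full = crop + offset`.
#'
#' @param image 2D numeric matrix.
#' @param centroid Numeric (row, col) position, inside the image.
#' @param crop_shape Integer (rows, cols).
#' @return List with `crop` (matrix of `crop_shape`) and `offset`
#'   (integer (row, col), possibly negative near borders).
#' @export
crop_around <- function(image, centroid, crop_shape = c(30, 35)) {
  cr <- round(centroid[1]); cc <- round(centroid[2])
  if (cr < 1 || cr > nrow(image) || cc < 1 || cc > ncol(image))
    abort("`centroid` lies outside the image.")
  r0 <- cr - floor(crop_shape[1] / 2)
  c0 <- cc - floor(crop_shape[2] / 2)
  rows <- r0:(r0 + crop_shape[1] - 1L)
  cols <- c0:(c0 + crop_shape[2] - 1L)
  med <- median(image)
  crop <- matrix(med, crop_shape[1], crop_shape[2])
  rin <- rows >= 1 & rows <= nrow(image)
  cin <- cols >= 1 & cols <= ncol(image)
  crop[rin, cin] <- image[rows[rin], cols[cin]]
  list(crop = crop, offset = c(r0 - 1L, c0 - 1L))
}

# separable convolution with replicated-edge padding
.conv_sep <- function(img, kr, kc) {
  pr <- (length(kr) - 1L) %/% 2L
  pc <- (length(kc) - 1L) %/% 2L
  padded <- img[c(rep(1L, pr), seq_len(nrow(img)), rep(nrow(img), pr)),
                c(rep(1L, pc), seq_len(ncol(img)), rep(ncol(img), pc)),
                drop = FALSE]
  out <- apply(padded, 2, function(col) stats::filter(col, kr, sides = 2))
  out <- out[(pr + 1):(pr + nrow(img)), , drop = FALSE]
  out <- t(apply(out, 1, function(row) stats::filter(row, kc, sides = 2)))
  out[, (pc + 1):(pc + ncol(img)), drop = FALSE]
}

#' Spatial band-pass filter for diffraction-limited spots
#'
#' The classic particle-pretracking band-pass: the image is convolved with a
#' normalized Gaussian of width set by `noise_size` (suppressing pixel-scale
#' noise) and a boxcar average of half-width `feature_size` (estimating the
#' slowly varying background), and the difference is taken; negative output
#' is clipped to zero. The Gaussian uses sigma = sqrt(2) * `noise_size`, the
#' convention of the standard particle-tracking kernels. The unclipped
#' response is attached as attribute `"raw_response"` for thresholding.
#'
#' @param image 2D numeric matrix.
#' @param noise_size Noise length scale, pixels.
#' @param feature_size Object length scale, pixels (kernel half-width).
#' @return Matrix of the clipped band-pass response, same shape as `image`,
#'   with attribute `raw_response`.
#' @export
bandpass <- function(image, noise_size = 1, feature_size = 7) {
  if (feature_size <= noise_size)
    abort("Need feature_size > noise_size.")
  w <- ceiling(feature_size)
  if (2 * w + 1 > min(dim(image)))
    abort("Band-pass kernel is larger than the image.")
  sg <- sqrt(2) * noise_size
  x <- -w:w
  g <- exp(-x^2 / (2 * sg^2)); g <- g / sum(g)
  b <- rep(1 / (2 * w + 1), 2 * w + 1)
  smooth <- .conv_sep(image, g, g)
  backgr <- .conv_sep(image, b, b)
  raw <- smooth - backgr
  out <- pmax(raw, 0)
  dim(out) <- dim(image)
  attr(out, "raw_response") <- raw
  out
}

#' Find diffraction-limited peaks
#'
#' A spot is a pixel that is maximal within its `window` x `window`
#' neighbourhood and exceeds the local threshold. For even windows the
#' neighbourhood offsets run `-window/2 .. window/2 - 1` in each direction
#' (there is no centre pixel); plateaus are broken by keeping the
#' topmost-then-leftmost pixel. When no explicit `threshold` is supplied it is
#' computed as median + `threshold_k` * MAD-based SD of the unclipped
#' band-pass response if present (attribute `"raw_response"`), otherwise of
#' the image itself.
#'
#' @param image 2D numeric matrix (normally a [bandpass()] output).
#' @param window Neighbourhood side, pixels (>= 3).
#' @param threshold_k Threshold multiplier.
#' @param threshold Optional explicit threshold (overrides `threshold_k`).
#' @return Tibble with columns `row`, `col`, `peak_intensity`.
#' @export
find_peaks <- function(image, window = 6, threshold_k = 3, threshold = NULL) {
  if (window < 3) abort("`window` must be >= 3.")
  if (is.null(threshold)) {
    ref <- attr(image, "raw_response")
    if (is.null(ref)) ref <- image
    threshold <- median(ref) + threshold_k * mad(ref)
  }
  lo <- -floor(window / 2)
  hi <- window + lo - 1L
  cand <- which(image > threshold, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  nr <- nrow(image); nc <- ncol(image)
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]; v <- image[r, c]
    rr <- max(1, r + lo):min(nr, r + hi)
    cc <- max(1, c + lo):min(nc, c + hi)
    nb <- image[rr, cc, drop = FALSE]
    if (any(nb > v)) next
    # tie-break: among equal-valued pixels in the window keep the
    # topmost-then-leftmost one
    ties <- which(nb == v, arr.ind = TRUE)
    ties_full <- cbind(rr[ties[, 1]], cc[ties[, 2]])
    ord <- order(ties_full[, 1], ties_full[, 2])
    first <- ties_full[ord[1], ]
    keep[i] <- first[1] == r && first[2] == c
  }
  cand <- cand[keep, , drop = FALSE]
  tibble(row = as.integer(cand[, 1]), col = as.integer(cand[, 2]),
         peak_intensity = image[cand])
}

#' Count diffraction-limited spots per cell
#'
#' The complete counting pipeline for one field: maximum projection of the
#' z-stack (excluding the first plane), a fixed-shape crop around each cell
#' centroid, band-pass filtering of the crop, windowed local-maximum peak
#' calling above the local threshold, and assignment of each peak to the cell
#' whose mask contains it. Peaks falling inside a crop but outside the owning
#' cell's mask are dropped, which resolves overlapping crops of neighbouring
#' cells.
#'
#' @param stack An [image_stack()] (spot channel).
#' @param regions Cell-region tibble from [segment_cells()] (after any
#'   filtering).
#' @param config A [spot_config()].
#' @param skip_first Passed to [max_projection()].
#' @return List with `counts`: tibble (cell_id, length_um, n_spots), and
#'   `spots`: tibble (cell_id, row, col, peak_intensity) in full-image
#'   coordinates.
#' @export
count_spots <- function(stack, regions, config = spot_config(),
                        skip_first = TRUE) {
  proj <- max_projection(stack, skip_first = skip_first)
  spots <- list(); counts <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    ctr <- c(regions$centroid_row[i], regions$centroid_col[i])
    cr <- crop_around(proj, ctr, config$crop_shape)
    bp <- bandpass(cr$crop, config$noise_size, config$feature_size)
    thr <- switch(config$threshold_source,
      raw = config$threshold_k * mad(cr$crop),
      bandpass = {
        raw <- attr(bp, "raw_response")
        median(raw) + config$threshold_k * mad(raw)
      })
    pk <- find_peaks(bp, window = config$window, threshold = thr)
    if (nrow(pk)) {
      pk$row <- pk$row + cr$offset[1]
      pk$col <- pk$col + cr$offset[2]
      px <- regions$pixels[[i]]
      inside <- paste(pk$row, pk$col) %in% paste(px[, 1], px[, 2])
      pk <- pk[inside, , drop = FALSE]
    }
    counts[i] <- nrow(pk)
    if (nrow(pk)) spots[[length(spots) + 1L]] <-
        dplyr::mutate(pk, cell_id = regions$cell_id[i], .before = 1)
  }
  list(
    counts = tibble(cell_id = regions$cell_id,
                    length_um = regions$length_um, n_spots = counts),
    spots = if (length(spots)) dplyr::bind_rows(spots) else
      tibble(cell_id = integer(0), row = integer(0), col = integer(0),
             peak_intensity = numeric(0))
  )
}
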