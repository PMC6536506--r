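#' Extract a background-subtracted spot intensity trace
#'
#' For every frame of a time stack, the trace value is the mean intensity in
#' a circular aperture around the spot minus the median intensity in a
#' surrounding annulus (the robust local background; the median resists
#' contamination by neighbouring spots).
#'
#' @param time_stack An [image_stack()] with `axis = "t"` (frames, y, x).
#' @param position Numeric (row, col) spot position, pixels.
#' @param aperture_radius Aperture radius, pixels.
#' @param bg_annulus Numeric (inner, outer) annulus radii, pixels.
#' @return A `bleach_trace` object (values per frame, background-subtracted).
#' @export
extract_trace <- function(time_stack, position, aperture_radius = 3,
                          bg_annulus = c(5, 8)) {
  d <- dim(time_stack$data)
  r <- round(position[1]); c <- round(position[2])
  out_r <- ceiling(bg_annulus[2])
  if (r - out_r < 1 || r + out_r > d[2] || c - out_r < 1 || c + out_r > d[3])
    abort("Background annulus is clipped by the image border.")
  ii <- (r - out_r):(r + out_r); jj <- (c - out_r):(c + out_r)
  dist <- sqrt(outer((ii - position[1])^2, (jj - position[2])^2, "+"))
  ap <- dist <= aperture_radius
  an <- dist >= bg_annulus[1] & dist <= bg_annulus[2]
  vals <- vapply(seq_len(d[1]), function(f) {
    patch <- time_stack$data[f, ii, jj]
    mean(patch[ap]) - median(patch[an])
  }, numeric(1))
  structure(list(values = vals, frame_interval = time_stack$z_spacing,
                 true_step_frames = NULL),
            class = "bleach_trace")
}

# best single change point of a segment by least squares; returns
# list(idx = first frame of the right part, gain = RSS reduction)
.best_split <- function(x) {
  n <- length(x)
  if (n < 2) return(NULL)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  k <- 1:(n - 1)
  lm_ <- cs[k] / k
  rm_ <- (cs[n] - cs[k]) / (n - k)
  # RSS reduction of splitting at k (left = 1..k)
  gain <- k * (n - k) / n * (lm_ - rm_)^2
  kb <- which.max(gain)
  list(idx = kb + 1L, gain = gain[kb])
}

#' Count photobleaching steps in a trace
#'
#' Change points are located by binary segmentation with a piecewise-constant
#' least-squares fit; the number of change points is chosen by a BIC-style
#' penalized residual criterion (`n log(RSS/n) + penalty * k * log(n)`).
#' Candidate steps are then kept only if they go downward with height at
#' least `min_step` — the signature of fluorophore bleaching. A clean
#' single-step trace therefore reports one step; a tandem double tag reports
#' two.
#'
#' @param trace A `bleach_trace` (or numeric vector of intensities).
#' @param min_step Minimum step height, counts (> 0). `NULL` (default)
#'   estimates it as 3x the frame-to-frame noise SD
#'   (`mad(diff(values)) / sqrt(2)`).
#' @param penalty Penalty multiplier of the model-order criterion.
#' @param max_steps Maximum number of change points considered.
#' @return Object of class `bleach_fit`: list with `n_steps`, `step_frames`
#'   (first frame of each new level), `step_heights` (negative = downward),
#'   `levels`, and the input values. Use [tidy()] / [glance()] for tabular
#'   access.
#' @export
count_steps <- function(trace, min_step = NULL, penalty = 3, max_steps = 8) {
  x <- if (inherits(trace, "bleach_trace")) trace$values else as.numeric(trace)
  n <- length(x)
  if (n < 2) abort("Trace must have >= 2 frames.")
  if (is.null(min_step)) {
    noise <- mad(diff(x)) / sqrt(2)
    min_step <- max(3 * noise, 1e-9)
  }
  if (min_step <= 0) abort("`min_step` must be > 0.")

  # binary segmentation: greedily add the globally best split
  bounds <- c(1L, n + 1L)  # segment starts (+ sentinel)
  cps <- integer(0)
  rss <- function(b) {
    segs <- split(x, findInterval(seq_len(n), b[-length(b)]))
    sum(vapply(segs, function(s) sum((s - mean(s))^2), numeric(1)))
  }
  cost <- function(r, k) n * log(max(r, 1e-12) / n) + penalty * k * log(n)
  best_k <- 0L; best_cost <- cost(rss(bounds), 0L); best_cps <- integer(0)
  for (k in seq_len(max_steps)) {
    # best split over all current segments
    top <- NULL
    for (s in seq_len(length(bounds) - 1L)) {
      seg <- x[bounds[s]:(bounds[s + 1L] - 1L)]
      sp <- .best_split(seg)
      if (!is.null(sp) && (is.null(top) || sp$gain > top$gain))
        top <- list(gain = sp$gain, at = bounds[s] + sp$idx - 1L)
    }
    if (is.null(top)) break
    bounds <- sort(unique(c(bounds, top$at)))
    cps <- sort(c(cps, top$at))
    ck <- cost(rss(bounds), k)
    if (ck < best_cost) { best_cost <- ck; best_k <- k; best_cps <- cps }
  }

  # refit at the selected order and keep only downward steps >= min_step
  b <- c(1L, best_cps, n + 1L)
  seg_means <- vapply(seq_len(length(b) - 1L),
                      function(s) mean(x[b[s]:(b[s + 1L] - 1L)]), numeric(1))
  heights <- diff(seg_means)
  keep <- heights <= -min_step
  step_frames <- best_cps[keep]
  step_heights <- heights[keep]
  # merge segments across rejected change points for the reported levels
  b2 <- c(1L, step_frames, n + 1L)
  levels <- vapply(seq_len(length(b2) - 1L),
                   function(s) mean(x[b2[s]:(b2[s + 1L] - 1L)]), numeric(1))
  structure(list(n_steps = length(step_frames),
                 step_frames = as.integer(step_frames),
                 step_heights = step_heights,
                 levels = levels, values = x,
                 min_step = min_step, penalty = penalty),
            class = "bleach_fit")
}

#' @export
print.bleach_fit <- function(x, ...) {
  cat(sprintf("<bleach_fit> %d downward step(s)%s over %d frames\n",
              x$n_steps,
              if (x$n_steps) paste0(" at frame(s) ",
                                    paste(x$step_frames, collapse = ", "))
              else "", length(x$values)))
  invisible(x)
}

#' Tidy a photobleach step fit
#'
#' @param x A `bleach_fit` from [count_steps()].
#' @param ... Unused.
#' @return Tibble with one row per detected step: `step_frame` (first frame
#'   of the new level), `height` (negative), `level_before`, `level_after`.
#' @export
tidy.bleach_fit <- function(x, ...) {
  if (x$n_steps == 0)
    return(tibble(step_frame = integer(0), height = numeric(0),
                  level_before = numeric(0), level_after = numeric(0)))
  tibble(step_frame = x$step_frames, height = x$step_heights,
         level_before = x$levels[seq_len(x$n_steps)],
         level_after = x$levels[seq_len(x$n_steps) + 1L])
}

#' @rdname tidy.bleach_fit
#' @return For `glance()`: a one-row tibble with `n_steps`, `n_frames`,
#'   `initial_level`, `final_level`, `min_step`, `penalty`.
#' @export
glance.bleach_fit <- function(x, ...) {
  tibble(n_steps = x$n_steps, n_frames = length(x$values),
         initial_level = x$levels[1],
         final_level = x$levels[length(x$levels)],
         min_step = x$min_step, penalty = x$penalty)
}
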