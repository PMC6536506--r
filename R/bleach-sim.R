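#' Simulate a photobleaching intensity trace
#'
#' Generates the background-subtracted intensity time series of a spot
#' containing `n_fluorophores` dyes. The trace starts at
#' `n_fluorophores * step_height` and loses one `step_height` at each bleach
#' event; per-fluorophore bleach frames are geometrically distributed with
#' `bleach_probability_per_frame` (fluorophores surviving the whole movie
#' simply never step). Gaussian noise of SD `noise_sd` is added. A single
#' fluorophore therefore gives the canonical single-step trace; two tandem
#' dyes give a two-step staircase.
#'
#' @param n_fluorophores Number of fluorophores on the spot (>= 0).
#' @param step_height Intensity lost per bleach event, counts.
#' @param frames Number of frames (>= 2).
#' @param bleach_probability_per_frame Per-frame bleach probability in
#'   `[0, 1]`.
#' @param noise_sd Gaussian noise SD, counts.
#' @param frame_interval Seconds per frame (metadata only).
#' @param rng_seed Optional integer seed.
#'
#' @return A list of class `bleach_trace`: `values` (numeric, length
#'   `frames`), `frame_interval`, and ground truth `true_step_frames`
#'   (the first noisy frame of each new level, sorted; events after the last
#'   frame are not included).
#' @export
simulate_bleach_trace <- function(n_fluorophores, step_height = 100,
                                  frames = 100,
                                  bleach_probability_per_frame = 0.02,
                                  noise_sd = 5, frame_interval = 1,
                                  rng_seed = NULL) {
  if (n_fluorophores < 0) abort("`n_fluorophores` must be >= 0.")
  if (frames < 2) abort("`frames` must be >= 2.")
  p <- bleach_probability_per_frame
  if (!is.finite(p) || p < 0 || p > 1)
    abort("`bleach_probability_per_frame` must be in [0, 1].")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  # each fluorophore stays bright >= 1 frame; dark from frame `dark_at` on
  dark_at <- if (n_fluorophores > 0 && p > 0)
    stats::rgeom(n_fluorophores, p) + 2L
  else rep(.Machine$integer.max, n_fluorophores)
  bleach_at <- sort(dark_at[dark_at <= frames])
  level <- vapply(seq_len(frames), function(f) sum(dark_at > f), numeric(1))
  values <- level * step_height + rnorm(frames, 0, noise_sd)
  structure(list(values = values, frame_interval = frame_interval,
                 true_step_frames = bleach_at),
            class = "bleach_trace")
}

#' @export
print.bleach_trace <- function(x, ...) {
  cat(sprintf("<bleach_trace> %d frames, %d true step(s)%s\n",
              length(x$values), length(x$true_step_frames),
              if (length(x$true_step_frames))
                paste0(" at ", paste(x$true_step_frames, collapse = ", "))
              else ""))
  invisible(x)
}
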