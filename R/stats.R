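#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares two per-cell count (or intensity) distributions. The statistic is
#' `D = max |ECDF_a - ECDF_b|` with the asymptotic two-sided p-value; at the
#' conventional 5% level, `p >= alpha` is read as "the distributions are
#' similar".
#'
#' @param a,b Numeric samples (non-empty).
#' @param alpha Significance level for the decision field.
#' @return One-row tibble: `statistic` (D), `p_value`, `n_a`, `n_b`,
#'   `similar` (logical, `p_value >= alpha`).
#' @export
ks_two_sample <- function(a, b, alpha = 0.05) {
  if (!length(a) || !length(b)) abort("Both samples must be non-empty.")
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  tibble(statistic = unname(kt$statistic), p_value = unname(kt$p.value),
         n_a = length(a), n_b = length(b),
         similar = unname(kt$p.value) >= alpha)
}

#' Aggregate per-cell count distributions across replicates
#'
#' For each replicate, computes the proportion of cells with each count
#' `0..max_count` (counts above `max_count` are pooled into the top bin),
#' then averages the per-bin proportions across replicates with their spread
#' — the way replicate count histograms are presented with error bars. Also
#' returns the per-replicate and overall mean counts.
#'
#' @param replicates List of non-empty integer vectors (per-cell counts, one
#'   vector per biological replicate).
#' @param max_count Top bin; larger counts are pooled here.
#' @param spread `"sd"` (default): standard deviation across replicates;
#'   `"sem"`: standard error of the mean across replicates.
#' @return Object of class `count_aggregate`: list with `proportions`
#'   (tibble: count, mean_proportion, spread, plus one `rep_*` column per
#'   replicate), `mean_count`, `mean_count_spread`, `replicate_means`,
#'   `n_cells`, `spread_type`.
#' @export
aggregate_replicates <- function(replicates, max_count = 10,
                                 spread = c("sd", "sem")) {
  spread <- match.arg(spread)
  if (!length(replicates)) abort("Need at least one replicate.")
  if (any(vapply(replicates, length, integer(1)) == 0))
    abort("Replicates must be non-empty.")
  if (any(unlist(replicates) < 0)) abort("Counts must be >= 0.")
  bins <- 0:max_count
  props <- vapply(replicates, function(x) {
    x <- pmin(x, max_count)
    tabulate(x + 1L, nbins = max_count + 1L) / length(x)
  }, numeric(max_count + 1L))
  props <- matrix(props, nrow = max_count + 1L)
  spread_fun <- if (spread == "sd") function(v) sd(v) else
    function(v) sd(v) / sqrt(length(v))
  spr <- if (ncol(props) > 1) apply(props, 1, spread_fun) else
    rep(0, nrow(props))
  tab <- tibble(count = bins,
                mean_proportion = rowMeans(props),
                spread = spr)
  for (r in seq_along(replicates))
    tab[[paste0("rep_", r)]] <- props[, r]
  rep_means <- vapply(replicates, mean, numeric(1))
  structure(list(proportions = tab,
                 mean_count = mean(rep_means),
                 mean_count_spread = if (length(rep_means) > 1)
                   spread_fun(rep_means) else 0,
                 replicate_means = rep_means,
                 n_cells = vapply(replicates, length, integer(1)),
                 spread_type = spread),
            class = "count_aggregate")
}

#' @export
print.count_aggregate <- function(x, ...) {
  cat(sprintf("<count_aggregate> %d replicate(s), %s cells; mean count %.2f +/- %.2f (%s)\n",
              length(x$n_cells), paste(x$n_cells, collapse = "/"),
              x$mean_count, x$mean_count_spread, x$spread_type))
  print(x$proportions[, c("count", "mean_proportion", "spread")])
  invisible(x)
}

#' @export
tidy.count_aggregate <- function(x, ...) x$proportions

#' @export
glance.count_aggregate <- function(x, ...) {
  tibble(n_replicates = length(x$n_cells), n_cells_total = sum(x$n_cells),
         mean_count = x$mean_count, mean_count_spread = x$mean_count_spread,
         spread_type = x$spread_type)
}

#' Summarize a dose-response series of per-cell intensities
#'
#' For an induction series (one set of per-cell mean-intensity-per-area
#' values per inducer concentration), returns the condition mean, spread and
#' sample size, preserving the input condition order.
#'
#' @param conditions Named list: condition label -> numeric vector of
#'   per-cell mean intensities.
#' @param spread `"sd"` or `"sem"`, as in [aggregate_replicates()].
#' @return Tibble: `condition`, `mean_intensity`, `spread`, `n`.
#' @export
dose_response <- function(conditions, spread = c("sd", "sem")) {
  spread <- match.arg(spread)
  if (!length(conditions)) abort("Need at least one condition.")
  spread_fun <- if (spread == "sd") sd else function(v) sd(v) / sqrt(length(v))
  purrr::imap_dfr(conditions, function(v, nm)
    tibble(condition = nm, mean_intensity = mean(v),
           spread = if (length(v) > 1) spread_fun(v) else 0,
           n = length(v)))
}
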