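#' Reduce pooled points to equally populated bins
#'
#' Sorts the pooled normalized points by relative height `x` and partitions
#' them into `n_bins` contiguous bins of equal population. When the point
#' count is not divisible by `n_bins`, remainder points are assigned to the
#' highest-`x` bins (fixed tie rule so results are reproducible).
#'
#' @param points Tibble with columns `x`, `y` ([normalize_pooled()]).
#' @param n_bins Number of bins (default 15).
#' @return Tibble of class `"binned_curve"`: `bin`, `bin_x` (mean x),
#'   `bin_mean` (mean y), `bin_sd` (SD of y), `bin_n`.
#' @export
bin_equal_population <- function(points, n_bins = 15L) {
  if (!all(c("x", "y") %in% names(points))) {
    abort_input("`points` must have columns `x` and `y`.")
  }
  n_bins <- as.integer(n_bins)
  check_number(n_bins, "n_bins", positive = TRUE)
  N <- nrow(points)
  if (N < n_bins) {
    abort_input(sprintf("Need at least as many points (%d) as bins (%d).", N, n_bins))
  }
  base_n <- N %/% n_bins
  remainder <- N %% n_bins
  counts <- rep(base_n, n_bins)
  if (remainder > 0) {
    counts[(n_bins - remainder + 1L):n_bins] <- base_n + 1L
  }
  ord <- order(points$x)
  bin_id <- rep(seq_len(n_bins), times = counts)

  out <- tibble(
    bin = bin_id,
    x = points$x[ord],
    y = points$y[ord]
  ) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      bin_x = mean(.data$x),
      bin_mean = mean(.data$y),
      bin_sd = sd(.data$y),
      bin_n = dplyr::n(),
      .groups = "drop"
    )
  class(out) <- c("binned_curve", class(out))
  out
}

#' Chi-square agreement of a binned curve with a model shape
#'
#' \deqn{\chi^2 = \sum_{b} \left(\frac{\bar y_b - g(\bar x_b)}{s_b}\right)^2,}
#' where \eqn{g} is the normalized model curve ([model_curve()]) and
#' \eqn{s_b} the per-bin SD of the pooled points. The reported `p` is the
#' lower-tail CDF \eqn{P(X \le \chi^2)} of a chi-square distribution with
#' `dof = n_bins`: *small* p means the bin means sit well inside the scatter,
#' i.e. a good fit; p near 1 flags a model far outside the scatter.
#'
#' @param binned A `"binned_curve"` ([bin_equal_population()]).
#' @param model Model tag.
#' @return One-row tibble: `model`, `chi2`, `dof`, `p`, `n_bins`.
#' @export
chi_square_model <- function(binned, model) {
  stopifnot(inherits(binned, "binned_curve"))
  model <- match_model(model)
  if (any(!is.finite(binned$bin_sd) | binned$bin_sd <= 0)) {
    abort_input(paste(
      "Every bin needs a positive SD to weight the chi-square statistic;",
      "pool more points or use fewer bins."
    ))
  }
  n_bins <- nrow(binned)
  chi2 <- sum(((binned$bin_mean - model_curve(binned$bin_x, model)) /
                 binned$bin_sd)^2)
  tibble(model = model, chi2 = chi2, dof = n_bins,
         p = pchisq(chi2, df = n_bins), n_bins = n_bins)
}

#' Chi-square comparison across several models
#'
#' Applies [chi_square_model()] to each model's own pooled normalization of
#' the same profiles and stacks the reports, sorted by `chi2`. Each model
#' normalizes the data by its own fitted amplitudes before binning, mirroring
#' the per-model panels of a widening-profile comparison figure.
#'
#' @param profiles A `"conduit_profiles"` tibble.
#' @param fits The matching `"wpm_fits"` table.
#' @param models Models to compare (default: all five).
#' @param n_bins Bin count (default 15).
#' @return Tibble of chi-square reports, one row per model, ascending `chi2`.
#' @export
chi_square_table <- function(profiles, fits, models = PROFILE_MODELS,
                             n_bins = 15L) {
  purrr::map(models, function(m) {
    pooled <- normalize_pooled(profiles, fits, model = m)
    chi_square_model(bin_equal_population(pooled, n_bins = n_bins), m)
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$chi2)
}
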