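# Per-plant hydraulic accounting and cohort-level comparative results:
# conductance-height flatness, conductance-versus-carbon cross-plots, and the
# Pareto front in (ln W, ln Omega) space.

#' Per-plant hydraulic cost summary
#'
#' Evaluates, for every plant with converged WPM and power-law fits, the
#' rescaled resistances, conductances, carbon costs and the WPM widening cost
#' with that plant's fitted \eqn{\sigma_M}, \eqn{A}, \eqn{h_M} and
#' \eqn{h_0}. Plants missing either fit are skipped with a warning.
#'
#' @param profiles A `"conduit_profiles"` tibble.
#' @param fits The matching `"wpm_fits"` table (must include `"wpm"` and
#'   `"sqrt_west"` fits).
#' @return Tibble of class `"cost_summary"`, one row per plant: `plant_id`,
#'   `conduit_type`, `h_0`, `h_M`, `sigma_M`, `amplitude_A`, `omega_wpm`,
#'   `omega_pl`, `cond_wpm`, `cond_pl`, `carbon_wpm`, `carbon_pl`,
#'   `widening_w`.
#' @export
summarize_costs <- function(profiles, fits) {
  stopifnot(inherits(profiles, "conduit_profiles"))
  wide <- fits |>
    dplyr::filter(.data$model %in% c("wpm", "sqrt_west"), .data$converged) |>
    dplyr::select("plant_id", "model", "amplitude") |>
    tidyr::pivot_wider(names_from = "model", values_from = "amplitude")
  if (!all(c("wpm", "sqrt_west") %in% names(wide))) {
    wide[setdiff(c("wpm", "sqrt_west"), names(wide))] <- NA_real_
  }
  meta <- profiles |>
    as_tibble() |>
    dplyr::select("plant_id", "conduit_type", "h_0", "h_M") |>
    dplyr::left_join(wide, by = "plant_id")
  missing <- is.na(meta$wpm) | is.na(meta$sqrt_west)
  if (any(missing)) {
    warn(sprintf("Skipping %d plant(s) without converged wpm and sqrt_west fits: %s",
                 sum(missing),
                 paste(utils::head(meta$plant_id[missing], 10), collapse = ", ")))
    meta <- meta[!missing, ]
  }
  out <- meta |>
    dplyr::rename(sigma_M = "wpm", amplitude_A = "sqrt_west") |>
    dplyr::mutate(summary = purrr::pmap(
      list(.data$sigma_M, .data$amplitude_A, .data$h_M, .data$h_0),
      function(sM, A, hM, h0) {
        p <- profile_params(sigma_M = sM, h_M = hM, h_0 = h0, amplitude_A = A)
        tibble(
          omega_wpm = resistance_wpm(p),
          omega_pl = resistance_powerlaw(p),
          cond_wpm = conductance(p, "wpm"),
          cond_pl = conductance(p, "powerlaw"),
          carbon_wpm = carbon_cost(p, "wpm"),
          carbon_pl = carbon_cost(p, "powerlaw"),
          widening_w = widening_cost(p, "wpm")
        )
      }
    )) |>
    tidyr::unnest("summary")
  class(out) <- c("cost_summary", class(out))
  out
}

#' Conductance–height regression
#'
#' Ordinary least squares of \eqn{\ln(\mathrm{Cond}_{WPM})} on
#' \eqn{\ln(h_M)} across the cohort. Under the WPM with basal area growing as
#' \eqn{\sigma_M \propto \sqrt{h_M}}, conductance is height-invariant up to a
#' logarithmic factor, so the slope should be near 0 and \eqn{R^2} near 0.
#'
#' @param costs A `"cost_summary"` tibble (≥ 3 plants).
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `n`.
#' @export
conductance_height_regression <- function(costs) {
  if (nrow(costs) < 3L) abort_input("Need at least 3 plants.")
  if (dplyr::n_distinct(costs$h_M) < 2L) {
    abort_input("All plants have the same height; regression is degenerate.")
  }
  fit <- lm(log(cond_wpm) ~ log(h_M), data = costs)
  s <- summary(fit)
  tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = s$r.squared,
    n = nrow(costs)
  )
}

#' Carbon-matched conductance advantage
#'
#' Cross-plot slopes comparing the WPM against the pure power law across the
#' cohort: a through-origin fit of WPM conductance on power-law conductance
#' (primary statistic, reported both as through-origin OLS and as the
#' geometric-mean slope \eqn{\sqrt{\sum y^2 / \sum x^2}}), and the analogous
#' through-origin OLS slope for the carbon cross-plot. A carbon cross-plot
#' slope near 1 with a conductance slope well above 1 is the signature that
#' the WPM buys extra conductance at no extra carbon.
#'
#' @param costs A `"cost_summary"` tibble (≥ 2 plants).
#' @return One-row tibble: `conductance_slope` (through-origin OLS),
#'   `conductance_slope_gm`, `carbon_slope`, `n`.
#' @export
carbon_matched_conductance_gain <- function(costs) {
  if (nrow(costs) < 2L) abort_input("Need at least 2 plants.")
  to_slope <- function(x, y) sum(x * y) / sum(x^2)
  tibble(
    conductance_slope = to_slope(costs$cond_pl, costs$cond_wpm),
    conductance_slope_gm = sqrt(sum(costs$cond_wpm^2) / sum(costs$cond_pl^2)),
    carbon_slope = to_slope(costs$carbon_pl, costs$carbon_wpm),
    n = nrow(costs)
  )
}

#' Analytic carbon-matched conductance gain
#'
#' For a single plant with relative cutoff \eqn{\varepsilon = h_0/h_M},
#' chooses the power-law amplitude \eqn{A} so its carbon cost equals the
#' WPM's, then returns the conductance ratio
#' \eqn{\mathrm{Cond}_{WPM}/\mathrm{Cond}_{PL} = \Omega_{PL}/\Omega_{WPM}}
#' under that matching:
#' \deqn{2\left(\frac{\sigma_M}{A}\right)^2
#'   \frac{\ln(1/\varepsilon)}{\ln((2-\varepsilon)/\varepsilon)},\quad
#'   \frac{\sigma_M}{A} = \left(\frac{4(1-\varepsilon^{5/4})}
#'   {5\,I(\varepsilon)}\right)^2,}
#' with \eqn{I(\varepsilon) = \int_\varepsilon^1 (t(2-t))^{1/4}\,dt}.
#' Independent of \eqn{\sigma_M} and \eqn{h_M}; as \eqn{\varepsilon \to 0}
#' the prefactor tends to \eqn{2(4/(5 I_0))^4 \approx 1.40}.
#'
#' @param eps Relative cutoff(s) \eqn{h_0/h_M} in (0, 1).
#' @return Conductance gain(s), dimensionless.
#' @export
analytic_conductance_gain <- function(eps) {
  check_numeric_vec(eps, "eps", positive = TRUE)
  if (any(eps >= 1)) abort_domain("`eps` must be below 1.")
  vapply(eps, function(e) {
    I <- integrate(function(t) (t * (2 - t))^0.25, e, 1,
                   rel.tol = 1e-10, subdivisions = 500L)$value
    sM_over_A <- (4 * (1 - e^(5 / 4)) / (5 * I))^2
    2 * sM_over_A^2 * log(1 / e) / log((2 - e) / e)
  }, numeric(1))
}

#' Pareto-front intercept J
#'
#' For a WPM-optimal profile the product \eqn{\Omega\,W} depends only on
#' \eqn{\varepsilon = h_0/h_M} (the \eqn{\sigma_M} and \eqn{h_M} factors
#' cancel), so optimal profiles satisfy
#' \eqn{\ln\Omega = -\ln W + J(\varepsilon)} with
#' \deqn{J(\varepsilon) = \ln\left[\frac{L}{2}\left(\frac{L}{2} -
#'   (1-\varepsilon)\right)\right], \quad
#'   L = \ln\frac{2-\varepsilon}{\varepsilon}.}
#' J varies only logarithmically with \eqn{h_M/h_0}, so the front is nearly a
#' single straight line of slope −1 in (ln W, ln Ω) space.
#'
#' @param eps Relative cutoff(s) in (0, 1).
#' @return J value(s).
#' @export
pareto_J <- function(eps) {
  check_numeric_vec(eps, "eps", positive = TRUE)
  if (any(eps >= 1)) abort_domain("`eps` must be below 1.")
  L <- log((2 - eps) / eps)
  log((L / 2) * (L / 2 - (1 - eps)))
}

#' Pareto front of resistance versus widening cost
#'
#' Places each plant at \eqn{(\ln W, \ln \Omega)} using its fitted WPM
#' parameters, classifies each point as `"optimal"` (no other plant has both
#' lower \eqn{\Omega} and lower \eqn{W}) or `"accessible"` (dominated), and
#' attaches the theoretical front \eqn{\ln\Omega = -\ln W + J(\varepsilon)}
#' traced over the cohort's \eqn{\varepsilon} range. (The `"inaccessible"`
#' zone below the front contains no realizable profiles, so no data point is
#' ever assigned to it.)
#'
#' @param costs A `"cost_summary"` tibble.
#' @return Tibble of class `"pareto_points"`: `plant_id`, `conduit_type`,
#'   `eps`, `ln_W`, `ln_Omega`, `zone`; the front curve is in
#'   `attr(, "front")` (columns `eps`, `ln_W`, `ln_Omega`).
#' @export
pareto_front <- function(costs) {
  if (nrow(costs) < 1L) abort_input("Need at least 1 plant.")
  pts <- costs |>
    as_tibble() |>
    dplyr::transmute(
      plant_id = .data$plant_id,
      conduit_type = .data$conduit_type,
      eps = .data$h_0 / .data$h_M,
      ln_W = log(.data$widening_w),
      ln_Omega = log(.data$omega_wpm)
    )
  n <- nrow(pts)
  dominated <- vapply(seq_len(n), function(i) {
    any(pts$ln_Omega < pts$ln_Omega[i] - 1e-12 &
          pts$ln_W < pts$ln_W[i] - 1e-12)
  }, logical(1))
  pts$zone <- ifelse(dominated, "accessible", "optimal")

  # exact front point below/at each plant, traced over the observed ln W span
  front <- tibble(
    eps = pts$eps,
    ln_W = pts$ln_W,
    ln_Omega = -pts$ln_W + pareto_J(pts$eps)
  ) |>
    dplyr::arrange(.data$ln_W)

  structure(pts, class = c("pareto_points", class(pts)), front = front)
}

#' @export
print.pareto_points <- function(x, ...) {
  cat(sprintf("<pareto_points: %d plants, %d optimal>\n",
              nrow(x), sum(x$zone == "optimal")))
  NextMethod()
}
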