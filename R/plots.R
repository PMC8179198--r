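# ggplot2 views of the main result types. The binned-curve plot uses the
# square-root display transform of the height axis so the near-tip power-law
# region is visible; bars are 3 SD as in the field's profile figures.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a binned universal-profile curve against model predictions
#'
#' @param object A `"binned_curve"` ([bin_equal_population()]).
#' @param models Model curves to overlay (default `"wpm"`).
#' @param sqrt_axis Apply the \eqn{X = \sqrt{x}} display stretch
#'   ([axis_transform()]) to the height axis (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot binned_curve
#' @export
autoplot.binned_curve <- function(object, models = "wpm", sqrt_axis = TRUE, ...) {
  tr <- if (sqrt_axis) axis_transform else identity
  xg <- seq(0, 1, length.out = 200)
  curves <- purrr::map(models, function(m) {
    tibble(model = m, x = tr(xg), y = model_curve(xg, m))
  }) |> purrr::list_rbind()
  dat <- as_tibble(object) |>
    dplyr::mutate(
      x = tr(.data$bin_x),
      ymin = .data$bin_mean - 3 * .data$bin_sd,
      ymax = .data$bin_mean + 3 * .data$bin_sd
    )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$bin_mean)) +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$model),
      linewidth = 0.8
    ) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ymin, ymax = .data$ymax),
                           width = 0.01, linewidth = 0.3) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = if (sqrt_axis) expression(sqrt(h / h[M])) else expression(h / h[M]),
      y = expression(sigma / sigma[model]),
      colour = "model"
    ) +
    ggplot2::theme_minimal()
}

#' Conductance–height flatness plot
#'
#' Log–log scatter of rescaled WPM conductance against plant height with the
#' OLS line; flat means leaves keep their water supply as plants grow taller.
#'
#' @param costs A `"cost_summary"` ([summarize_costs()]).
#' @return A ggplot object.
#' @export
plot_conductance_height <- function(costs) {
  ggplot2::ggplot(costs, ggplot2::aes(x = .data$h_M, y = .data$cond_wpm)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$conduit_type), alpha = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey30", linewidth = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(h[M] ~ (mu * m)),
                  y = expression(Cond[WPM] ~ (mu * m^3)),
                  colour = "conduit type") +
    ggplot2::theme_minimal()
}

#' Conductance and carbon cross-plots (WPM versus power law)
#'
#' @param costs A `"cost_summary"`.
#' @param what `"conductance"` or `"carbon"`.
#' @return A ggplot object with the unit slope (solid) and the fitted
#'   through-origin slope (dashed).
#' @export
plot_model_crossplot <- function(costs, what = c("conductance", "carbon")) {
  what <- match.arg(what)
  if (what == "conductance") {
    dat <- tibble(x = costs$cond_pl, y = costs$cond_wpm,
                  conduit_type = costs$conduit_type)
    labs <- ggplot2::labs(x = expression(Cond[PL] ~ (mu * m^3)),
                          y = expression(Cond[WPM] ~ (mu * m^3)),
                          colour = "conduit type")
  } else {
    dat <- tibble(x = costs$carbon_pl, y = costs$carbon_wpm,
                  conduit_type = costs$conduit_type)
    labs <- ggplot2::labs(x = expression(C[PL] ~ (mu * m^2)),
                          y = expression(C[WPM] ~ (mu * m^2)),
                          colour = "conduit type")
  }
  slope <- sum(dat$x * dat$y) / sum(dat$x^2)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40") +
    ggplot2::geom_abline(slope = slope, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$conduit_type), alpha = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    labs +
    ggplot2::theme_minimal()
}

#' Plot the Pareto front in (ln W, ln Omega) space
#'
#' @param object A `"pareto_points"` ([pareto_front()]).
#' @param ... Unused.
#' @return A ggplot object: per-plant points coloured by conduit type, shaped
#'   by optimality zone, with the theoretical front overlaid.
#' @method autoplot pareto_points
#' @export
autoplot.pareto_points <- function(object, ...) {
  front <- attr(object, "front")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$ln_W, y = .data$ln_Omega)) +
    ggplot2::geom_line(data = front, colour = "grey40", linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$conduit_type,
                                     shape = .data$zone), size = 2) +
    ggplot2::labs(x = expression(ln ~ W), y = expression(ln ~ Omega),
                  colour = "conduit type", shape = "zone") +
    ggplot2::theme_minimal()
}
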