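# Per-plant one-parameter least-squares fitting of the widening models.
#
# Every model is sigma(h) = z * g(h/h_M) with a single amplitude z (um^2) and
# known shape g (model_curve). The fit minimizes the unweighted sum of squared
# residuals in area space, as in the original analysis. Robustness protocol:
# a gradient-based optimizer (nlminb) started from a grid of amplitudes
# spanning 0.25x-4x the basal-most measured area, cross-checked with a
# derivative-free golden-section search (optimize); the two must agree to
# 1e-4 relative for a fit to be accepted.

AMPLITUDE_START_FACTORS <- c(0.25, 0.5, 1, 2, 4)

#' Fit one widening model to one plant
#'
#' @param heights Distances from the stem tip (µm), at least 3.
#' @param areas Measured mean lumen areas (µm²), same length.
#' @param h_M Plant height (µm); defaults to `max(heights)`.
#' @param model One of `"wpm"`, `"uniform"`, `"sqrt_west"`, `"linear_savage"`,
#'   `"wpm_avg_anchor"`. The `"wpm_avg_anchor"` variant does not fit: its
#'   amplitude is the mean area of the two basal-most points, anchoring the
#'   WPM curve to the base of the plant.
#' @return One-row tibble: `model`, `amplitude` (µm²), `sse`, `n_points`,
#'   `converged`, `optimizer_agreement` (relative disagreement between the
#'   two optimizers; 0 for the anchored variant).
#' @export
#' @examples
#' h <- seq(1e4, 1e6, length.out = 12)
#' y <- 800 * universal_curve(h / 1e6)
#' fit_plant(h, y, model = "wpm")
fit_plant <- function(heights, areas, h_M = max(heights), model = "wpm") {
  model <- match_model(model)
  check_numeric_vec(heights, "heights", positive = TRUE)
  check_numeric_vec(areas, "areas", positive = TRUE)
  if (length(heights) != length(areas)) {
    abort_input("`heights` and `areas` must have the same length.")
  }
  n <- length(heights)
  failed <- tibble(model = model, amplitude = NA_real_, sse = NA_real_,
                   n_points = n, converged = FALSE,
                   optimizer_agreement = NA_real_)
  if (n < 3L) return(failed)

  ord <- order(heights)
  heights <- heights[ord]
  areas <- areas[ord]
  x <- heights / h_M
  if (any(x > 1 + 1e-12)) abort_input("`heights` exceed `h_M`.")
  x <- pmin(x, 1)

  if (model == "wpm_avg_anchor") {
    amp <- mean(areas[c(n - 1L, n)])
    g <- model_curve(x, model)
    return(tibble(model = model, amplitude = amp,
                  sse = sum((amp * g - areas)^2), n_points = n,
                  converged = TRUE, optimizer_agreement = 0))
  }

  g <- model_curve(x, model)
  sse_of <- function(z) sum((z * g - areas)^2)
  basal <- areas[n]
  starts <- AMPLITUDE_START_FACTORS * basal

  runs <- lapply(starts, function(z0) {
    tryCatch(nlminb(z0, sse_of, lower = 1e-12),
             error = function(e) NULL)
  })
  runs <- Filter(function(r) !is.null(r) && r$convergence == 0, runs)
  if (length(runs) == 0L) return(failed)
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "objective"))]]

  # derivative-free cross-check over a wide bracket
  bracket <- c(min(starts) / 16, max(starts) * 16)
  alt <- optimize(sse_of, interval = bracket, tol = 1e-12)
  agreement <- abs(best$par - alt$minimum) /
    max(abs(best$par), abs(alt$minimum))

  tibble(
    model = model, amplitude = best$par, sse = best$objective,
    n_points = n, converged = agreement <= 1e-4,
    optimizer_agreement = agreement
  )
}

#' Fit widening models across a cohort
#'
#' Runs [fit_plant()] for every plant and requested model, returning a tidy
#' fit table.
#'
#' @param profiles A `"conduit_profiles"` tibble ([as_conduit_profiles()]).
#' @param models Character vector of model tags (default: all five).
#' @return A tibble of class `"wpm_fits"`, one row per plant × model, with
#'   the [fit_plant()] columns plus `plant_id`, `conduit_type`, `h_0`, `h_M`.
#' @export
fit_profiles <- function(profiles, models = PROFILE_MODELS) {
  stopifnot(inherits(profiles, "conduit_profiles"))
  models <- vapply(models, match_model, character(1))
  out <- profiles |>
    as_tibble() |>
    dplyr::select("plant_id", "conduit_type", "h_0", "h_M", "data") |>
    tidyr::expand_grid(.model = models) |>
    dplyr::mutate(
      fit = purrr::map2(.data$data, .data$.model,
                        ~ fit_plant(.x$height_um, .x$area_um2,
                                    h_M = max(.x$height_um), model = .y))
    ) |>
    dplyr::select(-"data", -".model") |>
    tidyr::unnest("fit") |>
    dplyr::relocate("plant_id", "model")
  class(out) <- c("wpm_fits", class(out))
  out
}

#' @export
print.wpm_fits <- function(x, ...) {
  cat(sprintf("<wpm_fits: %d fits, %d plants, models: %s>\n",
              nrow(x), dplyr::n_distinct(x$plant_id),
              paste(unique(x$model), collapse = ", ")))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cohort fit table
#'
#' @param x A `"wpm_fits"` tibble.
#' @param ... Unused.
#' @return A plain tibble of per-fit results.
#' @method tidy wpm_fits
#' @export
tidy.wpm_fits <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a cohort fit table
#'
#' @param x A `"wpm_fits"` tibble.
#' @param ... Unused.
#' @return Tibble with plant/model counts, convergence fraction and total SSE.
#' @export
#' @method glance wpm_fits
glance.wpm_fits <- function(x, ...) {
  tibble(
    n_plants = dplyr::n_distinct(x$plant_id),
    n_models = dplyr::n_distinct(x$model),
    n_fits = nrow(x),
    prop_converged = mean(x$converged),
    total_sse = sum(x$sse[x$converged], na.rm = TRUE)
  )
}

#' Pool normalized profile points across plants
#'
#' Normalizes each plant's measurements by its fitted model amplitude
#' (\eqn{y = \sigma / \hat z}) and plant height (\eqn{x = h/h_M}), pooling all
#' plants into one point cloud on which the universal curve can be tested.
#' Plants without a converged fit for the chosen model are excluded with a
#' warning.
#'
#' @param profiles A `"conduit_profiles"` tibble.
#' @param fits The matching `"wpm_fits"` table.
#' @param model Which model's amplitudes to normalize by.
#' @return Tibble with columns `plant_id`, `x`, `y`.
#' @export
normalize_pooled <- function(profiles, fits, model = "wpm") {
  stopifnot(inherits(profiles, "conduit_profiles"))
  model <- match_model(model)
  keep <- fits |>
    dplyr::filter(.data$model == !!model, .data$converged) |>
    dplyr::select("plant_id", "amplitude")
  dropped <- setdiff(profiles$plant_id, keep$plant_id)
  if (length(dropped) > 0) {
    warn(sprintf("Excluding %d plant(s) without a converged '%s' fit: %s",
                 length(dropped), model,
                 paste(utils::head(dropped, 10), collapse = ", ")))
  }
  profiles |>
    as_tibble() |>
    dplyr::inner_join(keep, by = "plant_id") |>
    dplyr::mutate(points = purrr::pmap(
      list(.data$data, .data$h_M, .data$amplitude),
      function(d, hM, amp) tibble(x = d$height_um / hM, y = d$area_um2 / amp)
    )) |>
    dplyr::select("plant_id", "points") |>
    tidyr::unnest("points")
}
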