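#' The universal conduit-widening curve F(x)
#'
#' The scaling function of the widened pipe model (WPM),
#' \deqn{F(x) = \sqrt{x\,(2 - x)},}
#' giving relative conduit lumen area \eqn{\sigma/\sigma_M} as a function of
#' relative distance from the stem tip \eqn{x = h/h_M}. The curve is the
#' stationary profile of the resistance–widening trade-off: near the tip it
#' behaves as \eqn{\sqrt{2x}} (so conduit *diameter* grows as \eqn{h^{0.25}}),
#' and at the base it falls about 29.3% below that tip-matched power law.
#'
#' @param x Numeric vector of relative heights in `[0, 1]`.
#' @return `F(x)`, dimensionless, same length as `x`; `F(1) = 1`.
#' @export
#' @examples
#' universal_curve(c(0, 0.5, 1))
universal_curve <- function(x) {
  check_numeric_vec(x, "x")
  if (any(x < 0 | x > 1)) {
    abort_domain("`x` must lie in [0, 1]: relative height h/h_M.")
  }
  sqrt(x * (2 - x))
}

#' WPM conduit lumen area at a given height
#'
#' Evaluates the closed-form widened-pipe profile
#' \eqn{\sigma(h) = \sigma_M F(h/h_M)} (µm²) at distances `h` from the stem
#' tip, restricted to the physical domain `[h_0, h_M]`.
#'
#' @param h Distances from the stem tip (µm), within `[h_0, h_M]`.
#' @param params A [profile_params()] object.
#' @return Lumen areas (µm²).
#' @export
#' @examples
#' p <- profile_params(sigma_M = 100, h_M = 1e6, h_0 = 400)
#' wpm_area(c(5e5, 1e6), p)
wpm_area <- function(h, params) {
  stopifnot(inherits(params, "profile_params"))
  check_numeric_vec(h, "h")
  if (any(h < params$h_0 | h > params$h_M)) {
    abort_domain("`h` must lie within [h_0, h_M].")
  }
  params$sigma_M * universal_curve(h / params$h_M)
}

#' Competitor conduit profiles
#'
#' The three competing widening models fitted alongside the WPM:
#' * `"uniform"` — the classical uniform pipe, \eqn{\sigma(h) = A};
#' * `"sqrt_west"` — square-root widening, \eqn{\sigma(h) = A \sqrt{h/h_M}}
#'   (area exponent 1/2, i.e. diameter \eqn{\propto h^{1/4}} everywhere);
#' * `"linear_savage"` — linear area widening, \eqn{\sigma(h) = A\, h/h_M}.
#'
#' @param h Distances from the stem tip (µm), within `[h_0, h_M]`.
#' @param model One of `"uniform"`, `"sqrt_west"`, `"linear_savage"`.
#' @param params A [profile_params()] with `amplitude_A` set.
#' @return Lumen areas (µm²).
#' @export
competitor_area <- function(h, model, params) {
  stopifnot(inherits(params, "profile_params"))
  model <- match_model(model, c("uniform", "sqrt_west", "linear_savage"))
  check_numeric_vec(h, "h")
  if (any(h < params$h_0 | h > params$h_M)) {
    abort_domain("`h` must lie within [h_0, h_M].")
  }
  A <- need_amplitude(params)
  A * model_curve(h / params$h_M, model)
}

#' Normalized model curve
#'
#' The dimensionless shape \eqn{g(x)} of each profile model, i.e. the curve a
#' plant's points fall on once area is normalized by the model amplitude and
#' height by \eqn{h_M}: `uniform` → 1, `sqrt_west` → \eqn{\sqrt{x}},
#' `linear_savage` → \eqn{x}, `wpm` / `wpm_avg_anchor` → \eqn{F(x)}.
#'
#' @param x Relative heights in `[0, 1]`.
#' @param model Model tag.
#' @return Dimensionless curve values.
#' @export
#' @examples
#' model_curve(0.25, "sqrt_west")
model_curve <- function(x, model) {
  model <- match_model(model)
  check_numeric_vec(x, "x")
  if (any(x < 0 | x > 1)) abort_domain("`x` must lie in [0, 1].")
  switch(model,
    uniform        = rep(1, length(x)),
    sqrt_west      = sqrt(x),
    linear_savage  = x,
    wpm            = ,
    wpm_avg_anchor = sqrt(x * (2 - x))
  )
}

#' Display-axis transform
#'
#' Square-root stretch of the normalized height axis, \eqn{X = x^{0.5}}, used
#' in widening-profile figures to spread out the near-tip region where the
#' power-law behaviour lives. Display only; never used in fitting or binning.
#'
#' @param x Normalized heights, `x >= 0`.
#' @return `sqrt(x)`.
#' @export
axis_transform <- function(x) {
  check_numeric_vec(x, "x")
  if (any(x < 0)) abort_domain("`x` must be non-negative.")
  sqrt(x)
}
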