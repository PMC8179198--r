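# Closed-form hydraulic accounting for the WPM and competitor profiles.
#
# All resistances are *rescaled* resistances Omega = R / (mu K): the
# Hagen-Poiseuille resistance of the whole tip-to-base path, Omega =
# integral over [h0, hM] of sigma(h)^-2 dh, stripped of viscosity mu and the
# circular-section factor K = 8*pi so only geometry remains. Units are
# therefore um^-3 and conductances (their reciprocals) um^3.

#' Rescaled hydraulic resistance of the WPM profile
#'
#' \deqn{\Omega_{WPM} = \int_{h_0}^{h_M} \sigma_{WPM}^{-2}\,dh
#'   = \frac{h_M}{2\sigma_M^2}\,\ln\frac{2 h_M - h_0}{h_0}.}
#'
#' @param params A [profile_params()].
#' @return Rescaled resistance (µm⁻³).
#' @export
#' @examples
#' resistance_wpm(profile_params(1, 1, 1e-3)) # 0.5 * log(1999)
resistance_wpm <- function(params) {
  stopifnot(inherits(params, "profile_params"))
  with(params, h_M / (2 * sigma_M^2) * log((2 * h_M - h_0) / h_0))
}

#' Rescaled hydraulic resistance of the pure power-law profile
#'
#' For \eqn{\sigma(h) = A\sqrt{h/h_M}}:
#' \deqn{\Omega_{PL} = \frac{h_M}{A^2}\,\ln\frac{h_M}{h_0}.}
#'
#' @inheritParams resistance_wpm
#' @return Rescaled resistance (µm⁻³).
#' @export
resistance_powerlaw <- function(params) {
  stopifnot(inherits(params, "profile_params"))
  A <- need_amplitude(params)
  params$h_M / A^2 * log(params$h_M / params$h_0)
}

#' Rescaled hydraulic resistance of the uniform pipe
#'
#' For a constant lumen area `amplitude_A`:
#' \eqn{\Omega = (h_M - h_0)/A^2}.
#'
#' @inheritParams resistance_wpm
#' @return Rescaled resistance (µm⁻³).
#' @export
resistance_uniform <- function(params) {
  stopifnot(inherits(params, "profile_params"))
  A <- need_amplitude(params)
  (params$h_M - params$h_0) / A^2
}

#' Resistance ratio of power law to WPM
#'
#' \deqn{\frac{\Omega_{PL}}{\Omega_{WPM}} =
#'   2\left(\frac{\sigma_M}{A}\right)^2
#'   \frac{\ln(h_M/h_0)}{\ln\!\big((2h_M - h_0)/h_0\big)}.}
#' Exceeds 1 whenever \eqn{\sigma_M = A}: at equal basal area the WPM profile
#' always conducts better than the power law. Tends to 2 as
#' \eqn{h_M/h_0 \to \infty}.
#'
#' @inheritParams resistance_wpm
#' @return Dimensionless ratio.
#' @export
resistance_ratio <- function(params) {
  stopifnot(inherits(params, "profile_params"))
  A <- need_amplitude(params)
  with(params,
    2 * (sigma_M / A)^2 * log(h_M / h_0) / log((2 * h_M - h_0) / h_0)
  )
}

#' Widening cost
#'
#' The penalty on rapid basipetal widening,
#' \eqn{W = \int_{h_0}^{h_M} \dot\sigma^2(h)\,dh} (quadratic-term convention,
#' coefficient fixed to 1), a proxy for embolism risk and construction cost of
#' fast-widening conduits. Closed forms (validated against adaptive quadrature
#' of the defining integrand):
#' * WPM: \eqn{(\sigma_M^2/h_M)\,[\tfrac12\ln\frac{2-\varepsilon}{\varepsilon}
#'   - (1-\varepsilon)]} with \eqn{\varepsilon = h_0/h_M};
#' * power law: \eqn{A^2/(4 h_M)\,\ln(h_M/h_0)};
#' * uniform: 0 (no widening at all).
#'
#' @inheritParams resistance_wpm
#' @param profile One of `"wpm"`, `"powerlaw"`, `"uniform"`.
#' @return Widening cost (µm³ under the unit-coefficient convention).
#' @export
#' @examples
#' widening_cost(profile_params(1, 1, 1e-3), "wpm")
widening_cost <- function(params, profile = c("wpm", "powerlaw", "uniform")) {
  stopifnot(inherits(params, "profile_params"))
  profile <- match.arg(profile)
  eps <- params$h_0 / params$h_M
  switch(profile,
    wpm = params$sigma_M^2 / params$h_M *
      (0.5 * log((2 - eps) / eps) - (1 - eps)),
    powerlaw = need_amplitude(params)^2 / (4 * params$h_M) * log(1 / eps),
    uniform = 0
  )
}

#' Carbon (wall construction) cost
#'
#' Proportional to the external surface area of the conduit, taken per unit
#' wall thickness: \eqn{C = \int_{h_0}^{h_M} 2\pi r(h)\,dh
#' = 2\sqrt{\pi} \int_{h_0}^{h_M} \sqrt{\sigma(h)}\,dh} (µm²).
#' The power-law branch has the closed form
#' \deqn{C_{PL} = \tfrac{8}{5}\,h_M\sqrt{\pi A}\,
#'   \big(1 - (h_0/h_M)^{5/4}\big),}
#' the WPM branch is evaluated by adaptive quadrature of
#' \eqn{2 h_M \sqrt{\pi\sigma_M}\int_\varepsilon^1 (t(2-t))^{1/4} dt}
#' (no elementary antiderivative), and the uniform branch is
#' \eqn{2\sqrt{\pi A}\,(h_M - h_0)}.
#'
#' @inheritParams widening_cost
#' @return Carbon cost (µm², surface-area-proportional).
#' @export
carbon_cost <- function(params, profile = c("wpm", "powerlaw", "uniform")) {
  stopifnot(inherits(params, "profile_params"))
  profile <- match.arg(profile)
  eps <- params$h_0 / params$h_M
  switch(profile,
    wpm = {
      I <- integrate(function(t) (t * (2 - t))^0.25, eps, 1,
                     rel.tol = 1e-10, subdivisions = 500L)$value
      2 * params$h_M * sqrt(pi * params$sigma_M) * I
    },
    powerlaw = {
      A <- need_amplitude(params)
      8 / 5 * params$h_M * sqrt(pi * A) * (1 - eps^(5 / 4))
    },
    uniform = {
      A <- need_amplitude(params)
      2 * sqrt(pi * A) * (params$h_M - params$h_0)
    }
  )
}

#' Whole-path rescaled conductance
#'
#' Reciprocal of the corresponding rescaled resistance (µm³); the quantity
#' that stays approximately height-invariant across plants under the WPM.
#'
#' @inheritParams widening_cost
#' @param profile One of `"wpm"`, `"powerlaw"`, `"uniform"`.
#' @return Conductance (µm³).
#' @export
conductance <- function(params, profile = c("wpm", "powerlaw", "uniform")) {
  profile <- match.arg(profile)
  1 / switch(profile,
    wpm = resistance_wpm(params),
    powerlaw = resistance_powerlaw(params),
    uniform = resistance_uniform(params)
  )
}

#' All hydraulic quantities for one parameter set
#'
#' Convenience wrapper returning the rescaled resistance, widening cost,
#' carbon cost and conductance of the WPM profile as a one-row tibble.
#'
#' @inheritParams resistance_wpm
#' @return A tibble with columns `omega`, `widening_cost`, `carbon_cost`,
#'   `conductance`.
#' @export
hydraulic_quantities <- function(params) {
  omega <- resistance_wpm(params)
  tibble(
    omega = omega,
    widening_cost = widening_cost(params, "wpm"),
    carbon_cost = carbon_cost(params, "wpm"),
    conductance = 1 / omega
  )
}
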