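# Quadrature oracles: every hydraulic quantity recomputed by adaptive
# quadrature of its *defining* integrand, independent of the closed forms in
# the package. Profiles and their derivatives are written out directly here.

profile_sigma <- function(h, params, profile) {
  x <- h / params$h_M
  switch(profile,
    wpm = params$sigma_M * sqrt(x * (2 - x)),
    powerlaw = params$amplitude_A * sqrt(x),
    uniform = rep(params$amplitude_A, length(h))
  )
}

profile_sigma_dot <- function(h, params, profile) {
  x <- h / params$h_M
  switch(profile,
    wpm = params$sigma_M / params$h_M * (1 - x) / sqrt(x * (2 - x)),
    powerlaw = params$amplitude_A / (2 * params$h_M * sqrt(x)),
    uniform = rep(0, length(h))
  )
}

# Quadrature is done in the scaled coordinate x = h/h_M (substitution
# dh = h_M dx) so integrate() sees a well-conditioned unit interval even for
# kilometre-scale plants with millimetre cutoffs.
oracle_resistance <- function(params, profile) {
  params$h_M * integrate(
    function(x) 1 / profile_sigma(x * params$h_M, params, profile)^2,
    params$h_0 / params$h_M, 1, rel.tol = 1e-12, abs.tol = 0, subdivisions = 2000L
  )$value
}

oracle_widening <- function(params, profile) {
  params$h_M * integrate(
    function(x) profile_sigma_dot(x * params$h_M, params, profile)^2,
    params$h_0 / params$h_M, 1, rel.tol = 1e-12, abs.tol = 0, subdivisions = 2000L
  )$value
}

oracle_carbon <- function(params, profile) {
  params$h_M * integrate(
    function(x) 2 * sqrt(pi * profile_sigma(x * params$h_M, params, profile)),
    params$h_0 / params$h_M, 1, rel.tol = 1e-12, abs.tol = 0, subdivisions = 2000L
  )$value
}

# Exact least-squares amplitude for the linear-in-amplitude models:
# independent closed-form oracle for fit_plant.
exact_amplitude <- function(heights, areas, h_M, model) {
  g <- model_curve(heights / h_M, model)
  sum(g * areas) / sum(g^2)
}

# A small noiseless cohort generated straight from the model formulas
# (bypassing the stochastic generator) for exact-recovery tests.
noiseless_profile <- function(sigma_M = 800, h_M = 1e6, model = "wpm",
                              n = 15, conduit_type = "vessel",
                              plant_id = "p1") {
  h <- sampling_heights(h_M)
  if (length(h) > n) h <- h[round(seq(1, length(h), length.out = n))]
  area <- sigma_M * model_curve(h / h_M, model)
  tibble::tibble(
    plant_id = plant_id, species = "Testus plantus", organ = "stem",
    conduit_type = conduit_type,
    height_um = h, diameter_um = 2 * sqrt(area / pi)
  )
}
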