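# Builds a cost table directly from chosen parameters (bypassing fitting) by
# faking converged fits, so analytic relationships can be checked exactly.
costs_from_params <- function(sigma_M, A, h_M, h_0, type = "vessel") {
  n <- length(sigma_M)
  profiles <- as_conduit_profiles(purrr::list_rbind(purrr::map(seq_len(n), function(i) {
    h <- c(h_0[i] * 2, h_M[i] / 2, h_M[i])
    tibble::tibble(
      plant_id = sprintf("p%02d", i), species = "T t", organ = "stem",
      conduit_type = type[min(i, length(type))],
      height_um = h,
      diameter_um = 2 * sqrt(sigma_M[i] * universal_curve(h / h_M[i]) / pi)
    )
  })))
  profiles$h_0 <- h_0 # override lookup with the requested cutoffs
  fits <- tibble::tibble(
    plant_id = rep(profiles$plant_id, 2),
    model = rep(c("wpm", "sqrt_west"), each = n),
    amplitude = c(sigma_M, A),
    converged = TRUE
  )
  summarize_costs(profiles, fits)
}

test_that("per-plant cost summaries reproduce the closed-form identities", {
  costs <- costs_from_params(sigma_M = 3, A = 3, h_M = 1000, h_0 = 1)
  expect_equal(costs$cond_wpm / costs$cond_pl, 2 * log(1000) / log(1999),
               tolerance = 1e-10)
  expect_equal(costs$cond_wpm * costs$omega_wpm, 1, tolerance = 1e-12)
  p <- profile_params(3, 1000, 1, amplitude_A = 3)
  expect_equal(costs$carbon_wpm, carbon_cost(p, "wpm"), tolerance = 1e-10)
  expect_equal(costs$widening_w, widening_cost(p, "wpm"), tolerance = 1e-10)
  # scaling all lengths by 10 at fixed areas scales omega by 10
  costs10 <- costs_from_params(sigma_M = 3, A = 3, h_M = 10000, h_0 = 10)
  expect_equal(costs10$omega_wpm, 10 * costs$omega_wpm, tolerance = 1e-10)
})

test_that("plants missing a converged fit are skipped with a warning", {
  costs <- costs_from_params(sigma_M = c(1, 2), A = c(1, 2),
                             h_M = c(1e5, 1e6), h_0 = c(400, 400))
  expect_equal(nrow(costs), 2)
  cohort <- generate_cohort(cohort_spec(n_plants = 3, seed = 6L))
  fits <- fit_profiles(cohort$profiles, c("wpm", "sqrt_west"))
  fits$converged[fits$plant_id == fits$plant_id[1]] <- FALSE
  expect_warning(out <- summarize_costs(cohort$profiles, fits), "Skipping 1")
  expect_equal(nrow(out), 2)
})

test_that("conductance is height-invariant when basal area grows as sqrt(h_M)", {
  h_M <- 10^seq(5, 8, length.out = 24)
  costs <- costs_from_params(sigma_M = 1.5 * sqrt(h_M), A = 1.5 * sqrt(h_M),
                             h_M = h_M, h_0 = rep(400, 24))
  reg <- conductance_height_regression(costs)
  expect_lt(abs(reg$slope), 0.15) # only the slowly varying log(h_M) factor remains
  # constant sigma_M: conductance must fall essentially in proportion to height
  costs_const <- costs_from_params(sigma_M = rep(2000, 24), A = rep(2000, 24),
                                   h_M = h_M, h_0 = rep(400, 24))
  reg_const <- conductance_height_regression(costs_const)
  expect_equal(reg_const$slope, -1, tolerance = 0.15)
  expect_gt(reg_const$r_squared, 0.99)
  expect_lt(abs(reg$slope), abs(reg_const$slope) / 5)
})

test_that("duplicating every plant leaves R^2 unchanged", {
  h_M <- 10^seq(5, 7, length.out = 10)
  costs <- costs_from_params(sigma_M = 1.5 * sqrt(h_M), A = 1.5 * sqrt(h_M),
                             h_M = h_M, h_0 = rep(400, 10))
  doubled <- dplyr::bind_rows(costs, dplyr::mutate(
    costs, plant_id = paste0(plant_id, "_b")))
  expect_equal(conductance_height_regression(doubled)$r_squared,
               conductance_height_regression(costs)$r_squared,
               tolerance = 1e-10)
  expect_error(conductance_height_regression(costs[1:2, ]),
               class = "widenedpipe_input_error")
})

test_that("carbon-matched amplitudes give unit carbon slope and the analytic gain", {
  eps <- 1e-4
  h_M <- c(1e6, 3e6, 1e7)
  sigma_M <- 1.5 * sqrt(h_M)
  # choose A so carbon costs match exactly: A/sigma_M = (5 I /(4(1-eps^(5/4))))^2
  I <- integrate(function(t) (t * (2 - t))^0.25, eps, 1, rel.tol = 1e-12)$value
  A <- sigma_M * (5 * I / (4 * (1 - eps^(5 / 4))))^2
  costs <- costs_from_params(sigma_M, A, h_M, h_0 = eps * h_M)
  gain <- carbon_matched_conductance_gain(costs)
  expect_equal(gain$carbon_slope, 1, tolerance = 1e-8)
  expect_gt(gain$conductance_slope, 1)
  expect_equal(gain$conductance_slope, analytic_conductance_gain(eps),
               tolerance = 1e-6)
  expect_equal(gain$conductance_slope, gain$conductance_slope_gm,
               tolerance = 1e-6) # identical-ratio cohort: both slopes agree
})

test_that("the analytic carbon-matched gain approaches ~1.40 for small cutoffs", {
  # 2 * (4/(5 I0))^4 * ln(1/eps)/ln(2/eps) with I0 = 0.874019
  expect_equal(analytic_conductance_gain(1e-4), 1.3056, tolerance = 1e-3)
  expect_equal(analytic_conductance_gain(1e-8) * log(2e8) / log(1e8),
               2 * (4 / (5 * 0.8740192))^4, tolerance = 1e-4)
  expect_true(all(diff(analytic_conductance_gain(10^seq(-2, -8))) > 0))
})

test_that("Omega * W for optimal profiles depends only on h_0/h_M", {
  eps <- 1e-3
  prods <- c()
  for (sigma_M in c(1, 10, 100)) {
    for (h_M in c(1e5, 1e6, 1e8)) {
      p <- profile_params(sigma_M, h_M, eps * h_M)
      prods <- c(prods, resistance_wpm(p) * widening_cost(p, "wpm"))
    }
  }
  expect_equal(prods, rep(prods[1], 9), tolerance = 1e-12)
  expect_equal(prods[1], 10.645, tolerance = 1e-4)
  expect_equal(pareto_J(eps), log(prods[1]), tolerance = 1e-12)
  expect_equal(pareto_J(eps), 2.3651, tolerance = 1e-4)
})

test_that("J varies slowly across the empirical cutoff range", {
  J <- pareto_J(10^seq(-5.5, -2, length.out = 30))
  expect_gt(min(J), 1.4)
  expect_lt(max(J), 3.8)
  expect_lt(max(abs(diff(J))), 0.2)
})

test_that("Pareto classification is correct, idempotent and order-independent", {
  # plant 2 (vessel, small cutoff ratio, high J) is strictly dominated by
  # plant 3 (tracheid, larger cutoff ratio, lower J): both lower Omega and W
  costs <- costs_from_params(
    sigma_M = c(4000, 554, 653, 60),
    A = c(4000, 554, 653, 60),
    h_M = c(1e7, 1e6, 1e6, 1e7),
    h_0 = c(400, 400, 4000, 4000),
    type = c("vessel", "vessel", "tracheid", "tracheid")
  )
  pp <- pareto_front(costs)
  expect_equal(pp$zone[2], "accessible")
  expect_setequal(unique(pp$zone), c("optimal", "accessible"))
  # a dominated point: strictly higher omega and W than some other plant
  for (i in which(pp$zone == "accessible")) {
    expect_true(any(pp$ln_Omega < pp$ln_Omega[i] & pp$ln_W < pp$ln_W[i]))
  }
  shuffled <- pareto_front(costs[c(3, 1, 4, 2), ])
  expect_equal(
    shuffled$zone[match(pp$plant_id, shuffled$plant_id)], pp$zone
  )
  # single plant is trivially optimal
  single <- pareto_front(costs[1, ])
  expect_equal(single$zone, "optimal")
  # narrow-conduit tracheid plants: higher resistance, lower widening cost
  expect_gt(mean(pp$ln_Omega[pp$conduit_type == "tracheid"]),
            mean(pp$ln_Omega[pp$conduit_type == "vessel"]))
  expect_lt(mean(pp$ln_W[pp$conduit_type == "tracheid"]),
            mean(pp$ln_W[pp$conduit_type == "vessel"]))
  # the theoretical front sits at or below every realized point
  front <- attr(pp, "front")
  expect_equal(front$ln_Omega, -front$ln_W + pareto_J(front$eps))
})

test_that("synthetic cohorts cluster by conduit type on the front", {
  cohort <- generate_cohort(cohort_spec(seed = 11L))
  fits <- fit_profiles(cohort$profiles, c("wpm", "sqrt_west"))
  pp <- pareto_front(summarize_costs(cohort$profiles, fits))
  expect_gt(mean(pp$ln_Omega[pp$conduit_type == "tracheid"]),
            mean(pp$ln_Omega[pp$conduit_type == "vessel"]))
  expect_lt(mean(pp$ln_W[pp$conduit_type == "tracheid"]),
            mean(pp$ln_W[pp$conduit_type == "vessel"]))
})
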