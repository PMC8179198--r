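test_that("WPM resistance matches its closed form and quadrature", {
  p <- profile_params(1, 1, 1e-3)
  expect_equal(resistance_wpm(p), 0.5 * log(1999), tolerance = 1e-12)
  expect_equal(resistance_wpm(p), oracle_resistance(p, "wpm"),
               tolerance = 1e-8)
  # sigma_M^-2 scaling
  p2 <- profile_params(2, 1, 1e-3)
  expect_equal(resistance_wpm(p2), resistance_wpm(p) / 4, tolerance = 1e-12)
  # h_0 -> h_M limit stays small and positive
  p3 <- profile_params(1, 1, 1 - 1e-9)
  expect_gt(resistance_wpm(p3), 0)
  expect_lt(resistance_wpm(p3), 1e-6)
})

test_that("power-law and uniform resistances match closed forms and quadrature", {
  p <- profile_params(1, 1, 1e-3, amplitude_A = 1)
  expect_equal(resistance_powerlaw(p), log(1000), tolerance = 1e-12)
  expect_equal(resistance_powerlaw(p), oracle_resistance(p, "powerlaw"),
               tolerance = 1e-8)
  expect_equal(resistance_uniform(p), 1 - 1e-3, tolerance = 1e-12)
  expect_equal(resistance_uniform(p), oracle_resistance(p, "uniform"),
               tolerance = 1e-8)
  pA2 <- profile_params(1, 1, 1e-3, amplitude_A = 2)
  expect_equal(resistance_powerlaw(pA2), resistance_powerlaw(p) / 4,
               tolerance = 1e-12)
})

test_that("resistance ratio follows its closed form and limits", {
  p <- profile_params(1, 1, 1e-3, amplitude_A = 1)
  expect_equal(resistance_ratio(p), 2 * log(1000) / log(1999),
               tolerance = 1e-12)
  expect_equal(resistance_ratio(p), 1.8177, tolerance = 1e-4)
  expect_equal(resistance_ratio(p),
               resistance_powerlaw(p) / resistance_wpm(p), tolerance = 1e-10)
  # (sigma_M/A)^2 scaling
  ph <- profile_params(1 / sqrt(2), 1, 1e-3, amplitude_A = 1)
  expect_equal(resistance_ratio(ph), resistance_ratio(p) / 2,
               tolerance = 1e-12)
  # ratio -> 2 (from below, logarithmically) as h_M/h_0 -> infinity
  ratios <- vapply(c(1e-6, 1e-12, 1e-30),
                   function(e) resistance_ratio(profile_params(1, 1, e, amplitude_A = 1)),
                   numeric(1))
  expect_true(all(diff(ratios) > 0))
  expect_true(all(ratios < 2))
  expect_equal(ratios[3], 2, tolerance = 0.02)
  # > 1 whenever sigma_M = A
  for (eps in 10^seq(-6, -1)) {
    expect_gt(resistance_ratio(profile_params(1, 1, eps, amplitude_A = 1)), 1)
  }
})

test_that("widening cost matches the quadrature oracle of its definition", {
  p <- profile_params(1, 1, 1e-3, amplitude_A = 1)
  expect_equal(widening_cost(p, "uniform"), 0)
  w <- widening_cost(p, "wpm")
  expect_equal(w, oracle_widening(p, "wpm"), tolerance = 1e-8)
  expect_equal(w, 2.8012, tolerance = 1e-4)
  expect_equal(widening_cost(p, "powerlaw"), oracle_widening(p, "powerlaw"),
               tolerance = 1e-8)
  p2 <- profile_params(2, 1, 1e-3)
  expect_equal(widening_cost(p2, "wpm"), 4 * w, tolerance = 1e-12)
})

test_that("carbon cost matches the quadrature oracle and closed-form limits", {
  p0 <- profile_params(1, 1, 1e-8, amplitude_A = 1)
  expect_equal(carbon_cost(p0, "powerlaw"), 8 / 5 * sqrt(pi), tolerance = 1e-6)
  expect_equal(carbon_cost(p0, "wpm"), 3.098317, tolerance = 1e-5)
  p <- profile_params(3, 2, 1e-3, amplitude_A = 5)
  for (prof in c("wpm", "powerlaw", "uniform")) {
    expect_equal(carbon_cost(p, prof), oracle_carbon(p, prof),
                 tolerance = 1e-8, label = prof)
  }
  # linear in h_M at fixed sigma_M and eps
  pa <- profile_params(1, 1, 1e-3)
  pb <- profile_params(1, 2, 2e-3)
  expect_equal(carbon_cost(pb, "wpm"), 2 * carbon_cost(pa, "wpm"),
               tolerance = 1e-10)
})

test_that("conductance is the reciprocal resistance", {
  p <- profile_params(1, 1, 1e-3, amplitude_A = 1)
  expect_equal(conductance(p, "wpm"), 1 / (0.5 * log(1999)), tolerance = 1e-12)
  expect_equal(conductance(p, "wpm"), 0.26314, tolerance = 1e-4)
  expect_equal(conductance(p, "wpm") * resistance_wpm(p), 1, tolerance = 1e-12)
  expect_equal(conductance(p, "powerlaw") * resistance_powerlaw(p), 1,
               tolerance = 1e-12)
  hq <- hydraulic_quantities(p)
  expect_equal(hq$conductance * hq$omega, 1, tolerance = 1e-12)
  expect_true(all(unlist(hq) > 0))
})

test_that("closed forms agree with quadrature across a parameter sweep", {
  grid <- expand.grid(
    eps = 10^seq(-6, -1, length.out = 5),
    sigma_M = 10^seq(0, 4, length.out = 3),
    A = 10^seq(0, 4, length.out = 3),
    h_M = 10^seq(4, 8, length.out = 3)
  )
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- profile_params(g$sigma_M, g$h_M, g$eps * g$h_M, amplitude_A = g$A)
    expect_equal(resistance_wpm(p), oracle_resistance(p, "wpm"),
                 tolerance = 1e-6)
    expect_equal(resistance_powerlaw(p), oracle_resistance(p, "powerlaw"),
                 tolerance = 1e-6)
    expect_equal(widening_cost(p, "wpm"), oracle_widening(p, "wpm"),
                 tolerance = 1e-6)
    expect_equal(carbon_cost(p, "powerlaw"), oracle_carbon(p, "powerlaw"),
                 tolerance = 1e-6)
  }
})

test_that("rescaling all lengths by k scales Omega, W, C as k^-3, k^3, k^2", {
  p <- profile_params(5, 2e6, 800, amplitude_A = 7)
  for (k in c(0.1, 10)) {
    pk <- profile_params(5 * k^2, 2e6 * k, 800 * k, amplitude_A = 7 * k^2)
    expect_equal(resistance_wpm(pk), resistance_wpm(p) / k^3,
                 tolerance = 1e-10)
    expect_equal(widening_cost(pk, "wpm"), widening_cost(p, "wpm") * k^3,
                 tolerance = 1e-10)
    expect_equal(carbon_cost(pk, "wpm"), carbon_cost(p, "wpm") * k^2,
                 tolerance = 1e-8)
  }
})
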