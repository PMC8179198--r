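# Independent variational oracle for the widened-pipe closed form.
#
# The trade-off functional is F[sigma] = integral of L(sigma, sigma_dot) dh
# with Lagrangian L = 1/sigma^2 + (alpha/2) sigma_dot^2, alpha > 0 the
# relative weight of widening cost against hydraulic resistance. Its
# Euler-Lagrange equation is
#     alpha * sigma'' = -2 / sigma^3 ,
# whose first integral sigma^3 * sigma'' = -2/alpha is constant along any
# solution. With alpha = 2 h_M^2 / sigma_M^4 and boundary values taken from
# the closed form, the solution is sigma_M * F(h/h_M).
#
# Two independent numerical routes are provided: a damped-Newton
# finite-difference BVP solver (solve_euler_lagrange) and direct
# gradient-based minimization of the discretized functional
# (minimize_functional_direct). They are used to certify the closed form and
# the universality collapse; the analysis pipeline itself never needs them.

#' Trade-off Lagrangian
#'
#' \deqn{L(\sigma, \dot\sigma) = \frac{1}{\sigma^2} +
#'   \frac{\alpha}{2}\,\dot\sigma^2,}
#' the pointwise cost density whose integral the optimal widening profile
#' minimizes: hydraulic resistance density plus weighted widening penalty.
#'
#' @param sigma Lumen area (µm²), strictly positive.
#' @param sigma_dot Widening rate \eqn{d\sigma/dh} (µm²/µm).
#' @param alpha Trade-off weight, strictly positive.
#' @return Cost density, same length as the inputs.
#' @export
#' @examples
#' lagrangian(1, 0, 2)
lagrangian <- function(sigma, sigma_dot, alpha) {
  check_numeric_vec(sigma, "sigma")
  check_numeric_vec(sigma_dot, "sigma_dot")
  check_number(alpha, "alpha", positive = TRUE)
  if (any(sigma <= 0)) abort_domain("`sigma` must be strictly positive.")
  1 / sigma^2 + alpha / 2 * sigma_dot^2
}

#' Define a variational trade-off problem
#'
#' @param alpha Trade-off weight (> 0).
#' @param h_0,h_M Domain endpoints (µm), `0 < h_0 < h_M`. The lower boundary
#'   is anchored at the physical cutoff `h_0` because the resistance density
#'   `1/sigma^2` is singular where the profile closes at `h = 0`.
#' @param sigma_at_h0,sigma_at_hM Boundary lumen areas (µm²), positive.
#' @param grid_size Number of mesh nodes (≥ 50; default 1001).
#' @param mesh `"sqrt"` (default) for a mesh uniform in \eqn{\sqrt{h}},
#'   concentrating nodes near the tip where the solution has square-root
#'   behaviour; `"uniform"` for an equally spaced mesh.
#' @return A list of class `"variational_problem"`.
#' @export
#' @examples
#' wp <- wpm_problem(sigma_M = 1, h_M = 1, h_0 = 1e-3)
#' sol <- solve_euler_lagrange(wp)
variational_problem <- function(alpha, h_0, h_M, sigma_at_h0, sigma_at_hM,
                                grid_size = 1001L, mesh = c("sqrt", "uniform")) {
  check_number(alpha, "alpha", positive = TRUE)
  check_number(h_0, "h_0", positive = TRUE)
  check_number(h_M, "h_M", positive = TRUE)
  if (h_0 >= h_M) abort_domain("`h_0` must be strictly less than `h_M`.")
  check_number(sigma_at_h0, "sigma_at_h0", positive = TRUE)
  check_number(sigma_at_hM, "sigma_at_hM", positive = TRUE)
  grid_size <- as.integer(grid_size)
  if (grid_size < 50L) abort_input("`grid_size` must be at least 50.")
  mesh <- match.arg(mesh)
  structure(
    list(alpha = alpha, h_0 = h_0, h_M = h_M,
         sigma_at_h0 = sigma_at_h0, sigma_at_hM = sigma_at_hM,
         grid_size = grid_size, mesh = mesh),
    class = "variational_problem"
  )
}

#' Variational problem whose solution is the WPM closed form
#'
#' Convenience constructor: sets `alpha = 2 h_M^2 / sigma_M^4` (the weight for
#' which the stationary profile has basal area `sigma_M`) and boundary values
#' from the closed form itself, so the numerical solution can be compared
#' against `sigma_M * universal_curve(h/h_M)`.
#'
#' @param sigma_M Basal lumen area (µm²).
#' @param h_M,h_0 Domain (µm).
#' @inheritParams variational_problem
#' @return A `"variational_problem"`.
#' @export
wpm_problem <- function(sigma_M, h_M, h_0, grid_size = 1001L,
                        mesh = c("sqrt", "uniform")) {
  check_number(sigma_M, "sigma_M", positive = TRUE)
  variational_problem(
    alpha = 2 * h_M^2 / sigma_M^4,
    h_0 = h_0, h_M = h_M,
    sigma_at_h0 = sigma_M * sqrt((h_0 / h_M) * (2 - h_0 / h_M)),
    sigma_at_hM = sigma_M,
    grid_size = grid_size, mesh = match.arg(mesh)
  )
}

problem_grid <- function(problem) {
  n <- problem$grid_size
  h <- if (problem$mesh == "sqrt") {
    seq(sqrt(problem$h_0), sqrt(problem$h_M), length.out = n)^2
  } else {
    seq(problem$h_0, problem$h_M, length.out = n)
  }
  # pin the endpoints exactly (squaring can overshoot by an ulp)
  h[1] <- problem$h_0
  h[n] <- problem$h_M
  h
}

# 3-point second-derivative weights on a (possibly non-uniform) mesh.
# Exact for quadratics; on a smoothly graded mesh the leading error is O(d^2).
fd2_weights <- function(h) {
  n <- length(h)
  d1 <- h[2:(n - 1)] - h[1:(n - 2)]
  d2 <- h[3:n] - h[2:(n - 1)]
  list(
    wl = 2 / (d1 * (d1 + d2)),
    wc = -2 / (d1 * d2),
    wr = 2 / (d2 * (d1 + d2))
  )
}

# Thomas algorithm for a tridiagonal system (sub, diag, super, rhs).
solve_tridiag <- function(lower, diag, upper, rhs) {
  n <- length(diag)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- upper[1] / diag[1]
  dp[1] <- rhs[1] / diag[1]
  for (i in 2:n) {
    denom <- diag[i] - lower[i] * cp[i - 1]
    cp[i] <- if (i < n) upper[i] / denom else 0
    dp[i] <- (rhs[i] - lower[i] * dp[i - 1]) / denom
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

discretized_objective <- function(h, sigma, alpha) {
  dh <- diff(h)
  ds <- diff(sigma)
  sum(dh * (0.5 * (1 / sigma[-length(sigma)]^2 + 1 / sigma[-1]^2)
            + alpha / 2 * (ds / dh)^2))
}

new_variational_solution <- function(problem, grid, sigma, converged,
                                     iterations, residual, method) {
  out <- tibble(h = grid, sigma = sigma)
  structure(out,
    class = c("variational_solution", class(out)),
    objective_value = discretized_objective(grid, sigma, problem$alpha),
    converged = converged,
    iterations = iterations,
    residual = residual,
    method = method,
    problem = problem
  )
}

#' @export
print.variational_solution <- function(x, ...) {
  cat(sprintf(
    "<variational_solution: %s, %d nodes, converged = %s, objective = %.8g>\n",
    attr(x, "method"), nrow(x), attr(x, "converged"), attr(x, "objective_value")
  ))
  NextMethod()
}

#' Solve the Euler–Lagrange boundary-value problem
#'
#' Solves \eqn{\alpha \ddot\sigma = -2/\sigma^3} with fixed boundary areas by
#' damped Newton iteration on a three-point finite-difference discretization.
#' Convergence requires the scaled Euler–Lagrange residual (max residual
#' divided by the magnitude of the source term) to fall below `tol`.
#' Non-convergence is flagged in the result, never silent.
#'
#' @param problem A [variational_problem()].
#' @param tol Scaled-residual convergence tolerance (default 1e-8).
#' @param max_iter Maximum Newton iterations.
#' @return A tibble of class `"variational_solution"` with columns `h`,
#'   `sigma` and attributes `objective_value`, `converged`, `iterations`,
#'   `residual`, `method`.
#' @export
solve_euler_lagrange <- function(problem, tol = 1e-8, max_iter = 60L) {
  stopifnot(inherits(problem, "variational_problem"))
  h <- problem_grid(problem)
  n <- length(h)
  alpha <- problem$alpha
  w <- fd2_weights(h)

  # initial guess: linear interpolation between boundary values
  sigma <- problem$sigma_at_h0 +
    (problem$sigma_at_hM - problem$sigma_at_h0) * (h - h[1]) / (h[n] - h[1])

  residual_of <- function(s) {
    sdd <- w$wl * s[1:(n - 2)] + w$wc * s[2:(n - 1)] + w$wr * s[3:n]
    alpha * sdd + 2 / s[2:(n - 1)]^3
  }
  res_scale <- function(s) max(2 / s[2:(n - 1)]^3)
  # round-off floor of the finite-difference residual: the second-difference
  # stencil amplifies double-precision noise by ~ alpha * sigma / dh^2
  res_floor <- function(s) {
    40 * alpha * .Machine$double.eps * max(abs(s)) / min(diff(h))^2
  }

  converged <- FALSE
  iter <- 0L
  scaled_res <- Inf
  r <- residual_of(sigma)
  while (iter < max_iter) {
    iter <- iter + 1L
    si <- sigma[2:(n - 1)]
    # tridiagonal Jacobian of the residual wrt interior nodes
    dl <- alpha * w$wl
    dc <- alpha * w$wc - 6 / si^4
    du <- alpha * w$wr
    m <- n - 2L
    step <- solve_tridiag(c(0, dl[-1]), dc, c(du[-m], 0), -r)
    # damped update keeping sigma positive and the residual decreasing
    lam <- 1
    norm0 <- max(abs(r))
    repeat {
      trial <- sigma
      trial[2:(n - 1)] <- si + lam * step
      if (all(trial > 0)) {
        rt <- residual_of(trial)
        if (max(abs(rt)) < norm0 || lam < 1e-6) break
      }
      lam <- lam / 2
      if (lam < 1e-8) break
    }
    sigma <- trial
    r <- rt
    scaled_res <- max(abs(r)) / res_scale(sigma)
    if (max(abs(r)) <= max(tol * res_scale(sigma), res_floor(sigma))) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf(
      "Euler-Lagrange solver did not reach tol = %g (scaled residual %.3g after %d iterations).",
      tol, scaled_res, iter
    ))
  }
  new_variational_solution(problem, h, sigma, converged, iter, scaled_res,
                           "euler_lagrange")
}

#' Minimize the discretized trade-off functional directly
#'
#' Trapezoid-rule discretization of the functional over the problem mesh,
#' minimized over all interior node values (endpoints fixed) by a
#' quasi-Newton optimizer (`nlminb`) with an analytic gradient. An
#' independent route to the same optimum as [solve_euler_lagrange()], used to
#' certify that the closed form is a true minimum and not merely stationary.
#' Convergence is accepted either on the optimizer's own relative-convergence
#' test or when the gradient has collapsed by eight orders of magnitude from
#' the starting profile.
#'
#' @param problem A [variational_problem()].
#' @param init `"linear"` (default) or `"powerlaw"` starting profile, or a
#'   numeric vector of length `grid_size`.
#' @param maxit Maximum optimizer iterations.
#' @return A `"variational_solution"` (method `"direct"`).
#' @export
minimize_functional_direct <- function(problem, init = c("linear", "powerlaw"),
                                       maxit = 5000L) {
  stopifnot(inherits(problem, "variational_problem"))
  h <- problem_grid(problem)
  n <- length(h)
  alpha <- problem$alpha
  dh <- diff(h)

  if (is.numeric(init)) {
    if (length(init) != n) abort_input("numeric `init` must have length `grid_size`.")
    sigma0 <- init
  } else {
    init <- match.arg(init)
    x <- (h - h[1]) / (h[n] - h[1])
    sigma0 <- switch(init,
      linear = problem$sigma_at_h0 + (problem$sigma_at_hM - problem$sigma_at_h0) * x,
      powerlaw = problem$sigma_at_hM * sqrt(h / h[n])
    )
    sigma0[1] <- problem$sigma_at_h0
    sigma0[n] <- problem$sigma_at_hM
  }

  obj <- function(si) {
    s <- c(problem$sigma_at_h0, si, problem$sigma_at_hM)
    discretized_objective(h, s, alpha)
  }
  grad <- function(si) {
    s <- c(problem$sigma_at_h0, si, problem$sigma_at_hM)
    g <- numeric(n)
    # d/ds_i of trapezoid resistance term
    wt <- c(dh[1] / 2, (dh[-length(dh)] + dh[-1]) / 2, dh[length(dh)] / 2)
    g <- -2 * wt / s^3
    # d/ds_i of the widening term
    ds <- diff(s) / dh
    g[1:(n - 1)] <- g[1:(n - 1)] - alpha * ds
    g[2:n] <- g[2:n] + alpha * ds
    g[2:(n - 1)]
  }

  fit <- nlminb(
    sigma0[2:(n - 1)], obj, grad,
    lower = 1e-10 * max(sigma0),
    control = list(iter.max = maxit, eval.max = 2L * maxit, rel.tol = 1e-14)
  )

  # polish: damped Newton on the stationarity system grad = 0 of the same
  # discrete objective (tridiagonal Jacobian), driving the gradient to
  # round-off so convergence can be certified by gradient collapse alone
  si <- fit$par
  wt <- (dh[-length(dh)] + dh[-1]) / 2
  m <- n - 2L
  for (k in seq_len(12L)) {
    g <- grad(si)
    if (max(abs(g)) == 0) break
    dc <- 6 * wt / si^4 + alpha * (1 / dh[1:m] + 1 / dh[2:(m + 1L)])
    dl <- -alpha / dh[2:m]
    du <- -alpha / dh[2:m]
    step <- solve_tridiag(c(0, dl), dc, c(du, 0), -g)
    lam <- 1
    repeat {
      trial <- si + lam * step
      if (all(trial > 0) && max(abs(grad(trial))) < max(abs(g))) break
      lam <- lam / 2
      if (lam < 1e-8) {
        trial <- si
        break
      }
    }
    if (identical(trial, si)) break
    si <- trial
  }

  g0 <- max(abs(grad(sigma0[2:(n - 1)])))
  g1 <- max(abs(grad(si)))
  converged <- g1 <= 1e-8 * g0 || fit$convergence == 0
  if (!converged) {
    warn(sprintf("Direct minimization did not converge (code %d: %s; gradient reduction %.2g).",
                 fit$convergence, fit$message %||% "", g1 / g0))
  }
  sigma <- c(problem$sigma_at_h0, si, problem$sigma_at_hM)
  new_variational_solution(problem, h, sigma, converged,
                           fit$iterations, NA_real_, "direct")
}

#' Local-optimality certificate
#'
#' Checks that the discretized objective of a solution does not decrease under
#' random interior perturbations of a given relative magnitude (endpoints
#' held fixed).
#'
#' @param solution A `"variational_solution"`.
#' @param n_directions Number of random perturbation directions.
#' @param magnitude Relative perturbation size (default 1%).
#' @param seed RNG seed for the perturbation draws.
#' @return `TRUE` if no tested perturbation lowers the objective.
#' @export
check_local_minimum <- function(solution, n_directions = 25L,
                                magnitude = 0.01, seed = 1L) {
  stopifnot(inherits(solution, "variational_solution"))
  problem <- attr(solution, "problem")
  h <- solution$h
  s <- solution$sigma
  n <- length(s)
  f0 <- discretized_objective(h, s, problem$alpha)
  withr::with_seed(seed, {
    all(vapply(seq_len(n_directions), function(i) {
      pert <- s
      pert[2:(n - 1)] <- s[2:(n - 1)] *
        (1 + magnitude * stats::runif(n - 2L, -1, 1))
      discretized_objective(h, pert, problem$alpha) >= f0 - 1e-12 * abs(f0)
    }, logical(1)))
  })
}
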