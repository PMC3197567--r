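#' Solver configuration
#'
#' Settings for the semi-implicit finite-difference solver. The defaults
#' `dx = 0.002` and `dt = 0.005` are the grid used for all reported
#' simulations; the steady-state criterion is on the rate of change
#' `max |du|/dt` (per unit time, hence dt-independent).
#'
#' @param dx Spatial step; must divide 1 within rounding so the grid
#'   contains `x = 0` and `x = 1` exactly.
#' @param dt Time step.
#' @param steady_tol Threshold on `max |change|/dt` for declaring steady
#'   state.
#' @param max_steps Cap on the number of time steps.
#' @param report_every Log a progress line (step index, per-species
#'   `max |du|/dt`) every this many steps; 0 disables logging.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(dx = 0.002, dt = 0.005, steady_tol = 1e-8,
                          max_steps = 400000L, report_every = 0L) {
  stopifnot(is.numeric(dx), dx > 0, is.numeric(dt), dt > 0,
            is.numeric(steady_tol), steady_tol > 0,
            max_steps >= 1, report_every >= 0)
  n <- 1 / dx
  if (abs(n - round(n)) > 1e-8) {
    stop(sprintf("dx = %g does not divide the unit interval (1/dx = %.6f)",
                 dx, n), call. = FALSE)
  }
  structure(list(dx = dx, dt = dt, steady_tol = steady_tol,
                 max_steps = as.integer(max_steps),
                 report_every = as.integer(report_every)),
            class = "solver_config")
}

#' Build the spatial grid of a solver configuration
#'
#' @param config A [solver_config()].
#' @return `N + 1` equispaced nodes `x_i = i * dx` with `x_0 = 0`,
#'   `x_N = 1` exactly.
#' @export
build_grid <- function(config) {
  stopifnot(inherits(config, "solver_config"))
  N <- round(1 / config$dx)
  x <- (0:N) * config$dx
  x[N + 1L] <- 1
  x
}

params_for_cpp <- function(p) {
  list(p$lambda1, p$lambda2, p$lambda3, p$lambda4, p$lambda5,
       p$delta_A, p$delta_B, p$mu_A, p$mu_B)
}

#' One semi-implicit time step
#'
#' Advances the state by one IMEX step: diffusion and linear reaction terms
#' are treated implicitly (backward Euler; one tridiagonal solve per
#' species), the bilinear complex-formation term `lambda1 A B` explicitly
#' with values from the current step. The complex is updated first, so the
#' linear breakdown sources in the other two equations use its fresh
#' value. The symmetry condition at `x = 0` is imposed to second order via
#' ghost-node reflection; the node at `x = 1` is held at 1.
#'
#' @param state A [concentration_profile()] on the configured grid.
#' @param p A [dimensionless_parameters()] object.
#' @param config A [solver_config()].
#' @return The state after one step (a [concentration_profile()] with `t`
#'   advanced by `dt`).
#' @export
imex_step <- function(state, p, config) {
  stopifnot(inherits(state, "concentration_profile"),
            inherits(config, "solver_config"))
  validate_dimensionless_parameters(p, strict = FALSE)
  x <- build_grid(config)
  if (length(x) != length(state$x) || max(abs(x - state$x)) > 1e-12) {
    stop("state is not on the configured grid", call. = FALSE)
  }
  res <- do.call(imex_run_cpp, c(
    list(state$A, state$B, state$C), params_for_cpp(p),
    list(dx = config$dx, dt = config$dt, steady_tol = 0,
         max_steps = 1L, report_every = 0L)))
  t0 <- if (is.numeric(state$t)) state$t else 0
  concentration_profile(x, res$A, res$B, res$C, t = t0 + config$dt)
}

#' Run the full nonlinear system to steady state
#'
#' Iterates [imex_step()] from the uniform initial state
#' `A = B = C = 1` (or a supplied initial profile) until
#' `max |change|/dt < steady_tol` for all species, or `max_steps` is
#' reached. On convergence the steady residual of the discrete equations
#' is certified below `10 * steady_tol * scale` where `scale` is the
#' largest concentration magnitude.
#'
#' @param p A [dimensionless_parameters()] object.
#' @param config A [solver_config()].
#' @param init Optional initial [concentration_profile()] on the
#'   configured grid.
#' @return An object of class `steady_state_solution`: fields `profile`,
#'   `steps_taken`, `residual` (per-species max-norm of the steady
#'   equations), `converged`, and `max_rate` (final `max |du|/dt`).
#'   Non-convergence within `max_steps` is reported through
#'   `converged = FALSE`, not an error.
#' @export
run_to_steady <- function(p, config = solver_config(), init = NULL) {
  stopifnot(inherits(config, "solver_config"))
  validate_dimensionless_parameters(p, strict = FALSE)
  x <- build_grid(config)
  if (is.null(init)) {
    ones <- rep(1, length(x))
    init <- concentration_profile(x, ones, ones, ones, t = 0)
  } else {
    stopifnot(inherits(init, "concentration_profile"))
    if (length(init$x) != length(x) || max(abs(init$x - x)) > 1e-12) {
      stop("init profile is not on the configured grid", call. = FALSE)
    }
  }
  res <- do.call(imex_run_cpp, c(
    list(init$A, init$B, init$C), params_for_cpp(p),
    list(dx = config$dx, dt = config$dt, steady_tol = config$steady_tol,
         max_steps = config$max_steps, report_every = config$report_every)))
  t_marker <- if (res$converged) "steady" else res$steps * config$dt
  profile <- concentration_profile(x, res$A, res$B, res$C, t = t_marker)
  resid <- steady_residual(profile, p)
  scale <- max(1, abs(res$A), abs(res$B), abs(res$C))
  converged <- isTRUE(res$converged) &&
    max(resid) < 10 * config$steady_tol * scale
  structure(list(profile = profile,
                 steps_taken = res$steps,
                 residual = resid,
                 converged = converged,
                 max_rate = res$max_rate),
            class = "steady_state_solution")
}

#' @export
print.steady_state_solution <- function(x, ...) {
  cat(sprintf("Steady-state solution: %s after %d steps\n",
              if (x$converged) "converged" else "NOT converged",
              x$steps_taken))
  cat("  residual (max-norm): ",
      paste(sprintf("%s=%.3g", names(x$residual), x$residual),
            collapse = ", "), "\n")
  print(x$profile)
  invisible(x)
}

#' Residual of the steady equations on a profile
#'
#' Assembles the steady balance of each species (time derivative zero)
#' with second-order central differences — ghost-node reflection at
#' `x = 0`, the Dirichlet node excluded — and returns the per-species
#' max-norm. A converged solver output has residual at the level of the
#' steady tolerance; the exact analytic solution has residual `O(dx^2)`.
#'
#' @param profile A [concentration_profile()] on a uniform grid with at
#'   least 5 nodes.
#' @param p A [dimensionless_parameters()] object.
#' @return Named numeric vector `c(A = , B = , C = )`.
#' @export
steady_residual <- function(profile, p) {
  stopifnot(inherits(profile, "concentration_profile"))
  validate_dimensionless_parameters(p, strict = FALSE)
  x <- profile$x
  n <- length(x)
  if (n < 5L) stop("steady_residual needs at least 5 nodes", call. = FALSE)
  h <- diff(x)
  if (max(abs(h - h[1L])) > 1e-10) {
    stop("steady_residual requires a uniform grid", call. = FALSE)
  }
  h <- h[1L]
  d2 <- function(u) {
    # interior nodes 2..n-1 plus symmetry node 1 via ghost u[0] = u[2]
    c((2 * u[2L] - 2 * u[1L]),
      u[1:(n - 2L)] - 2 * u[2:(n - 1L)] + u[3:n]) / h^2
  }
  idx <- 1:(n - 1L)
  A <- profile$A; B <- profile$B; C <- profile$C
  rA <- p$delta_A * d2(A) - p$lambda1 * p$mu_A * (A * B)[idx] +
    p$lambda2 * p$mu_A * C[idx] - p$lambda3 * A[idx]
  rB <- p$delta_B * d2(B) - p$lambda1 * p$mu_B * (A * B)[idx] -
    p$lambda4 * B[idx] + p$lambda5 * C[idx]
  rC <- d2(C) + p$lambda1 * (A * B)[idx] - p$lambda2 * C[idx]
  c(A = max(abs(rA)), B = max(abs(rB)), C = max(abs(rC)))
}
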