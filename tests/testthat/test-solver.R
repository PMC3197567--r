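test_that("grid construction honours the spacing contract", {
  expect_equal(build_grid(solver_config(dx = 0.5)), c(0, 0.5, 1))
  expect_length(build_grid(solver_config(dx = 0.002)), 501L)
  g <- build_grid(solver_config(dx = 0.002))
  expect_identical(g[1], 0)
  expect_identical(g[501], 1)
  expect_error(solver_config(dx = 0.3), "does not divide")
  expect_error(solver_config(dt = 0), "dt")
})

test_that("the uniform state is a fixed point without reactions", {
  p <- dimensionless_parameters()
  cfg <- solver_config(dx = 0.01)
  x <- build_grid(cfg)
  state <- concentration_profile(x, rep(1, length(x)), rep(1, length(x)),
                                 rep(1, length(x)), t = 0)
  nxt <- imex_step(state, p, cfg)
  expect_equal(nxt$A, state$A, tolerance = 1e-14)
  expect_equal(nxt$B, state$B, tolerance = 1e-14)
  expect_equal(nxt$C, state$C, tolerance = 1e-14)
  expect_equal(nxt$t, cfg$dt)
})

test_that("one step moves each species in the direction of its reaction terms", {
  # only breakdown active: C loses mass in the interior, A gains it
  p <- dimensionless_parameters(lambda2 = 5, mu_A = 2)
  cfg <- solver_config(dx = 0.01)
  x <- build_grid(cfg)
  ones <- rep(1, length(x))
  nxt <- imex_step(concentration_profile(x, ones, ones, ones, t = 0), p, cfg)
  interior <- seq_len(length(x) - 1L)
  expect_true(all(nxt$C[interior] < 1))
  expect_true(all(nxt$A[interior] > 1))
  expect_equal(nxt$B, ones)                 # B uncoupled here (lambda5 = 0)
  expect_identical(nxt$A[length(x)], 1)     # Dirichlet edge pinned
})

test_that("a single IMEX step is consistent with the semi-discrete flow", {
  skip_if_not_installed("deSolve")
  p <- dimensionless_parameters(lambda1 = 1, lambda2 = 3, lambda3 = 0.5,
                                lambda4 = 0.4, lambda5 = 0.8, mu_A = 2,
                                mu_B = 0.5, delta_A = 0.7, delta_B = 1.3)
  dx <- 0.05
  x <- build_grid(solver_config(dx = dx))
  n <- length(x)
  # start away from equilibrium
  A0 <- 1 + 0.3 * cos(pi * x / 2); B0 <- 1 - 0.2 * cos(pi * x / 2)
  C0 <- 1 + 0.1 * cos(3 * pi * x / 2)
  A0[n] <- B0[n] <- C0[n] <- 1
  semi <- function(t, y, parms) {
    A <- y[1:n]; B <- y[n + 1:n]; C <- y[2 * n + 1:n]
    d2 <- function(u) c(2 * u[2] - 2 * u[1],
                        u[1:(n - 2)] - 2 * u[2:(n - 1)] + u[3:n], 0) / dx^2
    AB <- A * B
    dA <- p$delta_A * d2(A) - p$lambda1 * p$mu_A * AB +
      p$lambda2 * p$mu_A * C - p$lambda3 * A
    dB <- p$delta_B * d2(B) - p$lambda1 * p$mu_B * AB - p$lambda4 * B +
      p$lambda5 * C
    dC <- d2(C) + p$lambda1 * AB - p$lambda2 * C
    dA[n] <- dB[n] <- dC[n] <- 0
    list(c(dA, dB, dC))
  }
  err <- vapply(c(0.02, 0.01, 0.005), function(dt) {
    ref <- deSolve::lsoda(c(A0, B0, C0), c(0, dt), semi, NULL,
                          rtol = 1e-11, atol = 1e-12)
    stepped <- imex_step(concentration_profile(x, A0, B0, C0, t = 0), p,
                         solver_config(dx = dx, dt = dt))
    max(abs(c(stepped$A, stepped$B, stepped$C) - ref[2, -1]))
  }, numeric(1))
  # local error shrinks at least linearly under dt halving
  expect_true(all(diff(err) < 0))
  expect_gt(err[1] / err[2], 1.7)
  expect_gt(err[2] / err[3], 1.7)
  expect_lt(err[3], 5e-3)
})

test_that("without reactions the steady state is uniform", {
  sol <- run_to_steady(dimensionless_parameters(), solver_config(dx = 0.01))
  expect_true(sol$converged)
  expect_lt(max(abs(sol$profile$A - 1), abs(sol$profile$B - 1),
                abs(sol$profile$C - 1)), 1e-8)
  expect_identical(sol$profile$t, "steady")
})

test_that("the solver reproduces the closed forms when complex formation is off", {
  p <- dimensionless_parameters(lambda2 = 50, lambda3 = 0.5)
  sol <- run_to_steady(p, solver_config())
  expect_true(sol$converged)
  x <- sol$profile$x
  expect_lt(max(abs(sol$profile$A - leading_order_A(x, p))), 1e-3)
  expect_lt(max(abs(sol$profile$B - leading_order_B(x, p))), 1e-3)
  expect_lt(max(abs(sol$profile$C - leading_order_C(x, p))), 1e-3)
})

test_that("steady solutions converge at second order in dx", {
  p <- dimensionless_parameters(lambda2 = 8, lambda3 = 0.7, lambda4 = 0.4,
                                lambda5 = 1.1, mu_A = 1.5)
  err <- vapply(c(0.008, 0.004), function(dx) {
    sol <- run_to_steady(p, solver_config(dx = dx, steady_tol = 1e-10))
    x <- sol$profile$x
    max(abs(sol$profile$A - leading_order_A(x, p)),
        abs(sol$profile$C - leading_order_C(x, p)))
  }, numeric(1))
  expect_gt(err[1] / err[2], 3)
  expect_lt(err[1] / err[2], 5.2)
})

test_that("turning on complex formation lowers A and raises C pointwise", {
  base <- fixture("fig6")$params
  cfg <- solver_config(dx = 0.004)
  sol0 <- run_to_steady(base, cfg)
  p2 <- dimensionless_parameters(lambda1 = 2, lambda2 = 5, lambda3 = 0.5,
                                 lambda4 = 1, lambda5 = 1)
  sol2 <- run_to_steady(p2, cfg)
  interior <- sol0$profile$x < 1
  expect_true(all(sol2$profile$A[interior] < sol0$profile$A[interior]))
  expect_true(all(sol2$profile$C[interior] > sol0$profile$C[interior]))
})

test_that("species stay positive and the steady state forgets its initial condition", {
  p <- dimensionless_parameters(lambda1 = 2, lambda2 = 5, lambda3 = 0.5,
                                lambda4 = 1, lambda5 = 1)
  cfg <- solver_config(dx = 0.004)
  sol <- run_to_steady(p, cfg)
  expect_true(all(sol$profile$A > 0, sol$profile$B > 0, sol$profile$C > 0))
  # start instead from the leading-order analytic profile
  x <- build_grid(cfg)
  init <- leading_order_profile(p, x = x)
  init$t <- 0
  sol_b <- run_to_steady(p, cfg, init = init)
  expect_true(sol_b$converged)
  expect_lt(max(abs(sol_b$profile$A - sol$profile$A),
                abs(sol_b$profile$B - sol$profile$B),
                abs(sol_b$profile$C - sol$profile$C)), 1e-6)
})

test_that("non-convergence is reported, not raised", {
  p <- dimensionless_parameters(lambda2 = 50, lambda3 = 0.5)
  sol <- run_to_steady(p, solver_config(dx = 0.01, max_steps = 5L))
  expect_false(sol$converged)
  expect_identical(sol$steps_taken, 5L)
  expect_true(is.numeric(sol$profile$t))
})

test_that("steady_residual vanishes for the trivial equilibrium and ranks profiles", {
  x <- seq(0, 1, length.out = 101)
  ones <- rep(1, 101)
  prof <- concentration_profile(x, ones, ones, ones)
  expect_equal(steady_residual(prof, dimensionless_parameters()),
               c(A = 0, B = 0, C = 0))
  # analytic leading-order profile: residual decays as O(dx^2)
  p <- dimensionless_parameters(lambda2 = 5, lambda3 = 0.5, lambda4 = 0.2,
                                lambda5 = 1)
  r <- vapply(c(101L, 201L), function(n) {
    max(steady_residual(leading_order_profile(p, x = seq(0, 1, length.out = n)),
                        p))
  }, numeric(1))
  expect_gt(r[1] / r[2], 3.4)
  expect_lt(r[1] / r[2], 4.6)
  # a perturbed profile has a strictly larger residual than the converged one
  sol <- run_to_steady(p, solver_config(dx = 0.01))
  pert <- sol$profile
  pert$A <- pert$A + 1e-3 * sin(pi * pert$x)
  expect_gt(max(steady_residual(pert, p)), max(steady_residual(sol$profile, p)))
})

test_that("mismatched grids and bad states are rejected", {
  cfg <- solver_config(dx = 0.01)
  x <- seq(0, 1, length.out = 51)
  state <- concentration_profile(x, rep(1, 51), rep(1, 51), rep(1, 51))
  expect_error(imex_step(state, dimensionless_parameters(), cfg),
               "not on the configured grid")
  expect_error(concentration_profile(c(0, 0.4, 0.9), 1:3, 1:3, 1:3),
               "span")
  expect_error(concentration_profile(seq(0, 1, 0.5), c(1, NA, 1),
                                     rep(1, 3), rep(1, 3)),
               "non-finite")
})
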