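test_that("cosh_ratio matches naive evaluation and survives huge wavenumbers", {
  x <- seq(0, 1, length.out = 21)
  for (k in c(0.3, 1, 25, 300, 700)) {
    expect_equal(cosh_ratio(k, x), cosh(k * x) / cosh(k), tolerance = 1e-13)
  }
  expect_equal(cosh_ratio(1, 0), 1 / cosh(1), tolerance = 1e-13)
  # ratio of identical terms and zero wavenumber
  for (k in c(0, 1, 1e3, 1e6)) expect_identical(cosh_ratio(k, 1), 1)
  expect_identical(cosh_ratio(0, 0.3), 1)
  # far beyond the naive overflow point: finite, decaying like exp(k(x-1))
  v <- cosh_ratio(1e6, c(0.999999, 0.999990))
  expect_true(all(is.finite(v)))
  expect_equal(v, exp(1e6 * (c(0.999999, 0.999990) - 1)), tolerance = 1e-12)
  expect_error(cosh_ratio(1, 1.5), "\\[0, 1\\]")
  expect_error(cosh_ratio(1, -0.1), "\\[0, 1\\]")
})

test_that("without reactions all leading-order profiles are uniform", {
  p <- dimensionless_parameters()
  x <- seq(0, 1, length.out = 11)
  expect_equal(leading_order_A(x, p), rep(1, 11))
  expect_equal(leading_order_B(x, p), rep(1, 11))
  expect_equal(leading_order_C(x, p), rep(1, 11))
  expect_equal(central_A0(p), 1)
})

test_that("leading-order solutions match an independent dense BVP oracle", {
  cases <- list(
    dimensionless_parameters(lambda2 = 50, lambda3 = 0.5),
    dimensionless_parameters(lambda2 = 5, lambda3 = 1.2, lambda4 = 0.2,
                             lambda5 = 1, delta_A = 0.7, delta_B = 1.6,
                             mu_A = 2, mu_B = 0.5),
    dimensionless_parameters(lambda2 = 50, lambda3 = 5)
  )
  for (p in cases) {
    o <- oracle_leading_order(p, n = 801)
    expect_lt(max(abs(leading_order_A(o$x, p) - o$A0)), 1e-8)
    expect_lt(max(abs(leading_order_B(o$x, p) - o$B0)), 1e-8)
    expect_lt(max(abs(leading_order_C(o$x, p) - o$C0)), 1e-8)
    expect_equal(central_A0(p), leading_order_A(0, p))
  }
})

test_that("closed forms satisfy the steady balances (residual oracle)", {
  x <- seq(0, 1, by = 1e-3)
  h <- 1e-3
  i <- 2:(length(x) - 1)
  for (p in list(dimensionless_parameters(lambda2 = 2, lambda3 = 0.5,
                                          lambda4 = 0.3, lambda5 = 1),
                 dimensionless_parameters(lambda2 = 1, lambda3 = 1.5,
                                          lambda5 = 0.7, delta_A = 2,
                                          delta_B = 0.5, mu_A = 1.5))) {
    A0 <- leading_order_A(x, p); B0 <- leading_order_B(x, p)
    C0 <- leading_order_C(x, p)
    d2 <- function(u) (u[i - 1] - 2 * u[i] + u[i + 1]) / h^2
    rA <- p$delta_A * d2(A0) + p$lambda2 * p$mu_A * C0[i] - p$lambda3 * A0[i]
    rB <- p$delta_B * d2(B0) - p$lambda4 * B0[i] + p$lambda5 * C0[i]
    rC <- d2(C0) - p$lambda2 * C0[i]
    expect_lt(max(abs(rA)), 1e-6)
    expect_lt(max(abs(rB)), 1e-6)
    expect_lt(max(abs(rC)), 1e-6)
  }
})

test_that("regular and degenerate branches agree across the resonance locus", {
  x <- seq(0, 1, length.out = 201)
  for (l2 in c(2, 50)) {
    for (dA in c(1, 0.5)) {
      p_deg <- dimensionless_parameters(lambda2 = l2, lambda3 = dA * l2,
                                        delta_A = dA, mu_A = 1.3)
      deg <- leading_order_A(x, p_deg)
      for (s in c(1 - 1e-6, 1 + 1e-6)) {
        p_reg <- dimensionless_parameters(lambda2 = l2, lambda3 = dA * l2 * s,
                                          delta_A = dA, mu_A = 1.3)
        expect_lt(max(abs(leading_order_A(x, p_reg) - deg)), 1e-4)
      }
      p_degB <- dimensionless_parameters(lambda2 = l2, lambda4 = dA * l2,
                                         delta_B = dA, lambda5 = 1.3)
      degB <- leading_order_B(x, p_degB)
      for (s in c(1 - 1e-6, 1 + 1e-6)) {
        p_regB <- dimensionless_parameters(lambda2 = l2, lambda4 = dA * l2 * s,
                                           delta_B = dA, lambda5 = 1.3)
        expect_lt(max(abs(leading_order_B(x, p_regB) - degB)), 1e-4)
      }
    }
  }
})

test_that("boundary values and centre symmetry hold", {
  set.seed(11)
  h <- 1e-5
  for (rep in 1:20) {
    p <- rand_o1_params()
    expect_equal(leading_order_A(1, p), 1)
    expect_equal(leading_order_B(1, p), 1)
    expect_equal(leading_order_C(1, p), 1)
    # centred difference about x = 0 (even extension): derivative O(h^2)
    for (f in list(leading_order_A, leading_order_B, leading_order_C)) {
      expect_lt(abs(f(h, p) - f(0, p)) / h, 1e-3) # f'(0)=0 => diff ~ f''(0) h/2
    }
  }
})

test_that("no removal of the free chemical: supply-limited ceiling 1 + mu_A/delta_A", {
  # printed limiting value: lambda3 = 0, mu_A = delta_A = 1, lambda2 large
  p <- dimensionless_parameters(lambda2 = 1e8)
  expect_equal(leading_order_A(0, p), 2, tolerance = 1e-3)
  # upper bound approached monotonically over a huge lambda2 range
  l2s <- 10^seq(0, 8, length.out = 30)
  a0 <- vapply(l2s, function(l2) {
    central_A0(dimensionless_parameters(lambda2 = l2, mu_A = 1.4,
                                        delta_A = 0.7))
  }, numeric(1))
  expect_true(all(a0 <= 1 + 1.4 / 0.7 + 1e-12))
  expect_gt(a0[30], (1 + 1.4 / 0.7) * 0.999)
  # strictly increasing until it saturates at the ceiling (then flat to
  # round-off)
  expect_true(all(diff(a0) > -1e-12))
  expect_true(all(diff(a0[a0 < 0.999 * (1 + 1.4 / 0.7)]) > 0))
})

test_that("no complex breakdown: free chemical and binding partner dip at the centre", {
  p <- dimensionless_parameters(lambda3 = 0.8, lambda4 = 0.6)
  x <- seq(0, 1, length.out = 101)
  expect_equal(leading_order_B(x, p),
               cosh_ratio(sqrt(0.6), x), tolerance = 1e-14)
  expect_equal(which.min(leading_order_A(x, p)), 1L)
  expect_equal(which.min(leading_order_B(x, p)), 1L)
})

test_that("complex boundary layer has width ~ lambda2^(-1/2)", {
  widths <- vapply(10^(3:6), function(l2) {
    p <- dimensionless_parameters(lambda2 = l2)
    1 - uniroot(function(x) leading_order_C(x, p) - 0.5, c(0, 1),
                tol = 1e-12)$root
  }, numeric(1))
  scaled <- widths * sqrt(10^(3:6))
  expect_lt(max(abs(scaled / scaled[1] - 1)), 0.05)
})

test_that("C0 increases strictly from centre to boundary whenever lambda2 > 0", {
  x <- seq(0, 1, length.out = 201)
  for (l2 in c(0.01, 1, 50, 1e4)) {
    C0 <- leading_order_C(x, dimensionless_parameters(lambda2 = l2))
    expect_true(all(diff(C0) > 0))
  }
})

test_that("a centre maximum of A0 excludes any other stationary point", {
  set.seed(23)
  x <- seq(0, 1, length.out = 2001)
  n_centre_max <- 0
  for (rep in 1:200) {
    p <- rand_o1_params()
    A0 <- leading_order_A(x, p)
    g <- diff(A0)
    if (g[1] < -1e-12) { # x = 0 is a strict local maximum
      n_centre_max <- n_centre_max + 1
      expect_true(all(g < 1e-12)) # monotone decrease: no interior extremum
    }
  }
  expect_gt(n_centre_max, 10) # the regime was actually exercised
})

test_that("central_A0 is non-increasing in the removal rate", {
  l3s <- seq(0, 10, length.out = 60)
  for (l2 in c(2, 50)) {
    a0 <- vapply(l3s, function(l3) {
      central_A0(dimensionless_parameters(lambda2 = l2, lambda3 = l3))
    }, numeric(1))
    expect_true(all(diff(a0) <= 1e-12))
  }
})

test_that("degenerate parameter corners are handled", {
  x <- seq(0, 1, length.out = 51)
  # lambda2 = lambda3 = 0: no source, no sink
  p <- dimensionless_parameters(mu_A = 5)
  expect_equal(leading_order_A(x, p), rep(1, 51))
  # lambda2 = lambda4 = 0 with lambda5 > 0: uniform source, parabolic excess
  p2 <- dimensionless_parameters(lambda5 = 2, delta_B = 0.5)
  expect_equal(leading_order_B(x, p2), 1 + 2 * (1 - x^2) / (2 * 0.5),
               tolerance = 1e-14)
  expect_equal(leading_order_B(x, dimensionless_parameters()), rep(1, 51))
})
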