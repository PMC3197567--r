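# Independent numerical oracles, deliberately sharing no code with the
# package: dense-matrix finite differences solved with base::solve(), with
# Richardson extrapolation where high accuracy is needed.

# Solve u'' - c u = rhs_fun(x) on [0,1], u'(0) = 0, u(1) = bc, by central
# differences on n nodes assembled as a dense matrix.
dense_bvp <- function(c_coef, rhs_fun, n, bc = 0) {
  h <- 1 / (n - 1)
  x <- seq(0, 1, length.out = n)
  m <- n - 1 # unknowns exclude the Dirichlet node
  M <- matrix(0, m, m)
  for (i in seq_len(m)) {
    M[i, i] <- -2 / h^2 - c_coef
    if (i > 1) M[i, i - 1] <- 1 / h^2
    if (i < m) M[i, i + 1] <- 1 / h^2
  }
  M[1, 2] <- 2 / h^2 # ghost node: u_{-1} = u_1
  b <- rhs_fun(x[seq_len(m)])
  b[m] <- b[m] - bc / h^2
  c(solve(M, b), bc)
}

# Richardson-extrapolated version (O(h^4)); returns values on the n-grid.
dense_bvp_rich <- function(c_coef, rhs_fun, n, bc = 0) {
  u1 <- dense_bvp(c_coef, rhs_fun, n, bc)
  u2 <- dense_bvp(c_coef, rhs_fun, 2 * (n - 1) + 1, bc)
  (4 * u2[seq(1, 2 * (n - 1) + 1, by = 2)] - u1) / 3
}

# Leading-order steady profiles by the dense oracle (solves the linear
# system sequentially: C0 decoupled, then A0 and B0 forced by it).
oracle_leading_order <- function(p, n = 801) {
  x <- seq(0, 1, length.out = n)
  C0 <- dense_bvp_rich(p$lambda2, function(xx) 0 * xx, n, bc = 1)
  c0f <- function(xx) stats::spline(x, C0, xout = xx)$y
  A0 <- dense_bvp_rich(p$lambda3 / p$delta_A,
                       function(xx) -(p$lambda2 * p$mu_A / p$delta_A) * c0f(xx),
                       n, bc = 1)
  B0 <- dense_bvp_rich(p$lambda4 / p$delta_B,
                       function(xx) -(p$lambda5 / p$delta_B) * c0f(xx),
                       n, bc = 1)
  list(x = x, A0 = A0, B0 = B0, C0 = C0)
}

# Fourth-order second derivative on interior nodes 3..(n-2) of a uniform
# grid; used to certify residuals of closed-form solutions well below the
# O(h^2) floor of central differences.
d2_o4 <- function(u, h) {
  n <- length(u)
  i <- 3:(n - 2)
  (-u[i - 2] + 16 * u[i - 1] - 30 * u[i] + 16 * u[i + 1] - u[i + 2]) /
    (12 * h^2)
}

# Max-norm residuals of the O(lambda1) correction system for given
# correction profiles on a uniform grid (interior nodes only).
correction_residuals <- function(p, x, A1, B1, C1) {
  h <- x[2] - x[1]
  i <- 3:(length(x) - 2)
  FF <- leading_order_A(x, p) * leading_order_B(x, p)
  rA <- d2_o4(A1, h) - (p$mu_A / p$delta_A) * FF[i] +
    (p$lambda2 * p$mu_A / p$delta_A) * C1[i] - (p$lambda3 / p$delta_A) * A1[i]
  rB <- d2_o4(B1, h) - (p$mu_B / p$delta_B) * FF[i] -
    (p$lambda4 / p$delta_B) * B1[i] + (p$lambda5 / p$delta_B) * C1[i]
  rC <- d2_o4(C1, h) + FF[i] - p$lambda2 * C1[i]
  c(A = max(abs(rA)), B = max(abs(rB)), C = max(abs(rC)))
}

# Scale on which round-off limits a finite-difference residual measurement
# of the assembled corrections: the summed magnitude of the cosh modes
# (large modes can cancel to an O(1) profile, and eps * amplitude / h^2
# noise survives in any second-difference check).
modal_amplitude <- function(cf) {
  grow <- cosh(cf$theta)
  kq <- cf$wavenumbers[["q"]]
  c(A = sum(abs(cf$coefA$a) * grow) + abs(cf$coefA$a7) * cosh(2 * kq) +
      abs(cf$coefA$a8) * cosh(kq) + abs(cf$coefA$star),
    B = sum(abs(cf$coefB$b) * grow) + abs(cf$coefB$b7) * cosh(2 * kq) +
      abs(cf$coefB$b8) + abs(cf$coefB$b9) * cosh(kq) + abs(cf$coefB$star),
    C = sum(abs(cf$coefC$c) * grow) + abs(cf$coefC$c7) * cosh(2 * kq) +
      abs(cf$coefC$c8) + abs(cf$coefC$star))
}

# Random O(1) dimensionless parameter set (lambda1 = 0 unless given).
rand_o1_params <- function(lambda1 = 0) {
  dimensionless_parameters(
    lambda1 = lambda1,
    lambda2 = runif(1, 0.5, 5),
    lambda3 = runif(1, 0, 2),
    lambda4 = runif(1, 0, 2),
    lambda5 = runif(1, 0, 2),
    delta_A = runif(1, 0.5, 2),
    delta_B = runif(1, 0.5, 2),
    mu_A = runif(1, 0.5, 2),
    mu_B = runif(1, 0.5, 2)
  )
}
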