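#' Overflow-safe evaluation of cosh(k x)/cosh(k)
#'
#' The leading-order steady solutions are built from ratios
#' `cosh(k x)/cosh(k)` with wavenumbers `k` that can be very large (fast
#' complex breakdown gives `k = sqrt(lambda2)` with `lambda2` up to 1e12).
#' Naive `cosh()` overflows near `k = 710`, so the ratio is computed as
#' \deqn{e^{k(x-1)} \frac{1 + e^{-2kx}}{1 + e^{-2k}},}
#' which involves only non-positive exponents.
#'
#' @param k Non-negative wavenumber (scalar).
#' @param x Positions in `[0, 1]` (vectorised).
#' @return `cosh(k x)/cosh(k)`, exactly 1 at `x = 1` for any `k` and
#'   identically 1 for `k = 0`.
#' @export
cosh_ratio <- function(k, x) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k), k >= 0)
  if (any(x < 0 | x > 1)) {
    stop("cosh_ratio: 'x' must lie in [0, 1]", call. = FALSE)
  }
  exp(k * (x - 1)) * (1 + exp(-2 * k * x)) / (1 + exp(-2 * k))
}

# x * sinh(k x)/cosh(k), same overflow-safe form; used by the degenerate
# (resonant) branches of the leading-order solutions.
xsinh_ratio <- function(k, x) {
  x * exp(k * (x - 1)) * (1 - exp(-2 * k * x)) / (1 + exp(-2 * k))
}

#' Leading-order steady complex concentration
#'
#' In the small-complex-formation-rate regime the complex decouples: it
#' enters at the boundary and decays throughout the tissue at rate
#' `lambda2`, giving
#' \deqn{C_0(x) = \frac{\cosh(\sqrt{\lambda_2}\,x)}{\cosh\sqrt{\lambda_2}}.}
#' For large `lambda2` this is a boundary layer of width
#' `O(lambda2^{-1/2})` at the tissue edge.
#'
#' @param x Positions in `[0, 1]`.
#' @param p A [dimensionless_parameters()] object.
#' @return `C0` values at `x`.
#' @export
leading_order_C <- function(x, p) {
  validate_dimensionless_parameters(p, strict = FALSE)
  cosh_ratio(sqrt(p$lambda2), x)
}

#' Leading-order steady free-chemical concentration
#'
#' Closed-form solution of the linear steady balance
#' `delta_A A0'' + lambda2 mu_A C0 - lambda3 A0 = 0` with symmetry at
#' `x = 0` and `A0(1) = 1`. The regular branch
#' (`delta_A lambda2 != lambda3`) is
#' \deqn{A_0 = \Big(1 + \frac{\mu_A\lambda_2}{\delta_A\lambda_2-\lambda_3}\Big)
#'   \frac{\cosh(\sqrt{\lambda_3/\delta_A}\,x)}{\cosh\sqrt{\lambda_3/\delta_A}}
#'   - \frac{\mu_A\lambda_2}{\delta_A\lambda_2-\lambda_3}
#'   \frac{\cosh(\sqrt{\lambda_2}\,x)}{\cosh\sqrt{\lambda_2}}.}
#' On the resonant locus `delta_A lambda2 == lambda3` the second
#' homogeneous mode coincides with the forcing mode and the solution picks
#' up a secular `x sinh` term (the limit of the regular branch). With
#' `lambda2 = lambda3 = 0` the equation has no source and no sink and
#' `A0 == 1`.
#'
#' @inheritParams leading_order_C
#' @return `A0` values at `x`.
#' @export
leading_order_A <- function(x, p) {
  validate_dimensionless_parameters(p, strict = FALSE)
  l2 <- p$lambda2; l3 <- p$lambda3; muA <- p$mu_A; dA <- p$delta_A
  if (l2 == 0 && l3 == 0) {
    return(cosh_ratio(0, x)) # validates x, returns 1s
  }
  if (dA * l2 == l3) {
    k <- sqrt(l2)
    amp <- muA * k / (2 * dA)
    (1 + amp * tanh(k)) * cosh_ratio(k, x) - amp * xsinh_ratio(k, x)
  } else {
    pref <- muA * l2 / (dA * l2 - l3)
    (1 + pref) * cosh_ratio(sqrt(l3 / dA), x) - pref * cosh_ratio(sqrt(l2), x)
  }
}

#' Leading-order steady binding-partner concentration
#'
#' Mirrors [leading_order_A()] for the balance
#' `delta_B B0'' - lambda4 B0 + lambda5 C0 = 0`: the removal rate `lambda4`
#' plays the role of `lambda3` and the breakdown source `lambda5` that of
#' `lambda2 mu_A`. With `lambda2 = lambda4 = 0` the forcing is uniform and
#' the solution is the parabola `1 + lambda5 (1 - x^2) / (2 delta_B)`.
#'
#' @inheritParams leading_order_C
#' @return `B0` values at `x`.
#' @export
leading_order_B <- function(x, p) {
  validate_dimensionless_parameters(p, strict = FALSE)
  l2 <- p$lambda2; l4 <- p$lambda4; l5 <- p$lambda5; dB <- p$delta_B
  if (l2 == 0 && l4 == 0) {
    ones <- cosh_ratio(0, x)
    return(ones + l5 * (1 - x^2) / (2 * dB))
  }
  if (dB * l2 == l4) {
    k <- sqrt(l2)
    amp <- l5 / (2 * dB * k)
    (1 + amp * tanh(k)) * cosh_ratio(k, x) - amp * xsinh_ratio(k, x)
  } else {
    pref <- l5 / (dB * l2 - l4)
    (1 + pref) * cosh_ratio(sqrt(l4 / dB), x) - pref * cosh_ratio(sqrt(l2), x)
  }
}

#' Free-chemical concentration at the tissue centre
#'
#' `A0(0)`, the quantity a delivery strategy aims to maximise. With no
#' removal of the free chemical (`lambda3 = 0`) and fast complex breakdown
#' (`lambda2 -> Inf`) it approaches the supply-limited bound
#' `1 + mu_A/delta_A`.
#'
#' @inheritParams leading_order_C
#' @return The scalar `A0(0)`.
#' @export
central_A0 <- function(p) {
  leading_order_A(0, p)
}

#' Leading-order steady profile on a grid
#'
#' Convenience wrapper assembling `A0`, `B0`, `C0` into a
#' [concentration_profile()].
#'
#' @param p A [dimensionless_parameters()] object.
#' @param x Grid positions (default 501 equispaced nodes, matching the
#'   solver default `dx = 0.002`).
#' @return A steady [concentration_profile()].
#' @export
leading_order_profile <- function(p, x = seq(0, 1, length.out = 501L)) {
  concentration_profile(
    x = x,
    A = leading_order_A(x, p),
    B = leading_order_B(x, p),
    C = leading_order_C(x, p),
    t = "steady"
  )
}
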