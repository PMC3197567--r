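#' Dimensional model parameters
#'
#' Bundles the physical constants of the three-species reaction--diffusion
#' system: a free chemical *a* and its binding partner *b* associate
#' reversibly into a complex *c*, which can additionally be cleaved within
#' the tissue to release *a*. All three species diffuse; *a* and *b* are
#' removed at constant rates.
#'
#' @param D_A,D_B,D_C Diffusivities of *a*, *b*, *c* (cm^2 s^-1); strictly
#'   positive.
#' @param k_plus1 Association rate of *a* + *b* -> *c* (M^-1 s^-1); strictly
#'   positive.
#' @param k_minus1 Dissociation rate of *c* -> *a* + *b* (s^-1); may be zero.
#' @param k_minus2 Cleavage rate of *c* -> *a* (binding partner destroyed in
#'   the complex, s^-1); may be zero.
#' @param alpha1,alpha2 Removal rates of *a* and *b* (s^-1); may be zero.
#' @param L Tissue half-width lengthscale (cm); strictly positive.
#' @param A_star,B_star,C_star Boundary concentrations of *a*, *b*, *c* (M);
#'   strictly positive (they are the concentration scales of the
#'   nondimensionalisation and appear in denominators).
#'
#' @return An object of class `dimensional_parameters` (a named list).
#' @seealso [nondimensionalise()]
#' @examples
#' igf <- dimensional_parameters(
#'   D_A = 1e-7, D_B = 1e-7, D_C = 1e-7,
#'   k_plus1 = 1e5, k_minus1 = 0, k_minus2 = 0,
#'   alpha1 = 0, alpha2 = 0, L = 1e-1,
#'   A_star = 1e-11, B_star = 1e-11, C_star = 1e-9
#' )
#' nondimensionalise(igf)$lambda1 # 1e-3
#' @export
dimensional_parameters <- function(D_A, D_B, D_C, k_plus1,
                                   k_minus1 = 0, k_minus2 = 0,
                                   alpha1 = 0, alpha2 = 0,
                                   L, A_star, B_star, C_star) {
  p <- list(
    D_A = D_A, D_B = D_B, D_C = D_C, k_plus1 = k_plus1,
    k_minus1 = k_minus1, k_minus2 = k_minus2,
    alpha1 = alpha1, alpha2 = alpha2,
    L = L, A_star = A_star, B_star = B_star, C_star = C_star
  )
  validate_dimensional_parameters(p)
  structure(p, class = "dimensional_parameters")
}

validate_dimensional_parameters <- function(p) {
  strict <- c("D_A", "D_B", "D_C", "k_plus1", "L", "A_star", "B_star", "C_star")
  nonneg <- c("k_minus1", "k_minus2", "alpha1", "alpha2")
  probs <- character(0)
  for (f in c(strict, nonneg)) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      probs <- c(probs, sprintf("'%s' must be a single finite number", f))
    } else if (f %in% strict && v <= 0) {
      probs <- c(probs, sprintf("'%s' must be strictly positive (got %g)", f, v))
    } else if (v < 0) {
      probs <- c(probs, sprintf("'%s' must be non-negative (got %g)", f, v))
    }
  }
  if (length(probs)) {
    stop("invalid dimensional parameters: ", paste(probs, collapse = "; "),
         call. = FALSE)
  }
  invisible(p)
}

#' Dimensionless model parameters
#'
#' The nine dimensionless groups governing the rescaled system. Space is
#' scaled by the tissue half-width `L`, time by the complex diffusion
#' timescale `L^2/D_C`, and each concentration by its boundary value, giving
#'
#' * `lambda1`: relative rate of complex formation,
#' * `lambda2`, `lambda5`: relative rates of complex breakdown releasing
#'   *a* and *b* respectively,
#' * `lambda3`, `lambda4`: dimensionless removal rates of *a* and *b*,
#' * `delta_A`, `delta_B`: diffusivities of *a*, *b* relative to the complex,
#' * `mu_A`, `mu_B`: boundary concentration of the complex relative to those
#'   of *a* and *b*.
#'
#' @param lambda1,lambda2,lambda3,lambda4,lambda5 Dimensionless reaction and
#'   removal rates; non-negative.
#' @param delta_A,delta_B Diffusivity ratios; strictly positive.
#' @param mu_A,mu_B Boundary concentration ratios; strictly positive.
#' @param strict Require `mu_A`, `mu_B` strictly positive (default). The
#'   relaxation `strict = FALSE` admits `mu_B = 0` (a binding partner absent
#'   from the boundary), used by the [fixture()] `"reviewer1_counterexample"`;
#'   `mu_B` only multiplies the bilinear term of the *b* equation so its
#'   zero limit is well defined.
#'
#' @return An object of class `dimensionless_parameters` (a named list).
#' @examples
#' p <- dimensionless_parameters(lambda2 = 50, lambda3 = 0.5)
#' leading_order_A(0, p)
#' @export
dimensionless_parameters <- function(lambda1 = 0, lambda2 = 0, lambda3 = 0,
                                     lambda4 = 0, lambda5 = 0,
                                     delta_A = 1, delta_B = 1,
                                     mu_A = 1, mu_B = 1,
                                     strict = TRUE) {
  p <- list(
    lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
    lambda4 = lambda4, lambda5 = lambda5,
    delta_A = delta_A, delta_B = delta_B, mu_A = mu_A, mu_B = mu_B
  )
  validate_dimensionless_parameters(p, strict = strict)
  structure(p, class = "dimensionless_parameters")
}

validate_dimensionless_parameters <- function(p, strict = TRUE) {
  nonneg <- c("lambda1", "lambda2", "lambda3", "lambda4", "lambda5")
  pos <- c("delta_A", "delta_B", "mu_A", if (strict) "mu_B")
  probs <- character(0)
  for (f in c(nonneg, "delta_A", "delta_B", "mu_A", "mu_B")) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      probs <- c(probs, sprintf("'%s' must be a single finite number", f))
    } else if (f %in% pos && v <= 0) {
      probs <- c(probs, sprintf("'%s' must be strictly positive (got %g)", f, v))
    } else if (v < 0) {
      probs <- c(probs, sprintf("'%s' must be non-negative (got %g)", f, v))
    }
  }
  if (length(probs)) {
    stop("invalid dimensionless parameters: ", paste(probs, collapse = "; "),
         call. = FALSE)
  }
  invisible(p)
}

#' Nondimensionalise a dimensional parameter set
#'
#' Forms the nine dimensionless groups from the physical constants:
#' \deqn{\lambda_1 = \frac{L^2 k_{+1} A^* B^*}{C^* D_C},\quad
#'       \lambda_2 = \frac{L^2 (k_{-1}+k_{-2})}{D_C},\quad
#'       \lambda_3 = \frac{\alpha_1 L^2}{D_C},\quad
#'       \lambda_4 = \frac{\alpha_2 L^2}{D_C},\quad
#'       \lambda_5 = \frac{L^2 k_{-1} C^*}{B^* D_C},}
#' \deqn{\delta_A = D_A/D_C,\quad \delta_B = D_B/D_C,\quad
#'       \mu_A = C^*/A^*,\quad \mu_B = C^*/B^*.}
#'
#' @param dim A [dimensional_parameters()] object.
#' @return A [dimensionless_parameters()] object.
#' @export
nondimensionalise <- function(dim) {
  stopifnot(inherits(dim, "dimensional_parameters"))
  validate_dimensional_parameters(dim)
  tscale <- dim$L^2 / dim$D_C
  dimensionless_parameters(
    lambda1 = tscale * dim$k_plus1 * dim$A_star * dim$B_star / dim$C_star,
    lambda2 = tscale * (dim$k_minus1 + dim$k_minus2),
    lambda3 = tscale * dim$alpha1,
    lambda4 = tscale * dim$alpha2,
    lambda5 = tscale * dim$k_minus1 * dim$C_star / dim$B_star,
    delta_A = dim$D_A / dim$D_C,
    delta_B = dim$D_B / dim$D_C,
    mu_A = dim$C_star / dim$A_star,
    mu_B = dim$C_star / dim$B_star
  )
}

#' Restore physical units to a dimensionless concentration profile
#'
#' Inverts the nondimensionalisation scalings: positions are multiplied by
#' the half-width `L`, concentrations by their boundary values, and the time
#' stamp (when numeric) by the complex diffusion timescale `L^2/D_C`.
#'
#' @param profile A [concentration_profile()].
#' @param dim The [dimensional_parameters()] that define the scales.
#' @return A list with fields `x` (cm), `A`, `B`, `C` (M) and `t`
#'   (seconds, or `"steady"`).
#' @export
redimensionalise <- function(profile, dim) {
  stopifnot(inherits(profile, "concentration_profile"),
            inherits(dim, "dimensional_parameters"))
  t_out <- profile$t
  if (is.numeric(t_out)) t_out <- t_out * dim$L^2 / dim$D_C
  list(
    x = profile$x * dim$L,
    A = profile$A * dim$A_star,
    B = profile$B * dim$B_star,
    C = profile$C * dim$C_star,
    t = t_out
  )
}

#' @export
print.dimensional_parameters <- function(x, ...) {
  cat("Dimensional parameters (cgs/molar units):\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' @export
print.dimensionless_parameters <- function(x, ...) {
  cat("Dimensionless parameters:\n")
  print(unlist(unclass(x)))
  invisible(x)
}
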