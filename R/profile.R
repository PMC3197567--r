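#' Concentration profile container
#'
#' One snapshot (or the steady state) of the three dimensionless
#' concentrations on the half-domain `0 <= x <= 1`. Concentrations are
#' relative to their boundary values, so the Dirichlet condition at the
#' tissue edge is `A = B = C = 1` at `x = 1`.
#'
#' @param x Strictly increasing grid positions with `x[1] == 0` and
#'   `x[length(x)] == 1`.
#' @param A,B,C Concentration values at each position; finite, same length
#'   as `x`.
#' @param t Elapsed dimensionless time, or the marker `"steady"`.
#'
#' @return An object of class `concentration_profile`.
#' @export
concentration_profile <- function(x, A, B, C, t = "steady") {
  p <- structure(list(x = as.numeric(x), A = as.numeric(A),
                      B = as.numeric(B), C = as.numeric(C), t = t),
                 class = "concentration_profile")
  validate_concentration_profile(p)
  p
}

validate_concentration_profile <- function(p) {
  x <- p$x
  if (length(x) < 2L || any(diff(x) <= 0)) {
    stop("profile positions must be strictly increasing", call. = FALSE)
  }
  if (abs(x[1L]) > 1e-12 || abs(x[length(x)] - 1) > 1e-12) {
    stop("profile positions must span [0, 1] exactly", call. = FALSE)
  }
  for (s in c("A", "B", "C")) {
    v <- p[[s]]
    if (length(v) != length(x)) {
      stop(sprintf("species '%s' must have one value per grid position", s),
           call. = FALSE)
    }
    if (!all(is.finite(v))) {
      stop(sprintf("species '%s' contains non-finite values", s), call. = FALSE)
    }
  }
  ok_t <- (is.numeric(p$t) && length(p$t) == 1L && is.finite(p$t)) ||
    identical(p$t, "steady")
  if (!ok_t) stop("'t' must be a finite number or \"steady\"", call. = FALSE)
  invisible(p)
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf("Concentration profile on %d nodes, t = %s\n",
              length(x$x), if (is.numeric(x$t)) format(x$t) else x$t))
  cat(sprintf("  A in [%.4g, %.4g], B in [%.4g, %.4g], C in [%.4g, %.4g]\n",
              min(x$A), max(x$A), min(x$B), max(x$B), min(x$C), max(x$C)))
  invisible(x)
}

#' @export
as.data.frame.concentration_profile <- function(x, ...) {
  data.frame(x = x$x, A = x$A, B = x$B, C = x$C)
}
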