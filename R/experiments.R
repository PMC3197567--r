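#' Classify the shape of a steady free-chemical profile
#'
#' Steady profiles of the free chemical fall into three regimes, controlled
#' chiefly by its removal rate `lambda3` relative to the complex breakdown
#' rate `lambda2`:
#'
#' * `centre_maximum` — the global maximum sits at the tissue centre
#'   `x = 0` (small `lambda3`);
#' * `interior_maximum` — a minimum at the centre with the maximum at an
#'   interior point (intermediate `lambda3`);
#' * `monotone_from_boundary` — concentration declines monotonically away
#'   from the boundary, maximum at `x = 1` (large `lambda3`).
#'
#' Ties on a discrete grid are resolved explicitly: values within
#' `1e-9 * max(A)` of the maximum count as maximal; if a maximal value
#' occurs within one node of `x = 1` (including a constant profile) the
#' regime is `monotone_from_boundary`, otherwise a maximal value at
#' `x = 0` gives `centre_maximum`.
#'
#' @param profile A [concentration_profile()] with at least 101 nodes
#'   (coarser sampling makes the discrete argmax unreliable).
#' @return An object of class `regime_classification`: fields `regime`,
#'   `argmax_x` and `max_value`.
#' @export
classify_profile <- function(profile) {
  stopifnot(inherits(profile, "concentration_profile"))
  A <- profile$A
  n <- length(A)
  if (n < 101L) {
    stop("classification needs at least 101 nodes", call. = FALSE)
  }
  m <- max(A)
  tol <- 1e-9 * max(abs(m), 1)
  near <- which(A >= m - tol)
  if (any(near >= n - 1L)) {
    out <- list(regime = "monotone_from_boundary", argmax_x = 1,
                max_value = A[n])
  } else if (1L %in% near) {
    out <- list(regime = "centre_maximum", argmax_x = 0, max_value = A[1L])
  } else {
    i <- which.max(A)
    out <- list(regime = "interior_maximum", argmax_x = profile$x[i],
                max_value = A[i])
  }
  structure(out, class = "regime_classification")
}

#' @export
print.regime_classification <- function(x, ...) {
  cat(sprintf("Regime: %s (argmax x = %.4g, A = %.6g)\n",
              x$regime, x$argmax_x, x$max_value))
  invisible(x)
}

new_sweep_result <- function(parameter, values, profiles) {
  stopifnot(length(values) == length(profiles))
  structure(list(
    swept_parameter = parameter,
    values = values,
    profiles = profiles,
    classifications = lapply(profiles, classify_profile)
  ), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep over %s (%d values):\n", x$swept_parameter,
              length(x$values)))
  for (i in seq_along(x$values)) {
    cl <- x$classifications[[i]]
    cat(sprintf("  %s = %-8g -> %s (A_max = %.6g at x = %.3g)\n",
                x$swept_parameter, x$values[i], cl$regime, cl$max_value,
                cl$argmax_x))
  }
  invisible(x)
}

# Swap one lambda/ratio in a dimensionless parameter set.
set_param <- function(p, name, value) {
  q <- unclass(p)
  q[[name]] <- value
  do.call(dimensionless_parameters, c(q, list(strict = FALSE)))
}

#' Breakdown-rate sweep: free chemical accumulation with no removal
#'
#' Leading-order profiles over a range of complex-breakdown rates
#' `lambda2`, holding `lambda3 = 0`, `mu_A = 100`, `delta_A = 1`
#' (and `lambda1 = 0`). As `lambda2` grows the complex is consumed in a
#' thin boundary layer while the free chemical approaches its
#' supply-limited ceiling `1 + mu_A/delta_A = 101` through most of the
#' tissue: apparently poor penetration of the complex coincides with high
#' levels of the active chemical.
#'
#' @param lambda2_values Swept breakdown rates.
#' @param x Evaluation grid.
#' @return A `sweep_result`.
#' @export
figure2_sweep <- function(lambda2_values = c(1, 5, 20, 100, 1000),
                          x = seq(0, 1, length.out = 501L)) {
  base <- dimensionless_parameters(mu_A = 100, mu_B = 1,
                                   delta_A = 1, delta_B = 1)
  profiles <- lapply(lambda2_values, function(l2) {
    leading_order_profile(set_param(base, "lambda2", l2), x = x)
  })
  new_sweep_result("lambda2", lambda2_values, profiles)
}

#' Removal-rate sweep: the three profile regimes
#'
#' Leading-order profiles over a range of free-chemical removal rates
#' `lambda3`, holding `lambda2 = 50`, `mu_A = delta_A = 1`,
#' `lambda1 = lambda4 = lambda5 = 0`. As `lambda3` increases the
#' classification passes through `centre_maximum`, `interior_maximum` and
#' `monotone_from_boundary`.
#'
#' @param lambda3_values Swept removal rates.
#' @param x Evaluation grid.
#' @return A `sweep_result`.
#' @export
figure3_sweep <- function(lambda3_values = c(0.01, 0.05, 0.2, 1, 5, 20, 50),
                          x = seq(0, 1, length.out = 501L)) {
  base <- dimensionless_parameters(lambda2 = 50)
  profiles <- lapply(lambda3_values, function(l3) {
    leading_order_profile(set_param(base, "lambda3", l3), x = x)
  })
  new_sweep_result("lambda3", lambda3_values, profiles)
}

#' Central free-chemical concentration over the (lambda2, lambda3) plane
#'
#' Evaluates `A0(0)` on a grid of breakdown and removal rates with
#' `mu_A = delta_A = 1`. The surface is maximal at `lambda3 = 0` and large
#' `lambda2`, approaching the ceiling `1 + mu_A/delta_A = 2`, and is
#' non-increasing in `lambda3` along every `lambda2` slice.
#'
#' @param lambda2_values,lambda3_values Grid of rates.
#' @return An object of class `surface_result`: fields `lambda2`,
#'   `lambda3` and matrix `A0_centre` (rows index `lambda2`).
#' @export
figure4_surface <- function(lambda2_values = 10^seq(-1, 8, length.out = 19L),
                            lambda3_values = c(0, 10^seq(-2, 2, length.out = 17L))) {
  base <- dimensionless_parameters()
  z <- outer(seq_along(lambda2_values), seq_along(lambda3_values),
             Vectorize(function(i, j) {
               p <- set_param(set_param(base, "lambda2", lambda2_values[i]),
                              "lambda3", lambda3_values[j])
               central_A0(p)
             }))
  dimnames(z) <- list(signif(lambda2_values, 6), signif(lambda3_values, 6))
  structure(list(lambda2 = lambda2_values, lambda3 = lambda3_values,
                 A0_centre = z),
            class = "surface_result")
}

#' First-order correction profiles for three representative parameter sets
#'
#' Evaluates `A1` and `C1` (and `B1`) for three parameter sets in the
#' small-`lambda1` regime; all hold `lambda4 = 0.2`,
#' `lambda5 = mu_B = delta_A = delta_B = 1`:
#' `dashed` (`lambda2 = 5, lambda3 = 0.5, mu_A = 1`),
#' `dotdash` (`lambda2 = 2, lambda3 = 1.5, mu_A = 1`) and
#' `solid` (`lambda2 = 1, lambda3 = 0.5, mu_A = 5`).
#' In each case the correction reduces the free chemical and raises the
#' complex throughout the tissue, most strongly at the centre.
#'
#' @param x Evaluation grid.
#' @return Named list of per-curve lists with fields `params`, `x`, `A1`,
#'   `B1`, `C1`.
#' @export
figure5_corrections <- function(x = seq(0, 1, length.out = 501L)) {
  sets <- list(
    dashed = list(lambda2 = 5, lambda3 = 0.5, mu_A = 1),
    dotdash = list(lambda2 = 2, lambda3 = 1.5, mu_A = 1),
    solid = list(lambda2 = 1, lambda3 = 0.5, mu_A = 5)
  )
  lapply(sets, function(s) {
    p <- dimensionless_parameters(
      lambda2 = s$lambda2, lambda3 = s$lambda3, lambda4 = 0.2, lambda5 = 1,
      mu_A = s$mu_A, mu_B = 1, delta_A = 1, delta_B = 1
    )
    corr <- first_order_correction(x, p)
    list(params = p, x = x, A1 = corr$A1, B1 = corr$B1, C1 = corr$C1)
  })
}

run_lambda1_sweep <- function(base, lambda1_values, config) {
  profiles <- lapply(lambda1_values, function(l1) {
    sol <- run_to_steady(set_param(base, "lambda1", l1), config)
    if (!sol$converged) {
      warning(sprintf("solver did not converge for lambda1 = %g", l1),
              call. = FALSE)
    }
    sol$profile
  })
  new_sweep_result("lambda1", lambda1_values, profiles)
}

#' Full-model sweep over the complex formation rate (O(1) parameters)
#'
#' Steady solutions of the full nonlinear system for several values of
#' `lambda1` at the O(1) reference set `lambda2 = 5`, `lambda3 = 0.5`,
#' `lambda4 = lambda5 = mu_A = mu_B = delta_A = delta_B = 1`. Increasing
#' `lambda1` lowers the free chemical and raises the complex pointwise.
#'
#' @param lambda1_values Swept complex-formation rates.
#' @param config A [solver_config()].
#' @return A `sweep_result` of steady profiles.
#' @export
figure6_sweep <- function(lambda1_values = c(0, 2, 20),
                          config = solver_config()) {
  base <- fixture("fig6")$params
  run_lambda1_sweep(base, lambda1_values, config)
}

#' Full-model sweep with strong coupling (non-O(1) parameters)
#'
#' Steady solutions at `lambda2 = 1`, `lambda3 = lambda4 = 0.5`,
#' `lambda5 = 12`, `mu_A = 10`, `mu_B = 0.2`, `delta_A = 0.02`,
#' `delta_B = 0.1`. Because `mu_A/delta_A` is large, even
#' `lambda1 = 0.01` shifts the free-chemical profile appreciably — the
#' two-term perturbation expansion is not valid here.
#'
#' @inheritParams figure6_sweep
#' @return A `sweep_result` of steady profiles.
#' @export
figure7_sweep <- function(lambda1_values = c(0, 0.01),
                          config = solver_config()) {
  base <- fixture("fig7")$params
  run_lambda1_sweep(base, lambda1_values, config)
}

#' Variant of [figure7_sweep()] with fast binding-partner removal
#'
#' Identical to [figure7_sweep()] except `lambda4 = 10`: removing the
#' binding partner faster leaves less of it to tie up the free chemical,
#' so the steady free-chemical concentration rises.
#'
#' @inheritParams figure6_sweep
#' @return A `sweep_result` of steady profiles.
#' @export
figure8_sweep <- function(lambda1_values = c(0, 0.01),
                          config = solver_config()) {
  base <- fixture("fig8")$params
  run_lambda1_sweep(base, lambda1_values, config)
}

#' Compare the perturbation approximation with the full numerical solution
#'
#' Runs the full solver to steady state and evaluates the two-term
#' expansion `A0 + lambda1 A1` (etc.) on the same grid, reporting the
#' per-species maximum absolute and relative discrepancies. Any expansion
#' validity warnings raised while evaluating the approximation are
#' captured in the report.
#'
#' @param p A [dimensionless_parameters()] object (`p$lambda1` is the
#'   expansion parameter).
#' @param config A [solver_config()].
#' @return An object of class `analytic_numeric_report`: fields
#'   `max_abs`, `max_rel` (named per species), `converged`, `steps`,
#'   `warnings` (character vector) and the two profiles.
#' @export
compare_analytic_numeric <- function(p, config = solver_config()) {
  sol <- run_to_steady(p, config)
  warns <- character(0)
  approx <- withCallingHandlers(
    small_lambda1_profile(sol$profile$x, p),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  max_abs <- c(A = max(abs(sol$profile$A - approx$A)),
               B = max(abs(sol$profile$B - approx$B)),
               C = max(abs(sol$profile$C - approx$C)))
  max_rel <- c(A = max(abs(sol$profile$A - approx$A) / pmax(abs(approx$A), 1e-12)),
               B = max(abs(sol$profile$B - approx$B) / pmax(abs(approx$B), 1e-12)),
               C = max(abs(sol$profile$C - approx$C) / pmax(abs(approx$C), 1e-12)))
  structure(list(max_abs = max_abs, max_rel = max_rel,
                 converged = sol$converged, steps = sol$steps_taken,
                 warnings = warns,
                 numeric = sol$profile, analytic = approx),
            class = "analytic_numeric_report")
}

#' @export
print.analytic_numeric_report <- function(x, ...) {
  cat("Perturbation expansion vs full numerical steady state:\n")
  cat("  max abs diff: ",
      paste(sprintf("%s=%.3g", names(x$max_abs), x$max_abs), collapse = ", "),
      "\n")
  cat("  max rel diff: ",
      paste(sprintf("%s=%.3g", names(x$max_rel), x$max_rel), collapse = ", "),
      "\n")
  if (length(x$warnings)) {
    cat("  validity warnings:\n")
    for (w in x$warnings) cat("   - ", w, "\n")
  }
  invisible(x)
}
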