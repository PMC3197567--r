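DIMENSIONAL_FIELDS <- c("D_A", "D_B", "D_C", "k_plus1", "k_minus1",
                        "k_minus2", "alpha1", "alpha2", "L",
                        "A_star", "B_star", "C_star")
DIMENSIONLESS_FIELDS <- c("lambda1", "lambda2", "lambda3", "lambda4",
                          "lambda5", "delta_A", "delta_B", "mu_A", "mu_B")
SOLVER_FIELDS <- c("dx", "dt", "steady_tol", "max_steps", "report_every")

run_manifest <- function(config, diagnostics = NULL) {
  list(
    package = "cdtarget",
    version = as.character(utils::packageVersion("cdtarget")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    diagnostics = diagnostics
  )
}

check_numeric_fields <- function(block, allowed, required, label) {
  probs <- character(0)
  unknown <- setdiff(names(block), allowed)
  if (length(unknown)) {
    probs <- c(probs, sprintf("%s: unknown key(s) %s", label,
                              paste(sQuote(unknown), collapse = ", ")))
  }
  missing <- setdiff(required, names(block))
  if (length(missing)) {
    probs <- c(probs, sprintf("%s: missing required key(s) %s", label,
                              paste(sQuote(missing), collapse = ", ")))
  }
  for (f in intersect(names(block), allowed)) {
    v <- block[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      probs <- c(probs, sprintf("%s: '%s' must be a single finite number",
                                label, f))
    }
  }
  probs
}

#' Load a model configuration from JSON
#'
#' The file must contain exactly one of the top-level objects
#' `"dimensional"` (fields as in [dimensional_parameters()]) or
#' `"dimensionless"` (fields as in [dimensionless_parameters()]), plus an
#' optional `"solver"` object (fields as in [solver_config()]; defaults
#' applied for omitted fields). Dimensional inputs are nondimensionalised
#' on load, and the resulting groups are echoed in the manifest. All
#' problems (unknown keys, missing keys, non-numeric values) are reported
#' in a single error.
#'
#' @param path Path to a JSON file.
#' @return A list with fields `params` (a [dimensionless_parameters()]),
#'   `dimensional` (the original [dimensional_parameters()] or `NULL`),
#'   `solver` (a [solver_config()]) and `manifest`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  probs <- character(0)
  top <- setdiff(names(raw), c("dimensional", "dimensionless", "solver"))
  if (length(top)) {
    probs <- c(probs, sprintf("unknown top-level key(s) %s",
                              paste(sQuote(top), collapse = ", ")))
  }
  has_dim <- "dimensional" %in% names(raw)
  has_nondim <- "dimensionless" %in% names(raw)
  if (has_dim == has_nondim) {
    probs <- c(probs, "exactly one of 'dimensional' or 'dimensionless' is required")
  }
  if (has_dim) {
    probs <- c(probs, check_numeric_fields(
      raw$dimensional, DIMENSIONAL_FIELDS,
      setdiff(DIMENSIONAL_FIELDS, c("k_minus1", "k_minus2", "alpha1", "alpha2")),
      "dimensional"))
  }
  if (has_nondim) {
    probs <- c(probs, check_numeric_fields(
      raw$dimensionless, DIMENSIONLESS_FIELDS, character(0), "dimensionless"))
  }
  if ("solver" %in% names(raw)) {
    probs <- c(probs, check_numeric_fields(raw$solver, SOLVER_FIELDS,
                                           character(0), "solver"))
  }
  if (length(probs)) {
    stop("invalid configuration '", path, "':\n  - ",
         paste(probs, collapse = "\n  - "), call. = FALSE)
  }
  dim_params <- NULL
  if (has_dim) {
    dim_params <- do.call(dimensional_parameters, as.list(raw$dimensional))
    params <- nondimensionalise(dim_params)
  } else {
    params <- do.call(dimensionless_parameters, as.list(raw$dimensionless))
  }
  solver <- do.call(solver_config, as.list(raw$solver %||% list()))
  list(
    params = params,
    dimensional = dim_params,
    solver = solver,
    manifest = run_manifest(list(
      source = path,
      dimensional = if (has_dim) as.list(unclass(dim_params)),
      dimensionless = as.list(unclass(params)),
      solver = as.list(unclass(solver))
    ))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a loaded configuration back to JSON
#'
#' Emits the dimensionless parameters and solver settings of a
#' configuration as produced by [load_config()]; loading the written file
#' reproduces the same parameters.
#'
#' @param config A list as returned by [load_config()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(
    list(dimensionless = as.list(unclass(config$params)),
         solver = as.list(unclass(config$solver))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Named parameter fixtures
#'
#' Returns the parameter set behind each reported experiment by name:
#' `"fig2"` ... `"fig8"` (the sweep drivers' base sets and swept values),
#' `"igf_estimate"` (the dimensional IGF/IGFBP-like set whose
#' nondimensionalisation gives `lambda1 = 1e-3`) and
#' `"reviewer1_counterexample"` (a set with `lambda1 mu_A/delta_A` large,
#' outside the validity region of the perturbation expansion; its
#' `mu_B = 0` relaxes the strict positivity check, with a warning, since
#' `mu_B` only scales the bilinear term of the binding-partner equation).
#'
#' @param name Fixture name.
#' @return A list with fields `name`, `description`, `params` (a
#'   parameter object) and, where applicable, `sweep` (list with
#'   `parameter` and `values`).
#' @export
fixture <- function(name) {
  fixtures <- list(
    fig2 = function() list(
      description = "leading-order breakdown-rate sweep; lambda3 = 0, mu_A = 100, delta_A = 1 (swept lambda2 values are package defaults; only the held parameters are prescribed)",
      params = dimensionless_parameters(mu_A = 100),
      sweep = list(parameter = "lambda2", values = c(1, 5, 20, 100, 1000))
    ),
    fig3 = function() list(
      description = "leading-order removal-rate sweep; lambda2 = 50, mu_A = delta_A = 1 (swept lambda3 values are package defaults)",
      params = dimensionless_parameters(lambda2 = 50),
      sweep = list(parameter = "lambda3",
                   values = c(0.01, 0.05, 0.2, 1, 5, 20, 50))
    ),
    fig4 = function() list(
      description = "central A0 surface over (lambda2, lambda3), mu_A/delta_A = 1",
      params = dimensionless_parameters(),
      sweep = list(parameter = c("lambda2", "lambda3"),
                   values = list(lambda2 = 10^seq(-1, 8, length.out = 19L),
                                 lambda3 = c(0, 10^seq(-2, 2, length.out = 17L))))
    ),
    fig5 = function() list(
      description = "first-order correction terms for three parameter sets; held: lambda4 = 0.2, lambda5 = mu_B = delta_A = delta_B = 1",
      params = list(
        dashed = dimensionless_parameters(lambda2 = 5, lambda3 = 0.5,
                                          lambda4 = 0.2, lambda5 = 1, mu_A = 1),
        dotdash = dimensionless_parameters(lambda2 = 2, lambda3 = 1.5,
                                           lambda4 = 0.2, lambda5 = 1, mu_A = 1),
        solid = dimensionless_parameters(lambda2 = 1, lambda3 = 0.5,
                                         lambda4 = 0.2, lambda5 = 1, mu_A = 5)
      )
    ),
    fig6 = function() list(
      description = "full-model formation-rate sweep at the O(1) set",
      params = dimensionless_parameters(lambda2 = 5, lambda3 = 0.5,
                                        lambda4 = 1, lambda5 = 1),
      sweep = list(parameter = "lambda1", values = c(0, 2, 20))
    ),
    fig7 = function() list(
      description = "full-model sweep with large mu_A/delta_A (expansion invalid)",
      params = dimensionless_parameters(lambda2 = 1, lambda3 = 0.5,
                                        lambda4 = 0.5, lambda5 = 12,
                                        mu_A = 10, mu_B = 0.2,
                                        delta_A = 0.02, delta_B = 0.1),
      sweep = list(parameter = "lambda1", values = c(0, 0.01))
    ),
    fig8 = function() list(
      description = "as fig7 but lambda4 = 10: fast binding-partner removal",
      params = dimensionless_parameters(lambda2 = 1, lambda3 = 0.5,
                                        lambda4 = 10, lambda5 = 12,
                                        mu_A = 10, mu_B = 0.2,
                                        delta_A = 0.02, delta_B = 0.1),
      sweep = list(parameter = "lambda1", values = c(0, 0.01))
    ),
    igf_estimate = function() list(
      description = "order-of-magnitude IGF/IGFBP parameter set; nondimensionalises to lambda1 = 1e-3",
      params = dimensional_parameters(
        D_A = 1e-7, D_B = 1e-7, D_C = 1e-7,
        k_plus1 = 1e5, k_minus1 = 0, k_minus2 = 0,
        alpha1 = 0, alpha2 = 0,
        L = 1e-1, A_star = 1e-11, B_star = 1e-11, C_star = 1e-9
      )
    ),
    reviewer1_counterexample = function() list(
      description = "set with lambda1*mu_A/delta_A = O(10): outside the validity region of the small-lambda1 expansion",
      params = {
        warning(paste0(
          "fixture 'reviewer1_counterexample' has mu_B = 0, relaxing the ",
          "strict positivity of the boundary concentration ratios"),
          call. = FALSE)
        dimensionless_parameters(lambda1 = 0.1, lambda2 = 1, lambda3 = 0.5,
                                 lambda4 = 0.1, lambda5 = 12,
                                 mu_A = 10, mu_B = 0,
                                 delta_A = 0.01, delta_B = 0.1,
                                 strict = FALSE)
      }
    )
  )
  if (!name %in% names(fixtures)) {
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(names(fixtures), collapse = ", ")), call. = FALSE)
  }
  c(list(name = name), fixtures[[name]]())
}

fmt_num <- function(v) sprintf("%.17g", v)

write_csv_full_precision <- function(df, path) {
  cols <- lapply(df, fmt_num)
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
}

#' Write a concentration profile as CSV (with manifest sidecar)
#'
#' Columns `x,A,B,C` at full double precision, plus a JSON manifest
#' sidecar `<path>.manifest.json` echoing the software version and any
#' supplied diagnostics. Repeated writes of the same profile are
#' bit-identical (the timestamp lives only in the sidecar).
#'
#' @param profile A [concentration_profile()].
#' @param path Output CSV path.
#' @param diagnostics Optional list (e.g. convergence info) for the
#'   manifest.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, diagnostics = NULL) {
  stopifnot(inherits(profile, "concentration_profile"))
  write_csv_full_precision(as.data.frame(profile), path)
  jsonlite::write_json(
    run_manifest(list(kind = "profile", t = profile$t,
                      n_nodes = length(profile$x)), diagnostics),
    paste0(path, ".manifest.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a profile CSV written by [write_profile()]
#'
#' @param path CSV path.
#' @param t Time marker to attach (default `"steady"`).
#' @return A [concentration_profile()].
#' @export
read_profile <- function(path, t = "steady") {
  df <- utils::read.csv(path)
  concentration_profile(df$x, df$A, df$B, df$C, t = t)
}

#' Write a sweep result as one CSV per profile (plus manifest)
#'
#' @param result A `sweep_result` (see e.g. [figure3_sweep()]).
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sweep <- function(result, dir) {
  stopifnot(inherits(result, "sweep_result"))
  if (length(result$values) == 0L) stop("empty sweep", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_%03d.csv", result$swept_parameter,
                   seq_along(result$values))
  for (i in seq_along(result$values)) {
    write_csv_full_precision(as.data.frame(result$profiles[[i]]),
                             file.path(dir, files[i]))
  }
  jsonlite::write_json(
    run_manifest(list(
      kind = "sweep", swept_parameter = result$swept_parameter,
      values = result$values, files = files,
      classifications = lapply(result$classifications, unclass)
    )),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' Write a central-concentration surface as long-format CSV
#'
#' Columns `lambda2,lambda3,A0_centre`, one row per grid point.
#'
#' @param surface A `surface_result` from [figure4_surface()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "surface_result"))
  grid <- expand.grid(lambda2 = surface$lambda2, lambda3 = surface$lambda3)
  grid$A0_centre <- as.vector(surface$A0_centre)
  write_csv_full_precision(grid, path)
  invisible(path)
}
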