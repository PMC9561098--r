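#' Thresholds and test-procedure configuration
#'
#' Collects every tunable of the evaluation procedure. Defaults follow the
#' published test protocol for 41-43 cm wide cushions:
#'
#' * redistribution criteria 0.50 (elliptical model) and 0.55 (trigonometric
#'   model) on the bony fraction of total surface pressure;
#' * equivalence band 0.9-1.1 on the internal-pressure ratio to the foam
#'   reference (a 10% meaningful difference);
#' * confidence intervals of the form `mu +/- z * sigma / sqrt(n)` with
#'   `ci_multiplier` z = 1, the form the protocol prints; set 1.96 or a
#'   t-quantile for conventional 95% coverage;
#' * outliers defined as datapoints differing from the condition median by
#'   `outlier_fraction` = 50% or more;
#' * applied masses 50 and 60 kg with 6 trials per load.
#'
#' @param redistribution_threshold Named fractions per model.
#' @param lel,uel Lower/upper equivalence limits on the magnitude ratio.
#' @param ci_multiplier Multiplier z in `mu +/- z * sigma / sqrt(n)`.
#' @param outlier_fraction Median-relative deviation defining an outlier.
#' @param borderline_tolerance Distance (in parameter units) within which a
#'   confidence bound is considered to minimally cross a threshold.
#' @param loads Applied masses in kg.
#' @param trials_per_load Repeated trials at each load.
#' @return An object of class `threshold_config` (a validated list).
#' @examples
#' cfg <- threshold_config()
#' cfg$redistribution_threshold
#' @export
threshold_config <- function(redistribution_threshold = c(elliptical = 0.50,
                                                          trigonometric = 0.55),
                             lel = 0.9,
                             uel = 1.1,
                             ci_multiplier = 1.0,
                             outlier_fraction = 0.5,
                             borderline_tolerance = 0.02,
                             loads = c(50, 60),
                             trials_per_load = 6L) {
  cfg <- structure(
    list(
      redistribution_threshold = redistribution_threshold,
      lel = lel, uel = uel,
      ci_multiplier = ci_multiplier,
      outlier_fraction = outlier_fraction,
      borderline_tolerance = borderline_tolerance,
      loads = as.numeric(loads),
      trials_per_load = as.integer(trials_per_load)
    ),
    class = "threshold_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  thr <- cfg$redistribution_threshold
  if (!all(buttock_models() %in% names(thr))) {
    cb_stop("redistribution_threshold must name both buttock models")
  }
  if (!all(thr > 0 & thr < 1)) cb_stop("redistribution thresholds must lie in (0, 1)")
  if (!(cfg$lel > 0 && cfg$lel < 1 && cfg$uel > 1)) {
    cb_stop("equivalence limits must satisfy 0 < lel < 1 < uel")
  }
  if (cfg$ci_multiplier <= 0) cb_stop("ci_multiplier must be positive")
  if (cfg$outlier_fraction <= 0) cb_stop("outlier_fraction must be positive")
  if (cfg$borderline_tolerance < 0) cb_stop("borderline_tolerance must be nonnegative")
  if (length(cfg$loads) < 1 || any(cfg$loads <= 0)) cb_stop("loads must be positive masses in kg")
  if (cfg$trials_per_load < 1) cb_stop("trials_per_load must be a positive integer")
  invisible(cfg)
}

#' Read or write a configuration as JSON
#'
#' The JSON schema nests the per-model thresholds:
#' `{"redistribution_threshold": {"elliptical": 0.5, "trigonometric": 0.55},
#'  "lel": 0.9, ...}`. Defaults round-trip unchanged.
#'
#' @param path File path.
#' @return `read_threshold_config` returns a `threshold_config`;
#'   `write_threshold_config` returns `path` invisibly.
#' @export
read_threshold_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("redistribution_threshold", "lel", "uel", "ci_multiplier",
               "outlier_fraction", "borderline_tolerance", "loads",
               "trials_per_load")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    cb_stop(sprintf("unknown configuration keys: %s", paste(unknown, collapse = ", ")))
  }
  defaults <- threshold_config()
  for (key in setdiff(allowed, names(raw))) raw[[key]] <- defaults[[key]]
  thr <- unlist(raw$redistribution_threshold)
  threshold_config(
    redistribution_threshold = thr,
    lel = raw$lel, uel = raw$uel,
    ci_multiplier = raw$ci_multiplier,
    outlier_fraction = raw$outlier_fraction,
    borderline_tolerance = raw$borderline_tolerance,
    loads = raw$loads,
    trials_per_load = raw$trials_per_load
  )
}

#' @rdname read_threshold_config
#' @param config A `threshold_config`.
#' @export
write_threshold_config <- function(config, path) {
  validate_config(config)
  out <- unclass(config)
  out$redistribution_threshold <- as.list(out$redistribution_threshold)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("Cushion evaluation configuration\n")
  cat(sprintf("  redistribution criteria: elliptical %.2f, trigonometric %.2f\n",
              x$redistribution_threshold[["elliptical"]],
              x$redistribution_threshold[["trigonometric"]]))
  cat(sprintf("  equivalence band: [%.2f, %.2f]\n", x$lel, x$uel))
  cat(sprintf("  CI: mu +/- %g * sigma / sqrt(n)\n", x$ci_multiplier))
  cat(sprintf("  outlier rule: |x - median| >= %.0f%% of median\n",
              100 * x$outlier_fraction))
  cat(sprintf("  loads: %s kg, %d trials per load\n",
              paste(x$loads, collapse = "/"), x$trials_per_load))
  invisible(x)
}
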