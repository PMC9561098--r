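#' Interval estimate of a pooled parameter
#'
#' Container for a mean with its confidence bounds, as used by the
#' classification rules. Construct directly (e.g. to encode published
#' interval rows) or via [pooled_interval()].
#'
#' @param mean Point estimate.
#' @param lower,upper Confidence bounds.
#' @param sd Sample standard deviation (optional).
#' @param n Number of trials (optional).
#' @return An object of class `interval_estimate`.
#' @export
interval_estimate <- function(mean, lower, upper, sd = NA_real_, n = NA_integer_) {
  if (!(lower <= mean && mean <= upper)) {
    cb_stop("interval bounds must satisfy lower <= mean <= upper")
  }
  if (!is.na(sd) && sd < 0) cb_stop("sd must be nonnegative")
  structure(list(mean = mean, sd = sd, n = n, lower = lower, upper = upper),
            class = "interval_estimate")
}

#' Pooled confidence interval across both load conditions
#'
#' The per-trial values of a parameter from all loads are pooled into a
#' single sample (nominally 6 trials x 2 loads = 12 values) and summarised
#' as `mu +/- z * sigma / sqrt(n)` with `z = ci_multiplier`, sample mean
#' `mu` and sample standard deviation `sigma` (n-1 denominator). Pooling the
#' loads deliberately widens the interval of load-sensitive cushions: a
#' cushion that supports both masses similarly earns a tighter interval.
#'
#' @param values Numeric vector of per-trial parameter values pooled across
#'   loads; at least 2 values after exclusions.
#' @param config A `threshold_config`.
#' @return An `interval_estimate`.
#' @examples
#' pooled_interval(c(rep(0.4, 6), rep(0.6, 6)))
#' @export
pooled_interval <- function(values, config = threshold_config()) {
  n <- length(values)
  if (n < 2) cb_stop("pooled interval needs at least 2 trials")
  mu <- mean(values)
  sigma <- stats::sd(values)
  half <- config$ci_multiplier * sigma / sqrt(n)
  interval_estimate(mean = mu, lower = mu - half, upper = mu + half,
                    sd = sigma, n = n)
}

#' Ratio of test to reference means with a confidence interval
#'
#' The magnitude parameter compares a test cushion's summed internal
#' pressures to those of a flat-foam reference: the quantity of interest is
#' `rho = mean(test) / mean(reference)` together with a confidence interval,
#' judged against the equivalence limits. Three interval constructions are
#' provided:
#'
#' * `"fieller"` (default): Fieller's construction for the ratio of two
#'   independent sample means, exact under normality and respectful of the
#'   positivity of pressures;
#' * `"delta"`: first-order delta method,
#'   `rho * (1 +/- z * sqrt(cv_t^2/n_t + cv_r^2/n_r))`;
#' * `"bootstrap"`: seeded percentile interval over `B` resamples of the
#'   trial-level values, at the coverage implied by `ci_multiplier`.
#'
#' All three use the same multiplier `z = ci_multiplier` as the pooled
#' intervals. If the reference mean is not significantly positive at that
#' multiplier, Fieller's denominator can change sign and the interval is
#' unbounded: a warning of class `cushionbench_unbounded_ratio` is signalled
#' and infinite bounds are returned (classification then falls back to
#' Comparable).
#'
#' @param test,ref Numeric vectors of per-trial SumInt values (pooled across
#'   loads), at least 2 each; `mean(ref) > 0`.
#' @param method Interval construction.
#' @param config A `threshold_config`.
#' @param seed Integer seed for the bootstrap (ignored otherwise).
#' @param B Bootstrap resample count.
#' @return An object of class `ratio_estimate` with fields `rho`, `lower`,
#'   `upper`, `method`, `n_test`, `n_ref`, `unbounded`.
#' @export
ratio_interval <- function(test, ref,
                           method = c("fieller", "delta", "bootstrap"),
                           config = threshold_config(),
                           seed = 1L, B = 2000L) {
  method <- match.arg(method)
  if (length(test) < 2 || length(ref) < 2) {
    cb_stop("ratio interval needs at least 2 trials in each sample")
  }
  m1 <- mean(test); m0 <- mean(ref)
  if (m0 <= 0) cb_stop("reference mean must be positive")
  z <- config$ci_multiplier
  rho <- m1 / m0
  n1 <- length(test); n0 <- length(ref)
  v1 <- stats::var(test) / n1
  v0 <- stats::var(ref) / n0

  if (method == "fieller") {
    denom <- m0^2 - z^2 * v0
    if (denom <= 0) {
      warning(structure(
        class = c("cushionbench_unbounded_ratio", "warning", "condition"),
        list(message = "reference mean not significantly positive; Fieller interval is unbounded",
             call = NULL)))
      return(ratio_estimate(rho, -Inf, Inf, method, n1, n0, unbounded = TRUE))
    }
    disc <- m0^2 * v1 + m1^2 * v0 - z^2 * v1 * v0
    half <- z * sqrt(max(disc, 0))
    lower <- (m1 * m0 - half) / denom
    upper <- (m1 * m0 + half) / denom
  } else if (method == "delta") {
    cv1 <- stats::sd(test) / m1
    cv0 <- stats::sd(ref) / m0
    half <- z * sqrt(cv1^2 / n1 + cv0^2 / n0)
    lower <- rho * (1 - half)
    upper <- rho * (1 + half)
  } else {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    idx1 <- matrix(sample.int(n1, n1 * B, replace = TRUE), nrow = n1)
    idx0 <- matrix(sample.int(n0, n0 * B, replace = TRUE), nrow = n0)
    ratios <- colMeans(matrix(test[idx1], nrow = n1)) /
      colMeans(matrix(ref[idx0], nrow = n0))
    coverage <- 2 * stats::pnorm(z) - 1
    qs <- stats::quantile(ratios, probs = c((1 - coverage) / 2,
                                            1 - (1 - coverage) / 2),
                          names = FALSE, type = 7)
    lower <- qs[1]; upper <- qs[2]
  }
  # guard against numerical inversion in degenerate zero-variance cases
  if (lower > upper) { tmp <- lower; lower <- upper; upper <- tmp }
  ratio_estimate(rho, min(lower, rho), max(upper, rho), method, n1, n0)
}

#' Construct a ratio estimate directly
#'
#' Used to encode published ratio rows (mean with CI bounds) for
#' classification without access to the underlying trials.
#'
#' @param rho Ratio of test to reference means.
#' @param lower,upper Confidence bounds.
#' @param method Label of the interval construction.
#' @param n_test,n_ref Sample sizes (optional).
#' @param unbounded Whether the interval is unbounded (Fieller degenerate
#'   case).
#' @return An object of class `ratio_estimate`.
#' @export
ratio_estimate <- function(rho, lower, upper, method = "fixed",
                           n_test = NA_integer_, n_ref = NA_integer_,
                           unbounded = FALSE) {
  if (!(lower <= rho && rho <= upper)) {
    cb_stop("ratio bounds must satisfy lower <= rho <= upper")
  }
  structure(list(rho = rho, lower = lower, upper = upper, method = method,
                 n_test = n_test, n_ref = n_ref, unbounded = unbounded),
            class = "ratio_estimate")
}

#' Derive the equivalence limit from literature interface-pressure data
#'
#' The width of the equivalence band is anchored to the dispersion of
#' localized interface-pressure measurements reported across cushion
#' studies: for each record the normalized confidence half-width
#' `1.96 * SEM / mean` is computed (with `SEM = sd / sqrt(n)`), and the
#' limit estimate is the average of these ratios over all records.
#'
#' @param records Data frame with columns `label, mean_mmHg, sd_mmHg, n`.
#' @return The averaged normalized half-width (a fraction).
#' @examples
#' derive_equivalence_limit(data.frame(label = "a", mean_mmHg = 100,
#'                                     sd_mmHg = 10, n = 16)) # 0.049
#' @export
derive_equivalence_limit <- function(records) {
  required <- c("label", "mean_mmHg", "sd_mmHg", "n")
  if (!all(required %in% names(records)) || nrow(records) == 0) {
    cb_stop("records must be a nonempty data frame with columns label, mean_mmHg, sd_mmHg, n")
  }
  if (any(records$mean_mmHg <= 0) || any(records$sd_mmHg < 0) ||
      any(records$n < 2)) {
    cb_stop("each record needs mean > 0, sd >= 0, n >= 2")
  }
  mean(1.96 * (records$sd_mmHg / sqrt(records$n)) / records$mean_mmHg)
}

#' Read a literature interface-pressure table
#'
#' CSV with header `label,mean_mmHg,sd_mmHg,n`, one row per cushion study
#' record.
#'
#' @param path CSV file path.
#' @return A data frame suitable for [derive_equivalence_limit()].
#' @export
read_ipm_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("label", "mean_mmHg", "sd_mmHg", "n")
  if (!setequal(names(df), required)) {
    cb_stop(sprintf("IPM table header must be %s", paste(required, collapse = ",")))
  }
  df
}

#' @export
print.interval_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("mean %.*f, CI [%.*f, %.*f]", digits, x$mean, digits, x$lower,
              digits, x$upper))
  if (!is.na(x$n)) cat(sprintf(" (n = %d)", x$n))
  cat("\n")
  invisible(x)
}

#' @export
print.ratio_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("ratio %.*f, CI [%.*f, %.*f] (%s", digits, x$rho, digits,
              x$lower, digits, x$upper, x$method))
  if (!is.na(x$n_test)) cat(sprintf(", n = %d/%d", x$n_test, x$n_ref))
  cat(")\n")
  invisible(x)
}
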