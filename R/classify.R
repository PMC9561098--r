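#' Trichotomous classification of pressure redistribution
#'
#' The pooled bony-fraction interval is judged against the model's
#' criterion (0.50 elliptical / 0.55 trigonometric): **High** redistribution
#' when the whole CI falls below the criterion, **Low** when it lies wholly
#' above, **Moderate** when the CI includes it. The comparisons are strict,
#' so a bound exactly at the criterion yields Moderate.
#'
#' @param interval An `interval_estimate` of the bony fraction.
#' @param model `"elliptical"` or `"trigonometric"`.
#' @param config A `threshold_config`.
#' @return `"High"`, `"Moderate"` or `"Low"`.
#' @examples
#' classify_redistribution(interval_estimate(0.46, 0.45, 0.47), "elliptical")
#' @export
classify_redistribution <- function(interval, model, config = threshold_config()) {
  model <- match.arg(model, buttock_models())
  tau <- config$redistribution_threshold[[model]]
  if (interval$upper < tau) "High"
  else if (interval$lower > tau) "Low"
  else "Moderate"
}

#' Trichotomous classification of pressure magnitude
#'
#' The ratio of the test cushion's mean SumInt to the reference material's
#' is judged against the equivalence band: **Superior** when the entire CI
#' is less than or equal to the lower equivalence limit, **Inferior** when
#' the entire CI is greater than or equal to the upper limit, **Comparable**
#' when the CI crosses either limit or lies fully between them. The
#' comparisons are non-strict (a CI touching a limit from inside the
#' superior/inferior region still qualifies). An unbounded Fieller interval
#' is classified Comparable with a warning.
#'
#' @param ratio A `ratio_estimate`.
#' @param config A `threshold_config`.
#' @return `"Superior"`, `"Comparable"` or `"Inferior"`.
#' @examples
#' classify_magnitude(ratio_estimate(0.70, 0.66, 0.75))
#' @export
classify_magnitude <- function(ratio, config = threshold_config()) {
  if (isTRUE(ratio$unbounded) || !is.finite(ratio$lower) || !is.finite(ratio$upper)) {
    warning("unbounded ratio interval; classifying as Comparable", call. = FALSE)
    return("Comparable")
  }
  if (ratio$upper <= config$lel) "Superior"
  else if (ratio$lower >= config$uel) "Inferior"
  else "Comparable"
}

# internal: class orderings (best first)
redistribution_levels <- c("High", "Moderate", "Low")
magnitude_levels <- c("Superior", "Comparable", "Inferior")

at_least <- function(label, floor, levels) {
  !is.na(label) && match(label, levels) <= match(floor, levels)
}

#' Overall pressure-management tier
#'
#' Applies the classification matrix combining the per-model redistribution
#' and magnitude classes into five tiers, searched best-first:
#'
#' * **Level1** -- High redistribution on both models and Superior magnitude
#'   on both models against the 3-inch reference;
#' * **Level2** -- at least Moderate on both models and at least Comparable
#'   on both models against the 3-inch reference;
#' * **Level3** -- at least Moderate on the elliptical model and at least
#'   Comparable on the elliptical model against the 3-inch reference;
#' * **GeneralUse** -- at least Comparable on the elliptical model against
#'   the 2-inch reference;
#' * **BelowMinimum** -- Inferior on the elliptical model against the 2-inch
#'   reference (no requisite therapeutic performance).
#'
#' A tier whose inputs are missing cannot be met; `Indeterminate` is
#' returned when no tier can be resolved from the available inputs.
#'
#' @param redistribution Named character vector of redistribution classes
#'   per model (`elliptical`, `trigonometric`; `NA` when unmeasured).
#' @param magnitude_3in Named magnitude classes per model against the 3-inch
#'   reference, or `NULL`.
#' @param magnitude_2in_elliptical Magnitude class of the elliptical model
#'   against the 2-inch reference, or `NA`.
#' @return One of `"Level1"`, `"Level2"`, `"Level3"`, `"GeneralUse"`,
#'   `"BelowMinimum"`, `"Indeterminate"`.
#' @examples
#' assign_level(c(elliptical = "High", trigonometric = "High"),
#'              c(elliptical = "Superior", trigonometric = "Superior"))
#' @export
assign_level <- function(redistribution,
                         magnitude_3in = NULL,
                         magnitude_2in_elliptical = NA_character_) {
  red <- function(model) {
    if (is.null(redistribution) || !model %in% names(redistribution)) NA_character_
    else redistribution[[model]]
  }
  mag3 <- function(model) {
    if (is.null(magnitude_3in) || !model %in% names(magnitude_3in)) NA_character_
    else magnitude_3in[[model]]
  }
  mag2e <- if (length(magnitude_2in_elliptical)) magnitude_2in_elliptical[[1]] else NA_character_

  if (at_least(red("elliptical"), "High", redistribution_levels) &&
      at_least(red("trigonometric"), "High", redistribution_levels) &&
      at_least(mag3("elliptical"), "Superior", magnitude_levels) &&
      at_least(mag3("trigonometric"), "Superior", magnitude_levels)) {
    return("Level1")
  }
  if (at_least(red("elliptical"), "Moderate", redistribution_levels) &&
      at_least(red("trigonometric"), "Moderate", redistribution_levels) &&
      at_least(mag3("elliptical"), "Comparable", magnitude_levels) &&
      at_least(mag3("trigonometric"), "Comparable", magnitude_levels)) {
    return("Level2")
  }
  if (at_least(red("elliptical"), "Moderate", redistribution_levels) &&
      at_least(mag3("elliptical"), "Comparable", magnitude_levels)) {
    return("Level3")
  }
  if (at_least(mag2e, "Comparable", magnitude_levels)) {
    return("GeneralUse")
  }
  if (!is.na(mag2e) && mag2e == "Inferior") {
    return("BelowMinimum")
  }
  "Indeterminate"
}

#' Flag thresholds minimally crossed by a confidence bound
#'
#' A classification is borderline when a CI bound lies within
#' `borderline_tolerance` of a decision threshold *and* a shift or shrink of
#' the interval by that distance would change the class; such cases warrant
#' additional trials to tighten the interval before the class is trusted.
#' An interval bound exactly on a threshold is always flagged.
#'
#' @param interval An `interval_estimate` or `ratio_estimate`.
#' @param type `"redistribution"` or `"magnitude"` (selects the thresholds
#'   and the classifier whose stability is probed).
#' @param model Buttock model (required for `type = "redistribution"`).
#' @param config A `threshold_config`.
#' @return Data frame with columns `threshold` and `distance` (zero rows
#'   when nothing is borderline).
#' @examples
#' flag_borderline(ratio_estimate(0.84, 0.78, 0.91), "magnitude")
#' @export
flag_borderline <- function(interval, type = c("redistribution", "magnitude"),
                            model = NULL, config = threshold_config()) {
  type <- match.arg(type)
  if (type == "redistribution") {
    if (is.null(model)) cb_stop("model is required for redistribution flags")
    thresholds <- config$redistribution_threshold[[match.arg(model, buttock_models())]]
    cls <- function(lo, hi) classify_redistribution(
      interval_estimate((lo + hi) / 2, lo, hi), model, config)
  } else {
    thresholds <- c(config$lel, config$uel)
    cls <- function(lo, hi) classify_magnitude(
      ratio_estimate((lo + hi) / 2, lo, hi), config)
  }
  lo <- interval$lower
  hi <- interval$upper
  if (!is.finite(lo) || !is.finite(hi)) {
    return(data.frame(threshold = numeric(), distance = numeric()))
  }
  base <- cls(lo, hi)
  out <- data.frame(threshold = numeric(), distance = numeric())
  for (tau in thresholds) {
    d <- min(abs(hi - tau), abs(lo - tau))
    if (d >= config$borderline_tolerance) next
    changes <- if (d == 0) TRUE else {
      shrink_ok <- (hi - d) >= (lo + d)
      any(c(cls(lo + d, hi + d) != base,
            cls(lo - d, hi - d) != base,
            if (shrink_ok) cls(lo + d, hi - d) != base))
    }
    if (isTRUE(changes)) {
      out <- rbind(out, data.frame(threshold = tau, distance = d))
    }
  }
  out
}

#' Suggested follow-up tests for a cushion report
#'
#' Emits machine-readable retest codes:
#' * `compare_vs_3in` -- the cushion was Superior to the 2-inch reference on
#'   some model but was never compared with the stricter 3-inch reference;
#'   it may in fact be comparable to it.
#' * `add_trials` -- some classification is borderline; additional trials
#'   would tighten the CI and allow re-assessment.
#'
#' @param report A `cushion_report` from [evaluate_cushion()].
#' @return Character vector of codes (possibly empty).
#' @export
suggest_retests <- function(report) {
  codes <- character()
  for (model in names(report$models)) {
    m <- report$models[[model]]
    if (is.null(m$magnitude_3in) && !is.null(m$magnitude_2in) &&
        identical(m$magnitude_2in$class, "Superior")) {
      codes <- c(codes, "compare_vs_3in")
    }
  }
  if (nrow(report$borderline_flags)) codes <- c(codes, "add_trials")
  unique(codes)
}
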