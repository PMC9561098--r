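#' Bony fraction of total surface pressure (pressure redistribution)
#'
#' The redistribution parameter of one trial: the summed pressure at the six
#' surface sensors under the rigid substructure's protuberances divided by
#' the sum over all twelve surface sensors. Lower values indicate better
#' redistribution away from high-risk bony sites.
#'
#' @param surface Named numeric vector of the 12 surface pressures (names are
#'   the channel ids `"1"`..`"12"`).
#' @param layout A `sensor_layout`.
#' @return The bony fraction, in `[0, 1]`.
#' @examples
#' p <- stats::setNames(rep(10, 12), as.character(1:12))
#' bony_fraction(p) # 0.5
#' @export
bony_fraction <- function(surface, layout = default_layout()) {
  ids <- as.character(layout$surface_ids)
  miss <- setdiff(ids, names(surface))
  if (length(miss)) {
    cb_stop(sprintf("surface vector is missing channel(s): %s",
                    paste(miss, collapse = ", ")))
  }
  total <- sum(surface[ids])
  if (total == 0) cb_stop("total surface pressure is zero; bony fraction undefined")
  sum(surface[as.character(layout$bony_ids)]) / total
}

#' Summed internal pressure (pressure magnitude)
#'
#' The magnitude parameter of one trial: the sum of the three internal
#' sensors mounted on the rigid substructure, representing loading at the
#' tips of the bony prominences.
#'
#' @param internal Named numeric vector of the 3 internal pressures (mmHg).
#' @param layout A `sensor_layout`.
#' @return SumInt in mmHg.
#' @export
sum_internal <- function(internal, layout = default_layout()) {
  miss <- setdiff(layout$internal_ids, names(internal))
  if (length(miss)) {
    cb_stop(sprintf("internal vector is missing channel(s): %s",
                    paste(miss, collapse = ", ")))
  }
  sum(internal[layout$internal_ids])
}

#' Per-trial performance parameters
#'
#' Computes, for every non-excluded trial, the three per-trial parameters:
#' the bony fraction, the summed internal pressure (SumInt, mmHg) and the
#' total surface pressure (mmHg). Trials listed in the table's
#' `"excluded_trials"` attribute (set by [impute_outliers()]) are dropped.
#'
#' @param trials A `trial_table`.
#' @param layout A `sensor_layout`.
#' @return A data frame with one row per trial and columns `cushion_id,
#'   model, load_kg, trial, bony_fraction, sum_internal, total_surface`.
#' @export
parameter_samples <- function(trials, layout = default_layout()) {
  excluded <- attr(trials, "excluded_trials")
  if (!is.null(excluded) && nrow(excluded)) {
    key <- paste(trials$cushion_id, trials$model, trials$load_kg, trials$trial)
    drop <- paste(excluded$cushion_id, excluded$model, excluded$load_kg,
                  excluded$trial)
    trials <- trials[!(key %in% drop), , drop = FALSE]
  }
  pieces <- lapply(split(trials, trial_groups(trials)), function(grp) {
    surf <- grp$pressure_mmhg[grp$class == "surface"]
    names(surf) <- grp$channel[grp$class == "surface"]
    int <- grp$pressure_mmhg[grp$class == "internal"]
    names(int) <- grp$channel[grp$class == "internal"]
    data.frame(cushion_id = grp$cushion_id[1], model = grp$model[1],
               load_kg = grp$load_kg[1], trial = grp$trial[1],
               bony_fraction = bony_fraction(surf, layout),
               sum_internal = sum_internal(int, layout),
               total_surface = sum(surf), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$cushion_id, out$model, out$load_kg, out$trial), , drop = FALSE]
}

#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean; the repeatability metric
#' used for the bench parameters.
#'
#' @param values Numeric vector, at least 2 values with nonzero mean.
#' @return The CV as a fraction.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) cb_stop("CV needs at least 2 values")
  m <- mean(values)
  if (m == 0) cb_stop("CV undefined for zero mean")
  stats::sd(values) / m
}

#' Repeatability of the pressure parameters
#'
#' Coefficients of variation of SumInt and total surface pressure across the
#' repeated trials of each model-load condition, the summary used to judge
#' bench repeatability.
#'
#' @param trials A `trial_table`.
#' @param layout A `sensor_layout`.
#' @return A data frame with columns `cushion_id, model, load_kg, parameter,
#'   cv`.
#' @export
repeatability <- function(trials, layout = default_layout()) {
  params <- parameter_samples(trials, layout)
  keys <- interaction(params$cushion_id, params$model, params$load_kg,
                      drop = TRUE, lex.order = TRUE)
  pieces <- lapply(split(params, keys), function(grp) {
    data.frame(cushion_id = grp$cushion_id[1], model = grp$model[1],
               load_kg = grp$load_kg[1],
               parameter = c("sum_internal", "total_surface"),
               cv = c(coefficient_of_variation(grp$sum_internal),
                      coefficient_of_variation(grp$total_surface)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
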