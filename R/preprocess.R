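#' Collapse a time series of pressure samples to a per-trial value
#'
#' Pressures are recorded at 1 Hz once the test load has settled; a trial's
#' stored value is the arithmetic mean of the last `window` samples.
#'
#' @param samples Numeric vector of time-ordered pressures (mmHg).
#' @param window Number of trailing samples to average (default 30).
#' @return The mean of the last `window` samples, in mmHg.
#' @examples
#' aggregate_samples(c(90, 100, 110), window = 3)
#' @export
aggregate_samples <- function(samples, window = 30L) {
  if (length(samples) == 0) cb_stop("sample series is empty")
  window <- as.integer(window)
  if (window < 1 || window > length(samples)) {
    cb_stop("window must be a positive count no larger than the series length")
  }
  mean(utils::tail(samples, window))
}

# internal: collapse a per-sample table (with t_s column) to per-trial rows
collapse_samples <- function(df, window = 30L) {
  keys <- interaction(df$cushion_id, df$model, df$load_kg, df$trial,
                      df$channel, drop = TRUE, lex.order = TRUE)
  pieces <- lapply(split(df, keys), function(grp) {
    grp <- grp[order(grp$t_s), , drop = FALSE]
    out <- grp[1, setdiff(names(grp), "t_s"), drop = FALSE]
    out$pressure_mmhg <- aggregate_samples(grp$pressure_mmhg, window = window)
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Flag outlying surface readings within a model-load condition
#'
#' A surface datapoint is an outlier when it differs from the median value of
#' its channel, taken across the repeated trials of one model-load condition,
#' by `outlier_fraction` (50%) or more of that median. The rule targets the
#' surface sensors, which can report erroneous values on cushions with
#' discontinuous loading surfaces; internal channels are never flagged.
#'
#' @param trials A `trial_table` with at least 2 trials per condition.
#' @param config A `threshold_config` (supplies `outlier_fraction`).
#' @param layout A `sensor_layout`.
#' @return A data frame of flags with columns `cushion_id, model, load_kg,
#'   trial, channel, observed, condition_median` (zero rows when clean).
#' @export
detect_outliers <- function(trials, config = threshold_config(),
                            layout = default_layout()) {
  surf <- trials[trials$class == "surface", , drop = FALSE]
  n_trials <- tapply(surf$trial, condition_groups(surf),
                     function(x) length(unique(x)))
  if (any(n_trials < 2)) {
    cb_stop("each model-load condition needs at least 2 trials for the median rule")
  }
  keys <- interaction(surf$cushion_id, surf$model, surf$load_kg, surf$channel,
                      drop = TRUE, lex.order = TRUE)
  flags <- lapply(split(surf, keys), function(grp) {
    med <- stats::median(grp$pressure_mmhg)
    hit <- abs(grp$pressure_mmhg - med) >= config$outlier_fraction * med
    if (!any(hit)) return(NULL)
    data.frame(cushion_id = grp$cushion_id[hit], model = grp$model[hit],
               load_kg = grp$load_kg[hit], trial = grp$trial[hit],
               channel = grp$channel[hit], observed = grp$pressure_mmhg[hit],
               condition_median = med, stringsAsFactors = FALSE)
  })
  flags <- do.call(rbind, flags)
  if (is.null(flags)) {
    flags <- data.frame(cushion_id = character(), model = character(),
                        load_kg = numeric(), trial = integer(),
                        channel = character(), observed = numeric(),
                        condition_median = numeric(), stringsAsFactors = FALSE)
  }
  rownames(flags) <- NULL
  flags[order(flags$cushion_id, flags$model, flags$load_kg, flags$trial,
              as.integer(flags$channel)), , drop = FALSE]
}

#' Replace flagged readings by their axisymmetric partner's value
#'
#' Each buttock location carries a left/right sensor pair, so a single
#' outlying reading does not void the trial: the flagged value is replaced by
#' its partner's value from the same trial. When both members of a pair are
#' flagged in one trial, that trial is excluded from parameter computation
#' for its model-load condition (recorded in the `"excluded_trials"`
#' attribute, with a warning).
#'
#' @param trials A `trial_table`.
#' @param flags Flags from [detect_outliers()] on the same trials.
#' @param layout A `sensor_layout`.
#' @return The `trial_table` with flagged values imputed and attributes
#'   `"excluded_trials"` (data frame of excluded trial keys) and
#'   `"outlier_flags"` (the flags applied).
#' @export
impute_outliers <- function(trials, flags, layout = default_layout()) {
  excluded <- data.frame(cushion_id = character(), model = character(),
                         load_kg = numeric(), trial = integer(),
                         stringsAsFactors = FALSE)
  if (nrow(flags)) {
    trial_key <- function(d) paste(d$cushion_id, d$model, d$load_kg, d$trial)
    chan_key <- function(d) paste(trial_key(d), d$channel)
    flagged <- chan_key(flags)
    original <- trials$pressure_mmhg
    all_keys <- chan_key(trials)
    for (i in seq_len(nrow(flags))) {
      f <- flags[i, ]
      partner <- as.character(axisymmetric_partner(f$channel, layout))
      partner_key <- paste(f$cushion_id, f$model, f$load_kg, f$trial, partner)
      if (partner_key %in% flagged) {
        excluded <- unique(rbind(excluded, f[c("cushion_id", "model",
                                               "load_kg", "trial")]))
      } else {
        trials$pressure_mmhg[all_keys == chan_key(f)] <-
          original[all_keys == partner_key]
      }
    }
    rownames(excluded) <- NULL
    if (nrow(excluded)) {
      warning(sprintf(
        "%d trial(s) excluded: both sensors of an axisymmetric pair were flagged",
        nrow(excluded)), call. = FALSE)
    }
  }
  attr(trials, "excluded_trials") <- excluded
  attr(trials, "outlier_flags") <- flags
  trials
}

# internal: run the outlier stage end to end
preprocess_trials <- function(trials, config = threshold_config(),
                              layout = default_layout()) {
  flags <- detect_outliers(trials, config, layout)
  impute_outliers(trials, flags, layout)
}
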