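#' Long-format trial tables
#'
#' All trial data move through the package as a long (tidy) data frame with
#' one row per channel reading and columns
#' `cushion_id, model, load_kg, trial, channel, class, pressure_mmhg`.
#' One loading trial of one cushion on one model therefore occupies 15 rows:
#' 12 surface channels (`class == "surface"`, channels `"1"`..`"12"`) and 3
#' internal channels (`class == "internal"`, channels `"I1"`..`"I3"`).
#' Pressures are calibrated values in mmHg, nonnegative and finite.
#'
#' `trial_table()` validates a data frame against this schema (channel
#' completeness per trial, key uniqueness, model tokens) and stamps it with
#' the `trial_table` class.
#'
#' @param df A data frame in the schema above.
#' @param layout A `sensor_layout`.
#' @return A validated `trial_table` data frame.
#' @export
trial_table <- function(df, layout = default_layout()) {
  required <- c("cushion_id", "model", "load_kg", "trial", "channel",
                "class", "pressure_mmhg")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    cb_stop(sprintf("trial table lacks columns: %s",
                    paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(df)[required]
  df$cushion_id <- as.character(df$cushion_id)
  df$model <- as.character(df$model)
  df$channel <- as.character(df$channel)
  df$class <- as.character(df$class)
  df$load_kg <- as.numeric(df$load_kg)
  df$trial <- as.integer(df$trial)
  df$pressure_mmhg <- as.numeric(df$pressure_mmhg)

  bad_model <- setdiff(unique(df$model), buttock_models())
  if (length(bad_model)) {
    cb_stop(sprintf("unknown model token(s) %s; accepted tokens: %s",
                    paste(sQuote(bad_model), collapse = ", "),
                    paste(buttock_models(), collapse = ", ")))
  }
  surf_ids <- as.character(layout$surface_ids)
  int_ids <- layout$internal_ids
  ok_surface <- df$class == "surface" & df$channel %in% surf_ids
  ok_internal <- df$class == "internal" & df$channel %in% int_ids
  if (!all(ok_surface | ok_internal)) {
    bad <- df[!(ok_surface | ok_internal), , drop = FALSE][1, ]
    cb_stop(sprintf("unknown channel %s for class %s",
                    sQuote(bad$channel), sQuote(bad$class)))
  }
  if (any(!is.finite(df$pressure_mmhg)) || any(df$pressure_mmhg < 0)) {
    cb_stop("pressures must be finite and nonnegative")
  }
  key <- paste(df$cushion_id, df$model, df$load_kg, df$trial, df$channel)
  if (anyDuplicated(key)) {
    cb_stop(sprintf("duplicate channel reading for key: %s", key[duplicated(key)][1]))
  }
  if (any(df$trial < 1)) cb_stop("trial indices must be positive")

  # channel completeness per trial
  split_keys <- interaction(df$cushion_id, df$model, df$load_kg, df$trial,
                            drop = TRUE)
  for (grp in split(df, split_keys)) {
    miss <- c(setdiff(surf_ids, grp$channel[grp$class == "surface"]),
              setdiff(int_ids, grp$channel[grp$class == "internal"]))
    if (length(miss)) {
      cb_stop(sprintf(
        "trial %d of %s (%s model, %g kg) is missing channel(s): %s",
        grp$trial[1], grp$cushion_id[1], grp$model[1], grp$load_kg[1],
        paste(miss, collapse = ", ")))
    }
  }
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Read and write trial tables as CSV
#'
#' The CSV header is exactly
#' `cushion_id,model,load_kg,trial,channel,class,pressure_mmhg`.
#' A per-sample file may carry one extra column `t_s` (seconds); its rows are
#' then collapsed to per-trial values by averaging the last `window` samples
#' of each channel (see [aggregate_samples()]).
#'
#' @param path CSV file path.
#' @param layout A `sensor_layout`.
#' @param window Sample window used to collapse per-sample files.
#' @return `read_trials` returns a `trial_table`; `write_trials` returns
#'   `path` invisibly.
#' @export
read_trials <- function(path, layout = default_layout(), window = 30L) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) cb_stop(sprintf("cannot read %s: %s", path, conditionMessage(e)))
  )
  expected <- c("cushion_id", "model", "load_kg", "trial", "channel",
                "class", "pressure_mmhg")
  has_time <- "t_s" %in% names(df)
  want <- if (has_time) union(expected, "t_s") else expected
  if (!setequal(names(df), want)) {
    cb_stop(sprintf("unexpected CSV header in %s: got %s", path,
                    paste(names(df), collapse = ",")))
  }
  num_cols <- c("load_kg", "pressure_mmhg", if (has_time) "t_s")
  for (col in c(num_cols, "trial")) {
    val <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(val) & !is.na(df[[col]]))
    if (length(bad)) {
      cb_stop(sprintf("malformed value %s in column %s at line %d of %s",
                      sQuote(df[[col]][bad[1]]), col, bad[1] + 1L, path))
    }
    df[[col]] <- val
  }
  if (has_time) df <- collapse_samples(df, window = window)
  trial_table(df, layout)
}

#' @rdname read_trials
#' @param trials A `trial_table`.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# internal: stable per-trial grouping factor
trial_groups <- function(trials) {
  interaction(trials$cushion_id, trials$model, trials$load_kg, trials$trial,
              drop = TRUE, lex.order = TRUE)
}

# internal: grouping at the model-load condition level
condition_groups <- function(trials) {
  interaction(trials$cushion_id, trials$model, trials$load_kg,
              drop = TRUE, lex.order = TRUE)
}
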