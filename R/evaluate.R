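#' Evaluate a cushion against reference materials
#'
#' The end-to-end evaluation pipeline: outlier flagging and axisymmetric
#' imputation on every trial table, per-trial parameters, pooled confidence
#' intervals across both loads, SumInt ratio intervals against each provided
#' reference, trichotomous classes, the overall pressure-management tier,
#' borderline flags and retest suggestions.
#'
#' @param test `trial_table` of the test cushion (both models, both loads).
#' @param ref3 `trial_table` of the 3-inch foam reference, or `NULL`.
#' @param ref2 `trial_table` of the 2-inch foam reference, or `NULL`.
#' @param config A `threshold_config`.
#' @param method Ratio-interval construction (see [ratio_interval()]).
#' @param seed Integer seed (used by the bootstrap method only).
#' @param layout A `sensor_layout`.
#' @return An object of class `cushion_report`: a list with the cushion id,
#'   a per-model list of intervals and classes, the overall tier, borderline
#'   flags, retest codes, outlier/exclusion accounting and the config used.
#' @examples
#' cfg <- threshold_config()
#' test <- simulate_trials(virtual_cushion_spec("demo",
#'   bony_fraction = c(elliptical = 0.46, trigonometric = 0.53),
#'   internal_ratio = c(elliptical = 0.8, trigonometric = 0.8),
#'   channel_cv = c(surface = 0.02, internal = 0.01), seed = 7))
#' ref3 <- make_reference("foam_3in", seed = 8)
#' report <- evaluate_cushion(test, ref3 = ref3, config = cfg)
#' report$overall_level
#' @export
evaluate_cushion <- function(test, ref3 = NULL, ref2 = NULL,
                             config = threshold_config(),
                             method = c("fieller", "delta", "bootstrap"),
                             seed = 1L,
                             layout = default_layout()) {
  method <- match.arg(method)

  clean <- preprocess_trials(test, config, layout)
  params <- parameter_samples(clean, layout)
  cushion_id <- unique(params$cushion_id)
  if (length(cushion_id) != 1) {
    cb_stop("test trials must describe exactly one cushion")
  }
  ref_params <- list(
    ref3 = if (!is.null(ref3)) parameter_samples(preprocess_trials(ref3, config, layout), layout),
    ref2 = if (!is.null(ref2)) parameter_samples(preprocess_trials(ref2, config, layout), layout)
  )

  models_present <- intersect(buttock_models(), unique(params$model))
  if (!setequal(models_present, buttock_models())) {
    warning("test trials do not cover both buttock models; evaluating the subset present",
            call. = FALSE)
  }

  borderline <- data.frame(parameter = character(), model = character(),
                           threshold = numeric(), distance = numeric(),
                           stringsAsFactors = FALSE)
  add_flags <- function(flags, parameter, model) {
    if (nrow(flags)) {
      rbind(borderline,
            cbind(data.frame(parameter = parameter, model = model,
                             stringsAsFactors = FALSE), flags))
    } else borderline
  }

  models <- list()
  for (model in models_present) {
    p <- params[params$model == model, , drop = FALSE]
    redist <- pooled_interval(p$bony_fraction, config)
    entry <- list(
      redistribution = list(
        interval = redist,
        class = classify_redistribution(redist, model, config)
      )
    )
    borderline <- add_flags(flag_borderline(redist, "redistribution", model, config),
                            "redistribution", model)
    for (ref_name in c("ref3", "ref2")) {
      rp <- ref_params[[ref_name]]
      if (is.null(rp)) next
      r <- rp[rp$model == model, , drop = FALSE]
      if (nrow(r) < 2 || nrow(p) < 2) next
      ratio <- ratio_interval(p$sum_internal, r$sum_internal,
                              method = method, config = config, seed = seed)
      slot <- if (ref_name == "ref3") "magnitude_3in" else "magnitude_2in"
      entry[[slot]] <- list(interval = ratio,
                            class = classify_magnitude(ratio, config))
      borderline <- add_flags(flag_borderline(ratio, "magnitude", config = config),
                              paste0("magnitude_", sub("ref", "", ref_name), "in"),
                              model)
    }
    models[[model]] <- entry
  }

  pull_class <- function(slot) {
    out <- vapply(buttock_models(), function(m) {
      cls <- models[[m]][[slot]]$class
      if (is.null(cls)) NA_character_ else cls
    }, "")
    names(out) <- buttock_models()
    out
  }
  redistribution_classes <- pull_class("redistribution")
  magnitude_3in_classes <- pull_class("magnitude_3in")
  magnitude_2in_classes <- pull_class("magnitude_2in")

  overall <- assign_level(
    redistribution = redistribution_classes,
    magnitude_3in = if (all(is.na(magnitude_3in_classes))) NULL else magnitude_3in_classes,
    magnitude_2in_elliptical = magnitude_2in_classes[["elliptical"]]
  )

  report <- structure(
    list(
      cushion_id = cushion_id,
      models = models,
      overall_level = overall,
      borderline_flags = borderline,
      outlier_flags = attr(clean, "outlier_flags"),
      excluded_trials = attr(clean, "excluded_trials"),
      config = config,
      method = method,
      seed = as.integer(seed)
    ),
    class = "cushion_report"
  )
  report$retest_suggestions <- suggest_retests(report)
  report
}

#' @export
print.cushion_report <- function(x, digits = 3, ...) {
  cat(sprintf("Cushion evaluation: %s\n", x$cushion_id))
  for (model in names(x$models)) {
    m <- x$models[[model]]
    r <- m$redistribution
    cat(sprintf("  %s model\n", model))
    cat(sprintf("    redistribution: %s (bony fraction %.*f, CI [%.*f, %.*f])\n",
                r$class, digits, r$interval$mean, digits, r$interval$lower,
                digits, r$interval$upper))
    for (slot in c("magnitude_3in", "magnitude_2in")) {
      if (is.null(m[[slot]])) next
      g <- m[[slot]]
      cat(sprintf("    magnitude vs %s\": %s (ratio %.*f, CI [%.*f, %.*f])\n",
                  if (slot == "magnitude_3in") "3" else "2", g$class,
                  digits, g$interval$rho, digits, g$interval$lower,
                  digits, g$interval$upper))
    }
  }
  cat(sprintf("  overall tier: %s\n", x$overall_level))
  if (nrow(x$borderline_flags)) {
    cat(sprintf("  borderline: %d threshold(s) minimally crossed\n",
                nrow(x$borderline_flags)))
  }
  if (length(x$retest_suggestions)) {
    cat("  retest suggestions: ", paste(x$retest_suggestions, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.cushion_report <- function(object, ...) {
  rows <- list()
  for (model in names(object$models)) {
    m <- object$models[[model]]
    grab <- function(slot, field) {
      if (is.null(m[[slot]])) NA_real_ else m[[slot]]$interval[[field]]
    }
    grab_cls <- function(slot) {
      if (is.null(m[[slot]])) NA_character_ else m[[slot]]$class
    }
    rows[[model]] <- data.frame(
      cushion_id = object$cushion_id, model = model,
      bony_fraction = m$redistribution$interval$mean,
      bony_lower = m$redistribution$interval$lower,
      bony_upper = m$redistribution$interval$upper,
      redistribution = m$redistribution$class,
      ratio_3in = grab("magnitude_3in", "rho"),
      magnitude_3in = grab_cls("magnitude_3in"),
      ratio_2in = grab("magnitude_2in", "rho"),
      magnitude_2in = grab_cls("magnitude_2in"),
      overall_level = object$overall_level,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a cushion report as a markdown table
#'
#' Mirrors the layout of the per-model classification tables, with an
#' overall-level line; the class labels are taken verbatim from the report,
#' so markdown and JSON output cannot diverge.
#'
#' @param report A `cushion_report`, or the list produced by parsing a
#'   report JSON written with [write_report()].
#' @return Character vector of markdown lines.
#' @export
report_markdown <- function(report) {
  fmt <- function(x) ifelse(is.na(x), "-", sprintf("%.2f", as.numeric(x)))
  lines <- c(sprintf("# Cushion evaluation: %s", report$cushion_id), "",
             "| Model | Bony fraction | CI- | CI+ | Redistribution | Ratio vs 3\" | Class vs 3\" | Ratio vs 2\" | Class vs 2\" |",
             "|---|---|---|---|---|---|---|---|---|")
  for (model in names(report$models)) {
    m <- report$models[[model]]
    ival <- m$redistribution$interval
    g3 <- m$magnitude_3in
    g2 <- m$magnitude_2in
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s | %s | %s | %s | %s | %s |",
      model, fmt(ival$mean), fmt(ival$lower), fmt(ival$upper),
      m$redistribution$class,
      if (is.null(g3)) "-" else fmt(g3$interval$rho),
      if (is.null(g3)) "-" else g3$class,
      if (is.null(g2)) "-" else fmt(g2$interval$rho),
      if (is.null(g2)) "-" else g2$class))
  }
  lines <- c(lines, "", sprintf("Overall level: **%s**", report$overall_level))
  if (length(report$retest_suggestions)) {
    lines <- c(lines, "", sprintf("Retest suggestions: %s",
                                  paste(unlist(report$retest_suggestions),
                                        collapse = ", ")))
  }
  lines
}

#' Write or read a cushion report as JSON
#'
#' The JSON mirrors the `cushion_report` structure and embeds the
#' configuration used, for audit.
#'
#' @param report A `cushion_report`.
#' @param path File path.
#' @return `write_report` returns `path` invisibly; `read_report` returns
#'   the parsed report list (classed `cushion_report` for printing and
#'   markdown rendering).
#' @export
write_report <- function(report, path) {
  strip <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  out <- strip(unclass(report))
  out$config$redistribution_threshold <- as.list(out$config$redistribution_threshold)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  report <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  class(report) <- "cushion_report"
  report
}

#' Benchmark cohort classifications
#'
#' Published interval estimates and class labels for a cohort of ten
#' commercial wheelchair cushions (six Skin Protection, four General Use)
#' and the two flat-foam reference materials, evaluated on both buttock
#' models at 50 and 60 kg. The redistribution table reports the pooled bony
#' fraction (mean, CI bounds) and its class per model; the magnitude table
#' reports the SumInt ratio to the applicable reference (3-inch foam for
#' Skin Protection cushions, 2-inch for General Use) with its class.
#' Bundled as a validation benchmark: re-classifying the printed intervals
#' must reproduce every printed label.
#'
#' @return A list of two data frames, `redistribution` and `magnitude`.
#' @export
cohort_benchmarks <- function() {
  path <- function(f) system.file("extdata", f, package = "cushionbench",
                                  mustWork = TRUE)
  list(
    redistribution = utils::read.csv(path("cohort_redistribution.csv"),
                                     stringsAsFactors = FALSE),
    magnitude = utils::read.csv(path("cohort_magnitude.csv"),
                                stringsAsFactors = FALSE)
  )
}
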