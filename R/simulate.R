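#' Specification of a virtual cushion for the trial simulator
#'
#' A virtual cushion is described by the quantities the evaluation procedure
#' actually measures: the designed bony fraction of total surface pressure
#' per model, a total surface-pressure budget per model and load, and the
#' designed ratio of its expected summed internal pressure (SumInt) to the
#' expected SumInt of a reference material. Channel noise is multiplicative
#' and parameterised by a coefficient of variation per channel class, so
#' simulated readings stay nonnegative and repeatability maps directly onto
#' the CV scale used to report bench repeatability.
#'
#' @param cushion_id Label for the simulated cushion.
#' @param bony_fraction Named fractions per model: expected share of total
#'   surface pressure on the six bony channels (at the 50 kg load).
#' @param total_surface_load Named list per model of total surface pressure
#'   budgets (mmHg summed over the 12 channels), either a single value or a
#'   vector named by load in kg.
#' @param internal_ratio Named per model: designed SumInt ratio to the
#'   reference material.
#' @param internal_reference_mean Named per model: the reference material's
#'   expected SumInt in mmHg (defaults match the 3-inch foam preset of
#'   [make_reference()]).
#' @param channel_cv Coefficients of variation, named `surface` and
#'   `internal`.
#' @param load_shift Additive change in the bony fraction per +10 kg of
#'   applied load (0 = load-insensitive cushion).
#' @param outlier_prob Probability that a surface datapoint is corrupted.
#' @param outlier_scale Multiplier applied to a corrupted datapoint.
#' @param seed Integer seed; identical seeds give identical trial tables.
#' @return An object of class `virtual_cushion_spec`.
#' @seealso [simulate_trials()], [make_reference()]
#' @export
virtual_cushion_spec <- function(cushion_id,
                                 bony_fraction = c(elliptical = 0.50,
                                                   trigonometric = 0.56),
                                 total_surface_load = list(
                                   elliptical = c(`50` = 620, `60` = 720),
                                   trigonometric = c(`50` = 640, `60` = 745)),
                                 internal_ratio = c(elliptical = 1,
                                                    trigonometric = 1),
                                 internal_reference_mean = c(elliptical = 230,
                                                             trigonometric = 250),
                                 channel_cv = c(surface = 0.05,
                                                internal = 0.02),
                                 load_shift = 0,
                                 outlier_prob = 0,
                                 outlier_scale = 2.0,
                                 seed = 1L) {
  spec <- structure(
    list(cushion_id = as.character(cushion_id),
         bony_fraction = bony_fraction,
         total_surface_load = total_surface_load,
         internal_ratio = internal_ratio,
         internal_reference_mean = internal_reference_mean,
         channel_cv = channel_cv,
         load_shift = load_shift,
         outlier_prob = outlier_prob,
         outlier_scale = outlier_scale,
         seed = as.integer(seed)),
    class = "virtual_cushion_spec"
  )
  validate_spec(spec)
  spec
}

validate_spec <- function(spec, config = threshold_config()) {
  models <- buttock_models()
  need_named <- function(x, field) {
    if (!all(models %in% names(x))) {
      cb_stop(sprintf("field %s must name both buttock models", sQuote(field)))
    }
  }
  need_named(spec$bony_fraction, "bony_fraction")
  need_named(spec$internal_ratio, "internal_ratio")
  need_named(spec$internal_reference_mean, "internal_reference_mean")
  need_named(spec$total_surface_load, "total_surface_load")
  if (!all(spec$bony_fraction > 0 & spec$bony_fraction < 1)) {
    cb_stop("field 'bony_fraction' must lie in (0, 1)")
  }
  shift_range <- spec$load_shift * (range(config$loads) - 50) / 10
  shifted <- c(outer(spec$bony_fraction[models], shift_range, `+`))
  if (!all(shifted > 0 & shifted < 1)) {
    cb_stop("field 'load_shift' pushes the bony fraction outside (0, 1)")
  }
  if (!all(unlist(spec$total_surface_load) > 0)) {
    cb_stop("field 'total_surface_load' must be positive")
  }
  if (!all(spec$internal_ratio > 0)) cb_stop("field 'internal_ratio' must be positive")
  if (!all(spec$internal_reference_mean > 0)) {
    cb_stop("field 'internal_reference_mean' must be positive")
  }
  if (!all(c("surface", "internal") %in% names(spec$channel_cv)) ||
      any(spec$channel_cv < 0)) {
    cb_stop("field 'channel_cv' must provide nonnegative surface and internal CVs")
  }
  if (spec$outlier_prob < 0 || spec$outlier_prob > 1) {
    cb_stop("field 'outlier_prob' must lie in [0, 1]")
  }
  if (spec$outlier_scale <= 0) cb_stop("field 'outlier_scale' must be positive")
  invisible(spec)
}

# internal: surface budget for one model at one load
surface_budget <- function(spec, model, load) {
  b <- spec$total_surface_load[[model]]
  if (length(b) == 1L && is.null(names(b))) return(as.numeric(b))
  key <- as.character(load)
  if (!key %in% names(b)) {
    cb_stop(sprintf("field 'total_surface_load' has no entry for load %s kg (%s model)",
                    key, model))
  }
  as.numeric(b[[key]])
}

# internal: mean-one lognormal multipliers with coefficient of variation cv
noise_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate bench trials for a virtual cushion
#'
#' Emulates the physical test procedure: for each buttock model and each
#' configured load, `trials_per_load` repeated loading trials are generated.
#' The noise-free construction shares the surface budget `T` equally within
#' channel class -- each bony channel carries `beta * T / 6` and each
#' non-bony channel `(1 - beta) * T / 6`, where
#' `beta = bony_fraction + load_shift * (load - 50) / 10` -- and each internal
#' channel carries one third of `internal_ratio * internal_reference_mean`.
#' Every reading is then multiplied by an independent mean-one lognormal
#' factor with the channel-class CV; with probability `outlier_prob` a
#' surface reading is additionally multiplied by `outlier_scale`.
#'
#' The positions of injected outliers are recorded in the returned table's
#' `"injected_outliers"` attribute, as ground truth for detector checks.
#'
#' @param spec A `virtual_cushion_spec`.
#' @param config A `threshold_config` (supplies loads and trials per load).
#' @return A `trial_table` with `config$trials_per_load` trials per model and
#'   load.
#' @examples
#' spec <- virtual_cushion_spec("demo", channel_cv = c(surface = 0, internal = 0))
#' trials <- simulate_trials(spec)
#' head(trials)
#' @export
simulate_trials <- function(spec, config = threshold_config()) {
  validate_spec(spec, config)
  if (length(config$loads) < 1) cb_stop("config$loads must be nonempty")

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  layout <- default_layout()
  surf_ids <- as.character(layout$surface_ids)
  bony <- surf_ids %in% as.character(layout$bony_ids)
  rows <- vector("list", 0L)
  injected <- vector("list", 0L)

  for (model in buttock_models()) {
    for (load in config$loads) {
      beta <- spec$bony_fraction[[model]] + spec$load_shift * (load - 50) / 10
      total <- surface_budget(spec, model, load)
      base_surface <- ifelse(bony, beta * total / 6, (1 - beta) * total / 6)
      base_internal <- rep(spec$internal_ratio[[model]] *
                             spec$internal_reference_mean[[model]] / 3, 3)
      for (trial in seq_len(config$trials_per_load)) {
        surf <- base_surface * noise_factor(12L, spec$channel_cv[["surface"]])
        if (spec$outlier_prob > 0) {
          hit <- stats::runif(12L) < spec$outlier_prob
          surf[hit] <- surf[hit] * spec$outlier_scale
          if (any(hit)) {
            injected[[length(injected) + 1L]] <- data.frame(
              cushion_id = spec$cushion_id, model = model, load_kg = load,
              trial = trial, channel = surf_ids[hit],
              stringsAsFactors = FALSE)
          }
        }
        int <- base_internal * noise_factor(3L, spec$channel_cv[["internal"]])
        rows[[length(rows) + 1L]] <- data.frame(
          cushion_id = spec$cushion_id, model = model, load_kg = load,
          trial = trial,
          channel = c(surf_ids, layout$internal_ids),
          class = rep(c("surface", "internal"), c(12L, 3L)),
          pressure_mmhg = c(surf, int),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- trial_table(do.call(rbind, rows), layout)
  attr(out, "injected_outliers") <- if (length(injected)) {
    do.call(rbind, injected)
  } else {
    data.frame(cushion_id = character(), model = character(),
               load_kg = numeric(), trial = integer(), channel = character(),
               stringsAsFactors = FALSE)
  }
  out
}

# internal: preset virtual specs for the two flat-foam reference materials.
# The 3" high-resiliency foam redistributes at the criterion values
# (bony fraction 0.50 elliptical / 0.56 trigonometric); the thinner 2" foam
# loads the bony set and the internal channels more heavily.
reference_presets <- function() {
  list(
    foam_3in = list(
      cushion_id = "HR45_3in",
      bony_fraction = c(elliptical = 0.50, trigonometric = 0.56),
      internal_reference_mean = c(elliptical = 230, trigonometric = 250)
    ),
    foam_2in = list(
      cushion_id = "HR45_2in",
      bony_fraction = c(elliptical = 0.52, trigonometric = 0.64),
      internal_reference_mean = c(elliptical = 285, trigonometric = 310)
    )
  )
}

#' Simulate trials of a flat-foam reference material
#'
#' Stands in for bench trials of the HR45 high-resiliency foam blocks used
#' as comparison standards: the 3-inch block (Skin Protection reference) and
#' the 2-inch block (General Use reference). Each preset is a fixed
#' [virtual_cushion_spec()] with `internal_ratio` 1, so the simulated SumInt
#' fluctuates around the preset reference mean; the 2-inch preset's internal
#' means are higher, making it the less stringent comparison standard.
#'
#' @param thickness `"foam_3in"` or `"foam_2in"`.
#' @param seed Integer seed.
#' @param config A `threshold_config`.
#' @param channel_cv Optional CV override (e.g. `c(surface = 0, internal = 0)`
#'   for noise-free reference trials).
#' @return A `trial_table` of reference trials.
#' @export
make_reference <- function(thickness = c("foam_3in", "foam_2in"),
                           seed = 1L,
                           config = threshold_config(),
                           channel_cv = NULL) {
  thickness <- match.arg(thickness)
  preset <- reference_presets()[[thickness]]
  args <- c(preset, list(seed = seed))
  if (!is.null(channel_cv)) args$channel_cv <- channel_cv
  spec <- do.call(virtual_cushion_spec, args)
  simulate_trials(spec, config)
}

#' Read or write a virtual-cushion spec as JSON
#'
#' The JSON sidecar written next to simulated trial CSVs records the
#' generating spec as ground truth for recovery tests.
#'
#' @param path File path.
#' @return `read_spec_json` returns a `virtual_cushion_spec`;
#'   `write_spec_json` returns `path` invisibly.
#' @export
read_spec_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$total_surface_load <- lapply(raw$total_surface_load, function(x) unlist(x))
  for (field in c("bony_fraction", "internal_ratio", "internal_reference_mean",
                  "channel_cv")) {
    raw[[field]] <- unlist(raw[[field]])
  }
  do.call(virtual_cushion_spec, raw)
}

#' @rdname read_spec_json
#' @param spec A `virtual_cushion_spec`.
#' @export
write_spec_json <- function(spec, path) {
  validate_spec(spec)
  out <- unclass(spec)
  out$total_surface_load <- lapply(out$total_surface_load, as.list)
  for (field in c("bony_fraction", "internal_ratio", "internal_reference_mean",
                  "channel_cv")) {
    out[[field]] <- as.list(out[[field]])
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.virtual_cushion_spec <- function(x, ...) {
  cat(sprintf("Virtual cushion '%s' (seed %d)\n", x$cushion_id, x$seed))
  cat(sprintf("  designed bony fraction: elliptical %.3f, trigonometric %.3f\n",
              x$bony_fraction[["elliptical"]], x$bony_fraction[["trigonometric"]]))
  cat(sprintf("  designed SumInt ratio:  elliptical %.3f, trigonometric %.3f\n",
              x$internal_ratio[["elliptical"]], x$internal_ratio[["trigonometric"]]))
  cat(sprintf("  channel CV: surface %.3f, internal %.3f; outliers p=%.3f x%.1f\n",
              x$channel_cv[["surface"]], x$channel_cv[["internal"]],
              x$outlier_prob, x$outlier_scale))
  invisible(x)
}
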