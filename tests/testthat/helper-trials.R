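# Fixture builders: small trial tables assembled in code.

# One model-load condition from a trials x 12 matrix of surface pressures.
make_condition <- function(surface_mat,
                           internal = c(I1 = 100, I2 = 80, I3 = 20),
                           cushion = "fixture", model = "elliptical",
                           load = 50) {
  stopifnot(ncol(surface_mat) == 12)
  rows <- lapply(seq_len(nrow(surface_mat)), function(i) {
    data.frame(cushion_id = cushion, model = model, load_kg = load, trial = i,
               channel = c(as.character(1:12), names(internal)),
               class = rep(c("surface", "internal"), c(12, 3)),
               pressure_mmhg = c(surface_mat[i, ], unname(internal)),
               stringsAsFactors = FALSE)
  })
  trial_table(do.call(rbind, rows))
}

# Uniform surface values with one channel overridden in one trial.
flat_surface <- function(n_trials = 6, value = 100) {
  matrix(value, nrow = n_trials, ncol = 12)
}

# Injected outliers that remain a minority within their channel-condition
# cell (at most 2 of the 6 repeated trials) -- the regime the median rule is
# designed for; a corrupted majority moves the median itself.
detectable_injected <- function(trials) {
  inj <- attr(trials, "injected_outliers")
  if (!nrow(inj)) return(inj)
  cell <- paste(inj$model, inj$load_kg, inj$channel)
  counts <- table(cell)
  inj[counts[cell] <= 2, , drop = FALSE]
}

# Per-cushion overall tiers assembled from the bundled benchmark cohort.
benchmark_levels <- function() {
  bench <- cohort_benchmarks()
  red <- bench$redistribution
  mag <- bench$magnitude
  cushions <- unique(red$cushion[red$category != "Reference"])
  levels <- vapply(cushions, function(cu) {
    r <- red[red$cushion == cu, ]
    redist <- stats::setNames(r$label, r$model)
    m3 <- mag[mag$cushion == cu & mag$reference == "foam_3in", ]
    m2 <- mag[mag$cushion == cu & mag$reference == "foam_2in" &
                mag$model == "elliptical", ]
    assign_level(
      redistribution = redist,
      magnitude_3in = if (nrow(m3)) stats::setNames(m3$label, m3$model),
      magnitude_2in_elliptical = if (nrow(m2)) m2$label else NA_character_
    )
  }, "")
  data.frame(cushion = cushions, level = unname(levels),
             stringsAsFactors = FALSE)
}
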