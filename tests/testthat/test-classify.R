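test_that("redistribution classes follow the strict CI-vs-criterion rule", {
  cfg <- threshold_config()
  expect_equal(classify_redistribution(interval_estimate(0.46, 0.45, 0.47),
                                       "elliptical", cfg), "High")
  expect_equal(classify_redistribution(interval_estimate(0.50, 0.49, 0.50),
                                       "elliptical", cfg), "Moderate")
  expect_equal(classify_redistribution(interval_estimate(0.69, 0.68, 0.71),
                                       "trigonometric", cfg), "Low")
  # a bound exactly at the criterion is Moderate (strict inequalities)
  expect_equal(classify_redistribution(interval_estimate(0.525, 0.50, 0.55),
                                       "elliptical", cfg), "Moderate")
})

test_that("magnitude classes follow the non-strict equivalence-band rule", {
  cfg <- threshold_config()
  expect_equal(classify_magnitude(ratio_estimate(0.70, 0.66, 0.75), cfg), "Superior")
  expect_equal(classify_magnitude(ratio_estimate(0.84, 0.78, 0.91), cfg), "Comparable")
  expect_equal(classify_magnitude(ratio_estimate(1.20, 1.11, 1.29), cfg), "Inferior")
  # CI touching a limit from the outer side still qualifies (<=, >=)
  expect_equal(classify_magnitude(ratio_estimate(0.85, 0.80, 0.90), cfg), "Superior")
  expect_equal(classify_magnitude(ratio_estimate(1.15, 1.10, 1.20), cfg), "Inferior")
  # fully inside the band is Comparable
  expect_equal(classify_magnitude(ratio_estimate(1.0, 0.95, 1.05), cfg), "Comparable")
})

test_that("both trichotomies are exhaustive and mutually exclusive", {
  cfg <- threshold_config()
  set.seed(12)
  for (i in 1:1000) {
    lo <- runif(1, 0, 1.6)
    hi <- lo + runif(1, 0, 0.5)
    mid <- (lo + hi) / 2
    tau <- cfg$redistribution_threshold[["elliptical"]]
    conds_r <- c(hi < tau, lo > tau, lo <= tau && tau <= hi)
    expect_equal(sum(conds_r), 1L)
    expect_equal(classify_redistribution(interval_estimate(mid, lo, hi),
                                         "elliptical", cfg),
                 c("High", "Low", "Moderate")[which(conds_r)])
    conds_m <- c(hi <= cfg$lel, lo >= cfg$uel, hi > cfg$lel && lo < cfg$uel)
    expect_equal(sum(conds_m), 1L)
    expect_equal(classify_magnitude(ratio_estimate(mid, lo, hi), cfg),
                 c("Superior", "Inferior", "Comparable")[which(conds_m)])
  }
})

test_that("shifting an interval upward never improves the redistribution class", {
  cfg <- threshold_config()
  rank_of <- function(lbl) match(lbl, c("High", "Moderate", "Low"))
  set.seed(13)
  for (i in 1:500) {
    lo <- runif(1, 0.2, 0.8)
    hi <- lo + runif(1, 0, 0.2)
    delta <- runif(1, 0, 0.3)
    base <- classify_redistribution(interval_estimate((lo + hi) / 2, lo, hi),
                                    "trigonometric", cfg)
    shifted <- classify_redistribution(
      interval_estimate((lo + hi) / 2 + delta, lo + delta, hi + delta),
      "trigonometric", cfg)
    expect_gte(rank_of(shifted), rank_of(base))
  }
})

test_that("shrinking a ratio interval cannot jump Superior <-> Inferior", {
  cfg <- threshold_config()
  set.seed(14)
  for (i in 1:500) {
    mid <- runif(1, 0.5, 1.5)
    w <- runif(1, 0, 0.4)
    shrink <- runif(1, 0, w / 2)
    base <- classify_magnitude(ratio_estimate(mid, mid - w / 2, mid + w / 2), cfg)
    tighter <- classify_magnitude(
      ratio_estimate(mid, mid - w / 2 + shrink, mid + w / 2 - shrink), cfg)
    if (base == "Superior") expect_equal(tighter, "Superior")
    if (base == "Inferior") expect_equal(tighter, "Inferior")
  }
})

test_that("the tier matrix places the cohort archetypes", {
  # High/High + Superior/Superior vs 3": top level
  expect_equal(assign_level(c(elliptical = "High", trigonometric = "High"),
                            c(elliptical = "Superior", trigonometric = "Superior")),
               "Level1")
  # Moderate/Low + Superior/Superior fails the both-model tiers, passes ellip-only
  expect_equal(assign_level(c(elliptical = "Moderate", trigonometric = "Low"),
                            c(elliptical = "Superior", trigonometric = "Superior")),
               "Level3")
  # Inferior against the 2" reference on the elliptical model
  expect_equal(assign_level(c(elliptical = "Moderate", trigonometric = "Low"),
                            magnitude_2in_elliptical = "Inferior"),
               "BelowMinimum")
  expect_equal(assign_level(c(elliptical = "Low", trigonometric = "Low"),
                            magnitude_2in_elliptical = "Comparable"),
               "GeneralUse")
  expect_equal(assign_level(c(elliptical = NA, trigonometric = NA)),
               "Indeterminate")
})

test_that("tier criteria nest: a top-level profile satisfies the lower tiers", {
  reds <- c("High", "Moderate", "Low")
  mags <- c("Superior", "Comparable", "Inferior")
  ge <- function(a, b, lv) match(a, lv) <= match(b, lv)
  set.seed(15)
  for (i in 1:500) {
    r <- stats::setNames(sample(reds, 2, replace = TRUE), buttock_models())
    m <- stats::setNames(sample(mags, 2, replace = TRUE), buttock_models())
    lvl <- assign_level(r, m)
    l1 <- all(r == "High") && all(m == "Superior")
    l2 <- all(ge(r[1], "Moderate", reds), ge(r[2], "Moderate", reds),
              ge(m[1], "Comparable", mags), ge(m[2], "Comparable", mags))
    l3 <- ge(r[["elliptical"]], "Moderate", reds) &&
      ge(m[["elliptical"]], "Comparable", mags)
    if (l1) {
      expect_true(l2 && l3)
      expect_equal(lvl, "Level1")
    }
    if (lvl == "Level2") expect_true(l3)
  }
})

test_that("borderline flags mark minimal threshold crossings", {
  cfg <- threshold_config()
  # CI 0.78-0.91 minimally crosses the 0.9 lower equivalence limit
  flags <- flag_borderline(ratio_estimate(0.84, 0.78, 0.91), "magnitude",
                           config = cfg)
  expect_equal(nrow(flags), 1)
  expect_equal(flags$threshold, 0.9)
  expect_equal(flags$distance, 0.01)
  # zero-width interval far from every threshold
  expect_equal(nrow(flag_borderline(ratio_estimate(1.0, 1.0, 1.0), "magnitude",
                                    config = cfg)), 0)
  # a bound exactly on the criterion is always borderline
  touch <- flag_borderline(interval_estimate(0.495, 0.49, 0.50),
                           "redistribution", "elliptical", cfg)
  expect_equal(touch$distance, 0)
  # near a limit, but no shift of that size can change the class: not flagged
  inert <- flag_borderline(ratio_estimate(0.97, 0.89, 1.05), "magnitude",
                           config = cfg)
  expect_equal(nrow(inert), 0)
})

test_that("retest suggestions trigger on 2\"-superiority and borderline flags", {
  base <- structure(list(
    cushion_id = "x",
    models = list(
      elliptical = list(magnitude_2in = list(class = "Superior")),
      trigonometric = list()
    ),
    borderline_flags = data.frame()
  ), class = "cushion_report")
  expect_equal(suggest_retests(base), "compare_vs_3in")

  base$models$elliptical$magnitude_3in <- list(class = "Comparable")
  base$borderline_flags <- data.frame(threshold = 0.9, distance = 0.01)
  expect_equal(suggest_retests(base), "add_trials")

  base$borderline_flags <- data.frame()
  expect_equal(suggest_retests(base), character())
})
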