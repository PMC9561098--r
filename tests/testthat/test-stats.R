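surface_vec <- function(bony, nonbony) {
  layout <- default_layout()
  v <- numeric(12)
  names(v) <- as.character(1:12)
  v[as.character(layout$bony_ids)] <- bony
  v[as.character(layout$nonbony_ids)] <- nonbony
  v
}

test_that("bony fraction is the bony share of total surface pressure", {
  expect_equal(bony_fraction(surface_vec(10, 10)), 0.5)
  expect_equal(bony_fraction(surface_vec(10, 5)), 60 / 90)
  expect_equal(bony_fraction(surface_vec(10, 0)), 1.0)
  expect_error(bony_fraction(surface_vec(0, 0)), "zero")
  expect_error(bony_fraction(surface_vec(1, 1)[-1]), "missing channel")
})

test_that("bony fraction is invariant to pressure rescaling", {
  set.seed(101)
  for (i in 1:50) {
    v <- stats::setNames(runif(12, 5, 200), as.character(1:12))
    c_scale <- runif(1, 0.01, 50)
    expect_equal(bony_fraction(v * c_scale), bony_fraction(v))
  }
})

test_that("SumInt adds the three internal channels", {
  expect_equal(sum_internal(c(I1 = 100, I2 = 80, I3 = 20)), 200)
  expect_equal(sum_internal(c(I1 = 0, I2 = 0, I3 = 0)), 0)
  expect_error(sum_internal(c(I1 = 1, I2 = 2)), "missing channel")
})

test_that("pooled interval matches the hand-computed two-load sample", {
  iv <- pooled_interval(c(rep(0.4, 6), rep(0.6, 6)))
  expect_equal(iv$mean, 0.5)
  expect_equal(iv$sd, sqrt(12 * 0.01 / 11))
  expect_equal(iv$upper - iv$mean, iv$sd / sqrt(12))
  expect_equal(round(iv$sd, 5), 0.10445)
  expect_equal(round(iv$upper - iv$mean, 5), 0.03015)
  # per-load subsets are degenerate; pooling deliberately widens the interval
  expect_equal(pooled_interval(rep(0.4, 6))$upper - pooled_interval(rep(0.4, 6))$lower, 0)
  expect_gt(iv$upper - iv$lower, 0)
})

test_that("pooled intervals are symmetric and tighten with replication", {
  set.seed(7)
  for (i in 1:25) {
    x <- rnorm(sample(4:16, 1), mean = 0.5, sd = 0.05)
    iv <- pooled_interval(x)
    expect_equal(iv$mean - iv$lower, iv$upper - iv$mean)
    wider <- iv$upper - iv$lower
    narrower <- with(pooled_interval(c(x, x)), upper - lower)
    expect_lt(narrower, wider)
  }
  expect_equal(with(pooled_interval(rep(0.5, 12)), c(mean, lower, upper)),
               c(0.5, 0.5, 0.5))
  expect_error(pooled_interval(0.5), "at least 2")
})

test_that("ci_multiplier scales the pooled half-width", {
  x <- c(rep(0.4, 6), rep(0.6, 6))
  iv1 <- pooled_interval(x, threshold_config(ci_multiplier = 1))
  iv196 <- pooled_interval(x, threshold_config(ci_multiplier = 1.96))
  expect_equal(iv196$upper - iv196$mean, 1.96 * (iv1$upper - iv1$mean))
})

test_that("ratio intervals behave on degenerate samples", {
  cfg <- threshold_config()
  x <- c(101, 99, 100, 100.5, 99.5, 100)
  for (method in c("fieller", "delta", "bootstrap")) {
    r <- ratio_interval(x, x, method, cfg, seed = 3)
    expect_equal(r$rho, 1.0)
    expect_lte(r$lower, 1.0)
    expect_gte(r$upper, 1.0)
    rz <- ratio_interval(rep(80, 6), rep(100, 6), method, cfg, seed = 3)
    expect_equal(c(rz$rho, rz$lower, rz$upper), c(0.8, 0.8, 0.8))
  }
})

test_that("Fieller flags a non-significant reference as unbounded", {
  cfg <- threshold_config(ci_multiplier = 1.96)
  test <- c(10, 11, 9, 10, 10.5, 9.5)
  ref <- c(-10, 12, -9, 11, -12, 10) # positive mean, CI spans 0
  expect_warning(r <- ratio_interval(test, ref, "fieller", cfg),
                 class = "cushionbench_unbounded_ratio")
  expect_true(r$unbounded)
  expect_warning(cls <- classify_magnitude(r), "unbounded")
  expect_equal(cls, "Comparable")
})

test_that("the three ratio constructions agree at bench noise levels", {
  cfg <- threshold_config()
  rel <- vapply(1:30, function(k) {
    set.seed(5000 + k)
    cv1 <- runif(1, 0.01, 0.05)
    cv0 <- runif(1, 0.01, 0.05)
    test <- rlnorm(12, log(180), sqrt(log(1 + cv1^2)))
    ref <- rlnorm(12, log(230), sqrt(log(1 + cv0^2)))
    h <- vapply(c("fieller", "delta", "bootstrap"), function(m) {
      r <- ratio_interval(test, ref, m, cfg, seed = k)
      (r$upper - r$lower) / 2
    }, numeric(1))
    (max(h) - min(h)) / max(h)
  }, numeric(1))
  expect_lt(mean(rel), 0.10)
})

test_that("coefficient of variation matches hand arithmetic", {
  expect_equal(coefficient_of_variation(rep(7, 5)), 0)
  expect_equal(round(coefficient_of_variation(c(90, 110)), 4), 0.1414)
  expect_error(coefficient_of_variation(c(1, -1)), "zero mean")
  expect_error(coefficient_of_variation(5), "at least 2")
})

test_that("equivalence-limit derivation averages 1.96*SEM/mean", {
  one <- data.frame(label = "a", mean_mmHg = 100, sd_mmHg = 10, n = 16)
  expect_equal(derive_equivalence_limit(one), 0.049)
  zero_sd <- data.frame(label = "b", mean_mmHg = 50, sd_mmHg = 0, n = 10)
  expect_equal(derive_equivalence_limit(zero_sd), 0)
  expect_equal(derive_equivalence_limit(rbind(one, zero_sd)), 0.0245)
  expect_error(derive_equivalence_limit(one[0, ]), "nonempty")
  bad <- data.frame(label = "c", mean_mmHg = -1, sd_mmHg = 1, n = 5)
  expect_error(derive_equivalence_limit(bad), "mean > 0")
})

test_that("simulated %Bony estimates recover the designed fraction", {
  spec <- virtual_cushion_spec(
    "recov", bony_fraction = c(elliptical = 0.46, trigonometric = 0.53),
    channel_cv = c(surface = 0.01, internal = 0.01), seed = 1L)
  params <- parameter_samples(simulate_trials(spec))
  for (model in buttock_models()) {
    iv <- pooled_interval(params$bony_fraction[params$model == model])
    expect_lt(abs(iv$mean - spec$bony_fraction[[model]]), 3 * iv$sd / sqrt(iv$n) + 1e-3)
  }
})
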