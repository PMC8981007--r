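# Uplift, cumulative gain and AUUC, checked against exhaustive hand
# computation on a small table and against exact normalization identities.

# Brute-force oracle: rank by score descending, take the top ceiling(f*n)
# rows, difference of mean(-y) between cohorts. Independent of the package's
# vectorized implementation.
brute_uplift <- function(scores, treat, y, fraction) {
  ord <- order(-scores)
  top <- ord[seq_len(ceiling(fraction * length(scores)))]
  tt <- top[treat[top] == 1]
  cc <- top[treat[top] == 0]
  if (length(tt) == 0 || length(cc) == 0) return(NA_real_)
  sum(-y[tt]) / length(tt) - sum(-y[cc]) / length(cc)
}

# 8-member toy: 4 treated, 4 control, hand-assigned outcomes and scores.
toy8 <- list(
  scores = c(8, 7, 6, 5, 4, 3, 2, 1),
  treat  = c(1, 0, 1, 0, 1, 0, 1, 0),
  y      = c(-2.0, -0.5, -1.5, -0.2, -0.6, -0.4, 0.3, 0.1))

test_that("uplift matches the brute-force table computation", {
  with(toy8, {
    # top half: rows 1-4, treated {-2.0, -1.5}, control {-0.5, -0.2}
    expect_equal(uplift_at_fraction(scores, treat, y, 0.5),
                 mean(c(2.0, 1.5)) - mean(c(0.5, 0.2)))
    for (f in c(0.25, 0.375, 0.5, 0.75, 1.0)) {
      expect_equal(uplift_at_fraction(scores, treat, y, f),
                   brute_uplift(scores, treat, y, f), tolerance = 1e-12)
    }
    # at fraction 1.0 the ranking is irrelevant
    expect_equal(uplift_at_fraction(rev(scores), treat, y, 1.0),
                 uplift_at_fraction(scores, treat, y, 1.0))
    # top quarter (rows 1-2) holds both cohorts; top eighth does not
    expect_true(is.na(uplift_at_fraction(scores, treat, y, 1 / 8)))
  })
})

test_that("the gain curve is uplift scaled by members covered", {
  with(toy8, {
    curve <- cumulative_gain_curve(scores, treat, y, n_quantiles = 4)
    fr <- c(0.25, 0.5, 0.75, 1.0)
    expected <- vapply(fr, function(f) brute_uplift(scores, treat, y, f) * f * 8,
                       numeric(1))
    expect_equal(curve$fractions, c(0, fr))
    expect_equal(curve$gains, c(0, expected), tolerance = 1e-12)
    expect_equal(curve$n_undefined, 0)
  })
})

test_that("constant outcomes give zero uplift and undefined normalization", {
  treat <- rep(c(1, 0), 10)
  y <- rep(1.5, 20)
  curve <- cumulative_gain_curve(seq_len(20), treat, y, n_quantiles = 5)
  expect_equal(curve$gains, rep(0, 6))
  expect_true(is.na(curve$auuc))
  expect_error(auuc(curve), class = "rdmprec_normalization_error")
})

test_that("a straight-line gain curve scores exactly one half", {
  curve <- structure(list(fractions = seq(0, 1, 0.1),
                          gains = seq(0, 1, 0.1) * -4.2,
                          n = 100, n_undefined = 0, auuc = NA_real_),
                     class = "uplift_curve")
  expect_equal(as.numeric(auuc(curve)), 0.5, tolerance = 1e-12)
})

test_that("constant scores trace the straight line to the total gain", {
  # a uniform treatment effect and no noise: every prefix of the (stable)
  # ranking has the same uplift, so the gain accrues linearly
  treat <- rep(c(1, 0), 50)
  y <- -0.8 * treat
  curve <- cumulative_gain_curve(rep(0, 100), treat, y, n_quantiles = 10)
  total <- curve$gains[11]
  expect_equal(curve$gains, curve$fractions * total, tolerance = 1e-9)
  expect_equal(as.numeric(curve$auuc), 0.5, tolerance = 1e-9)
})

test_that("AUUC is invariant to strictly monotone score transformations", {
  set.seed(7)
  n <- 200
  treat <- rep(c(1, 0), n / 2)
  sc <- stats::rnorm(n)
  y <- stats::rnorm(n) - treat * (0.5 + 0.3 * sc)
  a1 <- cumulative_gain_curve(sc, treat, y)$auuc
  a2 <- cumulative_gain_curve(exp(sc), treat, y)$auuc
  a3 <- cumulative_gain_curve(rank(sc, ties.method = "first"), treat, y)$auuc
  expect_equal(a1, a2, tolerance = 1e-12)
  expect_equal(a1, a3, tolerance = 1e-12)
})

test_that("single-cohort quantiles are skipped and counted", {
  # scores place all treated members first: the top deciles lack controls
  treat <- c(rep(1, 30), rep(0, 70))
  set.seed(13)
  y <- stats::rnorm(100) - 0.5 * treat
  curve <- cumulative_gain_curve(100:1, treat, y, n_quantiles = 10)
  expect_gt(curve$n_undefined, 0)
  expect_true(is.finite(curve$auuc))
})

test_that("random rankings average to one half", {
  set.seed(3)
  treat <- rbinom(400, 1, 0.4)
  y <- stats::rnorm(400) - 0.7 * treat
  rb <- random_auuc_baseline(treat, y, n_permutations = 100, seed = 5)
  expect_lt(abs(rb$mean - 0.5), 0.04)
  # deterministic under a fixed seed
  rb2 <- random_auuc_baseline(treat, y, n_permutations = 100, seed = 5)
  expect_identical(rb$values, rb2$values)
})
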