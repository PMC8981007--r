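# Doubly robust learner: feature construction, the pseudo-outcome identity,
# parameter recovery, and determinism.

test_that("pseudo-outcomes match hand-derived values", {
  # (g1 - g0) + t (y - g1)/p - (1 - t)(y - g0)/(1 - p)
  expect_equal(dr_pseudo_outcome(1.0, 1, 0.5, 0.2, 0.5), 1.3)
  expect_equal(dr_pseudo_outcome(0.0, 0, 0.5, 0.2, 0.5), 0.7)
  # zero-residual identity: y = g1, t = 1 -> g1 - g0 for any propensity
  for (p in c(0.1, 0.5, 0.9)) {
    expect_equal(dr_pseudo_outcome(0.5, 1, 0.5, 0.2, p), 0.3)
  }
  # vectorized
  expect_equal(dr_pseudo_outcome(c(1, 0), c(1, 0), c(0.5, 0.5),
                                 c(0.2, 0.2), c(0.5, 0.5)), c(1.3, 0.7))
  expect_error(dr_pseudo_outcome(1, 1, 0.5, 0.2, 0.5, clip = c(0, 0.99)),
               class = "rdmprec_config_error")
  # extreme propensities are clipped, keeping psi finite
  expect_true(is.finite(dr_pseudo_outcome(1, 1, 0.5, 0.2, 0)))
})

test_that("one-hot encoding yields one column per categorical level", {
  df <- data.frame(member_id = c("a", "b"),
                   x1 = c(1, 2), x2 = c(0, 1), x3 = c(5.5, 6.5),
                   x4 = c(10, 20), x5 = c(0.1, 0.2), x6 = c(3, 4),
                   x7 = c(1, 0), x8 = c(2, 2), x9 = c(7, 8),
                   x10 = c(0, 1), x11 = c(1, 1),
                   grp = c("low", "high"), stringsAsFactors = FALSE)
  fm <- build_feature_matrix(df, covariates = setdiff(names(df), "member_id"))
  # 11 numeric + 3 levels would be 14; here grp has 2 observed levels -> 13
  expect_equal(ncol(fm$X), 13)
  df2 <- rbind(df, df[1, ], df[1, ])
  df2$grp <- c("low", "high", "mid", "low")
  fm2 <- build_feature_matrix(df2, covariates = setdiff(names(df2), "member_id"))
  expect_equal(ncol(fm2$X), 14)  # 11 numeric + 3 one-hot columns
  expect_setequal(grep("^grp\\.", fm2$feature_names, value = TRUE),
                  c("grp.low", "grp.mid", "grp.high"))
  # identical members produce identical rows
  expect_equal(unname(fm2$X[1, ]), unname(fm2$X[4, ]))
  df2$x1 <- NA
  expect_error(build_feature_matrix(df2, covariates = setdiff(names(df2), "member_id")),
               class = "rdmprec_config_error")
})

test_that("feature means track the configured covariate distributions", {
  prep <- prepare_cohort(n = 2000, seed = 17)
  X <- prep$features$X
  expect_lt(abs(mean(X[, "age"]) - 55), 4 * 10 / sqrt(2000) + 1)
  expect_lt(abs(mean(X[, "bmi"]) - 32), 4 * 6 / sqrt(2000) + 1)
  expect_lt(abs(mean(X[, "insulin_use"]) - 0.35), 0.05)
  expect_lt(abs(mean(X[, "gender.female"]) - 0.55), 0.05)
})

test_that("a constant injected effect is recovered and fits are deterministic", {
  prep <- prepare_cohort(n = 1600, seed = 23,
                         effect_fn_coefs = constant_effects(list(coaching = -1)))
  tr <- as.integer(prep$flags$coaching)
  y <- prep$outcomes$outcome_y
  fit <- fit_light(prep$features$X, tr, y, seed = 7)
  expect_lt(abs(mean(fit$tau_validation) + 1.0), 0.25)
  # same seed -> identical model; different seed -> different split
  fit2 <- fit_light(prep$features$X, tr, y, seed = 7)
  expect_identical(fit$tau_validation, fit2$tau_validation)
  expect_identical(fit$idx_train, fit2$idx_train)
  fit3 <- fit_light(prep$features$X, tr, y, seed = 8)
  expect_false(identical(fit$idx_train, fit3$idx_train))
  # re-predicting training rows reproduces the stored predictions
  pred <- predict_cate(fit, prep$features$X[fit$idx_train, , drop = FALSE])
  expect_equal(pred$tau_hat, fit$tau_train)
  # column mismatch is a schema error
  Xbad <- prep$features$X[, rev(seq_len(ncol(prep$features$X)))]
  expect_error(predict_cate(fit, Xbad), class = "rdmprec_schema_error")
})

test_that("single-cohort training data cannot be fitted", {
  prep <- prepare_cohort(n = 300, seed = 2)
  expect_error(fit_light(prep$features$X, rep(1L, nrow(prep$features$X)),
                         prep$outcomes$outcome_y),
               class = "rdmprec_fit_error")
})

test_that("constant features collapse the CATE to the DR average effect", {
  prep <- prepare_cohort(n = 600, seed = 14,
                         effect_fn_coefs = constant_effects(list(coaching = -1)))
  X <- matrix(1, nrow(prep$features$X), 3,
              dimnames = list(rownames(prep$features$X), c("a", "b", "c")))
  fit <- fit_light(X, as.integer(prep$flags$coaching),
                   prep$outcomes$outcome_y, seed = 5)
  # no heterogeneity signal: tau_hat is a single constant ...
  expect_lt(stats::sd(fit$tau_train), 1e-8)
  # ... equal to the pseudo-outcome mean up to forest resampling error
  expect_lt(abs(mean(fit$tau_train) - mean(fit$psi_train)),
            3 * stats::sd(fit$psi_train) / sqrt(length(fit$psi_train)))
})

test_that("heterogeneous configurations yield mostly negative effects", {
  prep <- prepare_cohort(n = 1600, seed = 27)
  fit <- fit_light(prep$features$X, as.integer(prep$flags$coaching),
                   prep$outcomes$outcome_y, seed = 3)
  tau <- c(fit$tau_train, fit$tau_validation)
  expect_gt(mean(tau < 0), 0.6)   # most members predicted to benefit
  expect_gt(stats::sd(tau), 0.1)  # with real spread across members
})
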