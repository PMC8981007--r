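# Doubly robust CATE learner: cross-fitted nuisance models (gradient-boosted
# outcome regression g, gradient-boosted propensity classifier f), DR
# pseudo-outcomes, and a random-forest final stage regressing psi on X.

#' Build the model feature matrix
#'
#' Assembles the numeric covariate matrix used by the nuisance and CATE
#' models: demographics, self-reported medical variables, preferences, app/web
#' usage summaries, plus the outcome-derived covariates (eA1c at months two
#' and three, hypo-/hyperglycemic day counts in months one to three).
#' Character/factor columns are one-hot encoded with one column per level, in
#' sorted level order, so the column layout is a pure function of the input
#' schema.  Sporadic `NA`s (e.g. an undefined month-two eA1c) are imputed with
#' the column median; a column with no observed values at all is a
#' configuration error.
#'
#' @param members Eligible member data frame.
#' @param outcomes Matching [compute_outcomes()] rows, or `NULL` to use
#'   member covariates only.
#' @param covariates Character vector of member columns to include; defaults
#'   to every column except identifiers, eligibility flags, engagement
#'   counters and hidden ground truth.
#' @return List with `X` (numeric matrix, rownames = member ids) and
#'   `feature_names`.
#' @export
build_feature_matrix <- function(members, outcomes = NULL, covariates = NULL) {
  drop_cols <- c("member_id", "months_enrolled", "type2", "cgm_user",
                 "smbg_check_days", "coach_sessions_scheduled",
                 "coach_sessions_chat", "steps2000_days", "food_logs",
                 "nutrition_nudge_frac", "content_nudge_frac",
                 paste0("true_cate_", ACTION_CATEGORIES))
  if (is.null(covariates)) covariates <- setdiff(names(members), drop_cols)
  df <- members[, covariates, drop = FALSE]
  if (!is.null(outcomes)) {
    .assert(identical(members$member_id, outcomes$member_id),
            "members and outcomes must align on member_id",
            "rdmprec_config_error")
    keep <- intersect(c("ea1c_month2", "ea1c_month3",
                        paste0("hypo_days_month", 1:3),
                        paste0("hyper_days_month", 1:3)),
                      names(outcomes))
    df <- cbind(df, outcomes[, keep, drop = FALSE])
  }
  cols <- list()
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.character(v) || is.factor(v)) {
      v <- as.character(v)
      .assert(!all(is.na(v)), paste0("column '", nm, "' is entirely missing"),
              "rdmprec_config_error")
      for (lv in sort(unique(v[!is.na(v)]))) {
        cols[[paste0(nm, ".", lv)]] <- as.numeric(v == lv)
      }
    } else {
      v <- as.numeric(v)
      .assert(!all(is.na(v)), paste0("column '", nm, "' is entirely missing"),
              "rdmprec_config_error")
      if (anyNA(v)) v[is.na(v)] <- stats::median(v, na.rm = TRUE)
      cols[[nm]] <- v
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- members$member_id
  list(X = X, feature_names = colnames(X))
}

#' Doubly robust pseudo-outcome
#'
#' The DR score combining the outcome-model counterfactual contrast with the
#' inverse-propensity-weighted residual:
#' `psi = (g1 - g0) + t * (y - g1) / p - (1 - t) * (y - g0) / (1 - p)`.
#' Its conditional expectation equals the treatment effect tau(x) whenever
#' either the outcome model or the propensity model is correct.
#'
#' @param y Observed outcome (eA1c points).
#' @param t Treatment indicator, 0/1.
#' @param g1,g0 Outcome-model predictions under treatment / control.
#' @param p Propensity of treatment; clipped into `clip` before use.
#' @param clip Length-2 clipping bounds inside (0, 1).
#' @return Pseudo-outcome vector, eA1c points.
#' @export
dr_pseudo_outcome <- function(y, t, g1, g0, p, clip = c(0.01, 0.99)) {
  .assert(clip[1] > 0 && clip[2] < 1 && clip[1] <= clip[2],
          "clip bounds must satisfy 0 < low <= high < 1",
          "rdmprec_config_error")
  p <- pmin(pmax(p, clip[1]), clip[2])
  psi <- (g1 - g0) + t * (y - g1) / p - (1 - t) * (y - g0) / (1 - p)
  .assert(all(is.finite(psi)),
          paste("non-finite pseudo-outcome at rows",
                paste(utils::head(which(!is.finite(psi)), 5), collapse = ", ")),
          "rdmprec_fit_error")
  psi
}

# One gradient-boosted fit. kind = "regression" | "classification".
.boost_fit <- function(X, y, kind, params) {
  obj <- if (kind == "classification") "binary:logistic" else "reg:squarederror"
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = obj,
                  max_depth = params$max_depth %||% 3,
                  eta = params$eta %||% 0.1,
                  subsample = params$subsample %||% 0.8,
                  nthread = 1),
    data = dtrain,
    nrounds = params$nrounds %||% 120,
    verbose = 0)
}

.boost_predict <- function(model, X) {
  stats::predict(model, xgboost::xgb.DMatrix(X, nthread = 1))
}

# Counterfactual g1/g0 predictions from an outcome model fitted on [T, X].
.counterfactuals <- function(model, X) {
  list(g1 = .boost_predict(model, cbind(`.treat` = 1, X)),
       g0 = .boost_predict(model, cbind(`.treat` = 0, X)))
}

#' Fit the doubly robust CATE learner
#'
#' Procedure: (1) split rows into training and validation sets by
#' `split_ratio`; (2) on the training set, cross-fit the nuisance models in
#' `k_folds` folds — a gradient-boosted regressor of Y on (T, X) evaluated at
#' T=1 and T=0 for the counterfactual predictions g1/g0, and a
#' gradient-boosted classifier of T on X for the propensity, clipped into
#' `clip`; (3) form the DR pseudo-outcome psi per training row; (4) fit a
#' random-forest regression of psi on X as the final CATE model; (5) refit
#' the nuisances on the full training set, compute psi on the validation
#' rows, and report `validation_mse = mean((tau_hat(X_val) - psi_val)^2)`.
#'
#' All stochastic steps (split, folds, learners) are driven by `seed`, so an
#' identical call reproduces the identical model.
#'
#' @param X Numeric feature matrix from [build_feature_matrix()].
#' @param treat Treatment indicator vector, 0/1.
#' @param y Outcome vector (eA1c points; negative = improvement).
#' @param split_ratio Training fraction (default 0.65, i.e. a 65:35 split).
#' @param seed Integer seed.
#' @param k_folds Cross-fitting folds for the nuisances (default 5).
#' @param clip Propensity clipping bounds.
#' @param outcome_params,propensity_params Gradient-boosting hyperparameters
#'   (`nrounds`, `max_depth`, `eta`, `subsample`).
#' @param final_params Random-forest hyperparameters (`num.trees`,
#'   `min.node.size`).
#' @return Object of class `dr_learner`: the final `forest`, `feature_names`,
#'   train/validation indices, `psi_train`, `tau_train`, `tau_validation`,
#'   `psi_validation`, the refit nuisance models, and a `report` list
#'   (`n_train`, `n_validation`, `validation_mse`, `split_ratio`, `seed`,
#'   `k_folds`).
#' @export
fit_dr_learner <- function(X, treat, y,
                           split_ratio = 0.65,
                           seed = 1L,
                           k_folds = 5L,
                           clip = c(0.01, 0.99),
                           outcome_params = list(),
                           propensity_params = list(),
                           final_params = list()) {
  n <- nrow(X)
  .assert(length(treat) == n && length(y) == n,
          "X, treat, y must have matching lengths", "rdmprec_config_error")
  .assert(all(treat %in% c(0, 1)), "treat must be 0/1", "rdmprec_config_error")
  treat <- as.numeric(treat)

  set.seed(seed)
  idx_train <- sort(sample.int(n, round(split_ratio * n)))
  idx_val <- setdiff(seq_len(n), idx_train)
  .assert(length(unique(treat[idx_train])) == 2,
          "training split contains a single cohort; cannot fit nuisances",
          "rdmprec_fit_error")

  Xtr <- X[idx_train, , drop = FALSE]
  ttr <- treat[idx_train]
  ytr <- y[idx_train]
  ntr <- length(idx_train)

  folds <- sample(rep(seq_len(k_folds), length.out = ntr))
  g1 <- g0 <- p <- rep(NA_real_, ntr)
  for (k in seq_len(k_folds)) {
    hold <- folds == k
    fit_g <- .boost_fit(cbind(`.treat` = ttr[!hold], Xtr[!hold, , drop = FALSE]),
                        ytr[!hold], "regression", outcome_params)
    cf <- .counterfactuals(fit_g, Xtr[hold, , drop = FALSE])
    g1[hold] <- cf$g1
    g0[hold] <- cf$g0
    fit_f <- .boost_fit(Xtr[!hold, , drop = FALSE], ttr[!hold],
                        "classification", propensity_params)
    p[hold] <- .boost_predict(fit_f, Xtr[hold, , drop = FALSE])
  }
  psi_train <- dr_pseudo_outcome(ytr, ttr, g1, g0, p, clip)

  forest <- ranger::ranger(
    x = as.data.frame(Xtr), y = psi_train,
    num.trees = final_params$num.trees %||% 400,
    min.node.size = final_params$min.node.size %||% 20,
    seed = seed, num.threads = 1)

  # validation nuisances: refit on the full training set
  fit_g_full <- .boost_fit(cbind(`.treat` = ttr, Xtr), ytr, "regression",
                           outcome_params)
  fit_f_full <- .boost_fit(Xtr, ttr, "classification", propensity_params)
  Xval <- X[idx_val, , drop = FALSE]
  cf_val <- .counterfactuals(fit_g_full, Xval)
  p_val <- .boost_predict(fit_f_full, Xval)
  psi_val <- dr_pseudo_outcome(y[idx_val], treat[idx_val],
                               cf_val$g1, cf_val$g0, p_val, clip)
  tau_val <- stats::predict(forest, data = as.data.frame(Xval),
                     num.threads = 1)$predictions
  tau_tr <- stats::predict(forest, data = as.data.frame(Xtr),
                    num.threads = 1)$predictions

  structure(list(
    forest = forest,
    feature_names = colnames(X),
    idx_train = idx_train, idx_validation = idx_val,
    member_ids = rownames(X),
    psi_train = psi_train, psi_validation = psi_val,
    tau_train = tau_tr, tau_validation = tau_val,
    outcome_model = fit_g_full, propensity_model = fit_f_full,
    clip = clip,
    report = list(n_train = ntr, n_validation = length(idx_val),
                  validation_mse = mean((tau_val - psi_val)^2),
                  split_ratio = split_ratio, seed = seed,
                  k_folds = k_folds)),
    class = "dr_learner")
}

#' Predict per-member treatment effects from a fitted DR learner
#'
#' @param model A `dr_learner` from [fit_dr_learner()].
#' @param X Feature matrix with exactly the training columns.
#' @return Data frame `member_id` (row names of `X`, or row index), `tau_hat`
#'   in eA1c percentage points (negative = predicted improvement).
#' @export
predict_cate <- function(model, X) {
  .assert(inherits(model, "dr_learner"), "model must be a dr_learner",
          "rdmprec_config_error")
  .assert(identical(colnames(X), model$feature_names),
          "feature columns do not match the training columns",
          "rdmprec_schema_error")
  tau <- stats::predict(model$forest, data = as.data.frame(X),
                 num.threads = 1)$predictions
  .assert(all(is.finite(tau)), "non-finite CATE prediction",
          "rdmprec_fit_error")
  data.frame(member_id = rownames(X) %||% as.character(seq_len(nrow(X))),
             tau_hat = tau, stringsAsFactors = FALSE)
}

#' @export
print.dr_learner <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("Doubly robust CATE learner: %d train / %d validation ",
                     "(split %.2f), %d-fold cross-fit\n"),
              r$n_train, r$n_validation, r$split_ratio, r$k_folds))
  cat(sprintf("  validation MSE (tau_hat vs psi): %.4f\n", r$validation_mse))
  cat(sprintf("  mean validation tau_hat: %.3f eA1c points\n",
              mean(x$tau_validation)))
  invisible(x)
}
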