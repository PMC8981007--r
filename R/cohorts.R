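# Treatment / control cohort assignment from engagement thresholds, and the
# threshold sweep trading off model error, effect size and cohort balance.

#' Standard engagement thresholds for treatment assignment
#'
#' The program's per-category engagement thresholds over the first 90 days:
#' monitoring, >= 70 days with SMBG checks; coaching, >= 3 sessions (scheduled
#' or chat); physical activity, >= 30 days with 2000+ daily steps; nutrition,
#' >= 2 food logs OR >= 50\% yes responses to nutrition nudges; content,
#' >= 50\% yes responses to content nudges.
#'
#' @return Named list of thresholds keyed by category; nutrition is a
#'   two-clause list (`food_logs`, `nudge_frac`).
#' @export
box2_thresholds <- function() {
  list(monitoring = 70,
       coaching = 3,
       physical_activity = 30,
       nutrition = list(food_logs = 2, nudge_frac = 0.5),
       content = 0.5)
}

#' Per-category engagement metrics over days 0-90
#'
#' Reduces each member's engagement counters to the scalar metric each
#' category thresholds on: days with SMBG checks (monitoring), scheduled plus
#' chat coaching sessions (coaching), days with 2000+ steps (physical
#' activity), food logs and nutrition-nudge yes-fraction (nutrition), and
#' content-nudge yes-fraction (content).
#'
#' @param members Member data frame with engagement columns.
#' @return Data frame: `member_id`, `monitoring`, `coaching`,
#'   `physical_activity`, `nutrition_food_logs`, `nutrition_nudge_frac`,
#'   `content`.
#' @export
engagement_metrics <- function(members) {
  data.frame(
    member_id = members$member_id,
    monitoring = members$smbg_check_days,
    coaching = members$coach_sessions_scheduled + members$coach_sessions_chat,
    physical_activity = members$steps2000_days,
    nutrition_food_logs = members$food_logs,
    nutrition_nudge_frac = members$nutrition_nudge_frac,
    content = members$content_nudge_frac,
    stringsAsFactors = FALSE)
}

#' Assign treatment / control cohorts from engagement thresholds
#'
#' A member is in a category's treatment cohort when their engagement metric
#' meets or exceeds the threshold (nutrition: food logs >= threshold OR nudge
#' yes-fraction >= threshold).  Members below all five thresholds form the
#' "other" (control-only) group.
#'
#' @param members Member data frame with engagement columns.
#' @param thresholds Named threshold list covering all five categories; see
#'   [box2_thresholds()].
#' @return Data frame: `member_id`, one logical column per category
#'   (`TRUE` = treatment), and logical `other`.
#' @export
assign_cohorts <- function(members, thresholds = box2_thresholds()) {
  for (cat in ACTION_CATEGORIES) {
    .assert(cat %in% names(thresholds),
            paste0("thresholds missing category '", cat, "'"),
            "rdmprec_config_error")
  }
  m <- engagement_metrics(members)
  flags <- data.frame(member_id = m$member_id, stringsAsFactors = FALSE)
  flags$coaching <- m$coaching >= thresholds$coaching
  flags$monitoring <- m$monitoring >= thresholds$monitoring
  flags$physical_activity <- m$physical_activity >= thresholds$physical_activity
  flags$nutrition <- m$nutrition_food_logs >= thresholds$nutrition$food_logs |
    m$nutrition_nudge_frac >= thresholds$nutrition$nudge_frac
  flags$content <- m$content >= thresholds$content
  flags$other <- !(flags$coaching | flags$monitoring |
                     flags$physical_activity | flags$nutrition | flags$content)
  flags
}

# Replace one category's scalar threshold clause with a grid value.
.with_threshold <- function(thresholds, category, value) {
  if (category == "nutrition") {
    thresholds$nutrition$food_logs <- value
  } else {
    thresholds[[category]] <- value
  }
  thresholds
}

#' Sweep engagement thresholds for one category
#'
#' For each candidate threshold: assigns cohorts, fits the doubly robust
#' learner, and records cohort sizes, validation MSE and the mean predicted
#' treatment effect on the validation split.  Grid values that leave either
#' cohort below `min_cohort` members are flagged degenerate and not fitted.
#' For nutrition the grid varies the food-log clause while the nudge-fraction
#' clause stays at its configured value.
#'
#' @param members Eligible member data frame.
#' @param outcomes Matching [compute_outcomes()] rows.
#' @param category One of [ACTION_CATEGORIES].
#' @param grid Ascending numeric vector of candidate thresholds.
#' @param split_seed Seed for the train/validation split (and model fits).
#' @param thresholds Base threshold list for the other categories.
#' @param min_cohort Minimum treatment and control size to attempt a fit.
#' @param features Optional precomputed [build_feature_matrix()] result.
#' @param ... Passed to [fit_dr_learner()] (e.g. `k_folds`, learner params).
#' @return Data frame of sweep records: `category`, `threshold`,
#'   `n_treatment`, `n_control`, `degenerate`, `model_mse`,
#'   `avg_treatment_effect`.
#' @export
threshold_sweep <- function(members, outcomes, category, grid,
                            split_seed = 1L,
                            thresholds = box2_thresholds(),
                            min_cohort = 50,
                            features = NULL, ...) {
  .assert(length(grid) > 0 && !is.unsorted(grid),
          "grid must be nonempty and ascending", "rdmprec_config_error")
  .assert(category %in% ACTION_CATEGORIES,
          paste0("unknown action category '", category, "'"),
          "rdmprec_domain_error")
  if (is.null(features)) features <- build_feature_matrix(members, outcomes)
  res <- lapply(grid, function(th) {
    flags <- assign_cohorts(members, .with_threshold(thresholds, category, th))
    tr <- flags[[category]]
    n_t <- sum(tr)
    n_c <- sum(!tr)
    if (min(n_t, n_c) < min_cohort) {
      return(data.frame(category = category, threshold = th,
                        n_treatment = n_t, n_control = n_c,
                        degenerate = TRUE, model_mse = NA_real_,
                        avg_treatment_effect = NA_real_))
    }
    fit <- fit_dr_learner(features$X, as.integer(tr), outcomes$outcome_y,
                          seed = split_seed, ...)
    data.frame(category = category, threshold = th,
               n_treatment = n_t, n_control = n_c, degenerate = FALSE,
               model_mse = fit$report$validation_mse,
               avg_treatment_effect = mean(fit$tau_validation))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Select an engagement threshold from a sweep table
#'
#' Operationalizes "lower MSE while optimizing treatment effect": among
#' non-degenerate sweep records whose validation MSE lies within a relative
#' band of the minimum MSE, picks the record with the most negative average
#' treatment effect; ties go to the smaller threshold.
#'
#' @param sweep Data frame from [threshold_sweep()].
#' @param mse_band Relative band above the minimum MSE (default 0.10 = 10\%).
#' @return List `(category, threshold)` of the selected record.
#' @export
select_threshold <- function(sweep, mse_band = 0.10) {
  ok <- sweep[!sweep$degenerate, , drop = FALSE]
  .assert(nrow(ok) > 0, "all sweep records are degenerate",
          "rdmprec_selection_error")
  band_max <- min(ok$model_mse) * (1 + mse_band)
  cand <- ok[ok$model_mse <= band_max, , drop = FALSE]
  cand <- cand[order(cand$avg_treatment_effect, cand$threshold), , drop = FALSE]
  list(category = cand$category[1], threshold = cand$threshold[1])
}
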