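# Argmin-CATE action recommendation and the matched-vs-unmatched
# personalization analysis.

#' Recommend an action from per-category treatment effects
#'
#' The recommended action is the category with the most negative predicted
#' treatment effect (largest predicted eA1c reduction).  Members whose
#' predicted effects are all non-negative get `"none"`.  Exact ties are broken
#' by the fixed order of [ACTION_CATEGORIES] (coaching first).  Note that the
#' policy ranks purely on predicted outcome benefit; propensity to engage is
#' deliberately not part of the ranking.
#'
#' @param tau_by_category Named numeric vector with one finite tau-hat per
#'   category in [ACTION_CATEGORIES].
#' @return The recommended category name, or `"none"`.
#' @export
recommend_action <- function(tau_by_category) {
  .assert(all(ACTION_CATEGORIES %in% names(tau_by_category)),
          "tau_by_category must cover all five categories",
          "rdmprec_schema_error")
  tau <- tau_by_category[ACTION_CATEGORIES]
  .assert(all(is.finite(tau)), "tau values must be finite",
          "rdmprec_schema_error")
  if (min(tau) >= 0) return("none")
  ACTION_CATEGORIES[which.min(tau)]
}

#' Recommend actions for a table of members
#'
#' @param tau_df Data frame with `member_id` and one `tau_hat` column per
#'   category, named after [ACTION_CATEGORIES].
#' @param cohorts Optional [assign_cohorts()] flags; when given, a `matched`
#'   flag records whether the member's treatment memberships include the
#'   recommendation.
#' @return `tau_df` with added columns `recommended` and (when `cohorts` is
#'   given) `matched`.
#' @export
recommend_actions <- function(tau_df, cohorts = NULL) {
  .assert(all(c("member_id", ACTION_CATEGORIES) %in% names(tau_df)),
          "tau_df must have member_id and one column per category",
          "rdmprec_schema_error")
  tau_mat <- as.matrix(tau_df[, ACTION_CATEGORIES])
  .assert(all(is.finite(tau_mat)), "tau values must be finite",
          "rdmprec_schema_error")
  rec <- apply(tau_mat, 1, function(z) {
    if (min(z) >= 0) "none" else ACTION_CATEGORIES[which.min(z)]
  })
  out <- tau_df
  out$recommended <- unname(rec)
  if (!is.null(cohorts)) {
    idx <- match(out$member_id, cohorts$member_id)
    .assert(!anyNA(idx), "cohorts missing some members",
            "rdmprec_schema_error")
    out$matched <- vapply(seq_len(nrow(out)), function(i) {
      r <- out$recommended[i]
      if (r == "none") return(FALSE)
      isTRUE(cohorts[[r]][idx[i]])
    }, logical(1))
  }
  out
}

#' Matched-versus-unmatched outcome analysis
#'
#' For each category, among members in that category's treatment cohort,
#' compares the mean outcome of members whose recommendation matches the
#' category against those whose recommendation differs; also reports pooled
#' means over members in at least one treatment cohort (matched = the
#' recommended category is among their treatments).  Intended for
#' validation-split members.  Empty partitions are reported as `NA`, not
#' errors.
#'
#' @param recommendations Output of [recommend_actions()].
#' @param cohorts [assign_cohorts()] flags for the same members.
#' @param outcomes [compute_outcomes()] rows for the same members.
#' @return Data frame with one row per category plus a `"pooled"` row:
#'   `category`, `n_matched`, `n_unmatched`, `mean_y_matched`,
#'   `mean_y_unmatched`, `difference` (matched minus unmatched; negative
#'   means matched members improved more).
#' @export
matched_outcome_analysis <- function(recommendations, cohorts, outcomes) {
  idx_c <- match(recommendations$member_id, cohorts$member_id)
  idx_o <- match(recommendations$member_id, outcomes$member_id)
  .assert(!anyNA(idx_c) && !anyNA(idx_o),
          "cohorts/outcomes missing some recommended members",
          "rdmprec_schema_error")
  y <- outcomes$outcome_y[idx_o]
  rows <- lapply(ACTION_CATEGORIES, function(cat) {
    in_cohort <- cohorts[[cat]][idx_c]
    matched <- in_cohort & recommendations$recommended == cat
    unmatched <- in_cohort & recommendations$recommended != cat
    data.frame(category = cat,
               n_matched = sum(matched), n_unmatched = sum(unmatched),
               mean_y_matched = if (any(matched)) mean(y[matched]) else NA_real_,
               mean_y_unmatched = if (any(unmatched)) mean(y[unmatched]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  any_cohort <- Reduce(`|`, lapply(ACTION_CATEGORIES,
                                   function(cat) cohorts[[cat]][idx_c]))
  rec_received <- vapply(seq_along(idx_c), function(i) {
    r <- recommendations$recommended[i]
    r != "none" && isTRUE(cohorts[[r]][idx_c[i]])
  }, logical(1))
  pool_m <- any_cohort & rec_received
  pool_u <- any_cohort & !rec_received
  rows[[length(rows) + 1]] <- data.frame(
    category = "pooled",
    n_matched = sum(pool_m), n_unmatched = sum(pool_u),
    mean_y_matched = if (any(pool_m)) mean(y[pool_m]) else NA_real_,
    mean_y_unmatched = if (any(pool_u)) mean(y[pool_u]) else NA_real_,
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  out$difference <- out$mean_y_matched - out$mean_y_unmatched
  out
}

#' Distribution of recommended actions
#'
#' Fractions of each category among members with a non-`"none"`
#' recommendation; sums to one when nonempty.
#'
#' @param recommendations Output of [recommend_actions()].
#' @return Named numeric vector over [ACTION_CATEGORIES] (empty when no
#'   member has a recommendation).
#' @export
recommendation_distribution <- function(recommendations) {
  rec <- recommendations$recommended
  rec <- rec[rec != "none"]
  if (length(rec) == 0) return(stats::setNames(numeric(0), character(0)))
  tab <- table(factor(rec, levels = ACTION_CATEGORIES))
  stats::setNames(as.numeric(tab) / length(rec), ACTION_CATEGORIES)
}

#' Personalization effect: as-received versus if-optimal treatment effects
#'
#' For members in each category's treatment cohort, compares the mean
#' predicted effect of the category they received with the mean of their
#' per-member best (minimum) predicted effect across categories.  The
#' if-optimal mean is bounded above by the as-received mean by construction.
#'
#' @param tau_df Data frame with `member_id` and one tau-hat column per
#'   category.
#' @param cohorts [assign_cohorts()] flags for the same members.
#' @return Data frame: `category`, `n`, `mean_tau_as_received`,
#'   `mean_tau_if_optimal`.
#' @export
personalization_effect <- function(tau_df, cohorts) {
  idx <- match(tau_df$member_id, cohorts$member_id)
  .assert(!anyNA(idx), "cohorts missing some members", "rdmprec_schema_error")
  tau_mat <- as.matrix(tau_df[, ACTION_CATEGORIES])
  best <- apply(tau_mat, 1, min)
  rows <- lapply(ACTION_CATEGORIES, function(cat) {
    in_cohort <- cohorts[[cat]][idx]
    data.frame(category = cat, n = sum(in_cohort),
               mean_tau_as_received = if (any(in_cohort))
                 mean(tau_mat[in_cohort, cat]) else NA_real_,
               mean_tau_if_optimal = if (any(in_cohort))
                 mean(best[in_cohort]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
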