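# Outcome computation: estimated A1c from SMBG streams, the month-4 minus
# month-1 change score Y, and the study eligibility funnel.

#' Estimated A1c from SMBG readings over a 30-day window
#'
#' Applies the A1c-derived average glucose (ADAG) relation
#' eA1c = (mean BG + 46.7) / 28.7 to the valid readings falling in a 30-day
#' window.  Readings are valid when the value lies in \[50, 400\] mg/dL; the
#' window is half-open on the left, `(start, end]` in day offsets from
#' enrollment.  Fewer than `min_readings` valid in-window readings is an
#' insufficient-data error (classed condition `rdmprec_insufficient_data`),
#' never a silent default.
#'
#' @param readings Data frame with columns `day` and `value_mgdl` (a numeric
#'   vector of values may be given when all readings are in-window).
#' @param window Length-2 numeric `(start, end]`; must span 30 days.
#' @param min_readings Minimum number of valid in-window readings (default 5).
#' @param valid_range Per-reading validity range in mg/dL.
#' @return Estimated A1c in percent.
#' @export
#' @examples
#' days <- 1:30
#' estimated_a1c(data.frame(day = days, value_mgdl = rep(154.2, 30)),
#'               window = c(0, 30))  # 7.0
estimated_a1c <- function(readings, window, min_readings = 5,
                          valid_range = c(50, 400)) {
  if (is.numeric(readings)) {
    readings <- data.frame(day = rep(mean(window), length(readings)),
                           value_mgdl = readings)
  }
  .assert(length(window) == 2 && diff(window) == 30,
          "window must be a 30-day span c(start, end]", "rdmprec_config_error")
  v <- readings$value_mgdl[readings$day > window[1] &
                             readings$day <= window[2]]
  v <- v[v >= valid_range[1] & v <= valid_range[2]]
  if (length(v) < min_readings) {
    stop(errorCondition(
      sprintf("only %d valid readings in window (%g, %g]; need >= %d",
              length(v), window[1], window[2], min_readings),
      class = c("rdmprec_insufficient_data", "error", "condition")))
  }
  (mean(v) + ADAG_OFFSET) / ADAG_SCALE
}

#' Mean blood glucose implied by an estimated A1c
#'
#' Inverse of the ADAG relation: mean BG = 28.7 * eA1c - 46.7.
#'
#' @param ea1c Estimated A1c in percent.
#' @return Mean blood glucose in mg/dL.
#' @export
ea1c_to_mean_bg <- function(ea1c) ADAG_SCALE * ea1c - ADAG_OFFSET

#' Compute monthly eA1c values and the outcome Y for every member
#'
#' For each member, computes estimated A1c on the four consecutive 30-day
#' windows `(0,30], (30,60], (60,90], (90,120]` and the intervention outcome
#' `outcome_y = ea1c_month4 - ea1c_month1` (negative = clinical improvement).
#' Windows with fewer than `min_readings` valid readings yield `NA` — members
#' with an undefined month-1 or month-4 eA1c are later excluded by
#' [apply_eligibility()] rather than erroring here.  Months two and three are
#' retained because they serve as model covariates, together with counts of
#' hypo- and hyperglycemic reading days in months one to three.
#'
#' @param cohort An `rdmp_cohort`, or a member data frame when `smbg` is given.
#' @param smbg Long SMBG data frame (`member_id`, `day`, `value_mgdl`);
#'   ignored when `cohort` is an `rdmp_cohort`.
#' @param min_readings Minimum valid readings per window (default 5).
#' @param valid_range Per-reading validity range in mg/dL.
#' @param hypo_below,hyper_above Thresholds (mg/dL) defining hypo-/
#'   hyperglycemic readings for the day-count covariates.
#' @return Data frame with one row per member: `member_id`,
#'   `ea1c_month1` .. `ea1c_month4`, `n_valid_month1`, `n_valid_month4`,
#'   `outcome_y`, `hypo_days_month1..3`, `hyper_days_month1..3`.  Member order
#'   follows the input.
#' @export
compute_outcomes <- function(cohort, smbg = NULL, min_readings = 5,
                             valid_range = c(50, 400),
                             hypo_below = 70, hyper_above = 180) {
  if (inherits(cohort, "rdmp_cohort")) {
    members <- cohort$members
    smbg <- cohort$smbg
  } else {
    members <- cohort
    .assert(!is.null(smbg), "smbg readings required", "rdmprec_config_error")
  }
  ids <- members$member_id
  out <- data.frame(member_id = ids, stringsAsFactors = FALSE)
  for (k in 1:4) {
    out[[paste0("ea1c_month", k)]] <- NA_real_
  }
  out$n_valid_month1 <- 0L
  out$n_valid_month4 <- 0L
  for (k in 1:3) {
    out[[paste0("hypo_days_month", k)]] <- 0L
    out[[paste0("hyper_days_month", k)]] <- 0L
  }
  if (nrow(smbg) > 0) {
    valid <- smbg$value_mgdl >= valid_range[1] & smbg$value_mgdl <= valid_range[2]
    sv <- smbg[valid & smbg$day > 0 & smbg$day <= 120, , drop = FALSE]
    sv$month <- ceiling(sv$day / 30)
    means <- tapply(sv$value_mgdl, list(factor(match(sv$member_id, ids),
                                               levels = seq_along(ids)),
                                        factor(sv$month, levels = 1:4)),
                    mean)
    counts <- tapply(sv$value_mgdl, list(factor(match(sv$member_id, ids),
                                                levels = seq_along(ids)),
                                         factor(sv$month, levels = 1:4)),
                     length)
    counts[is.na(counts)] <- 0L
    for (k in 1:4) {
      enough <- counts[, k] >= min_readings
      ea <- ifelse(enough, (means[, k] + ADAG_OFFSET) / ADAG_SCALE, NA_real_)
      out[[paste0("ea1c_month", k)]] <- as.numeric(ea)
    }
    out$n_valid_month1 <- as.integer(counts[, 1])
    out$n_valid_month4 <- as.integer(counts[, 4])
    # distinct days with at least one hypo / hyper reading, months 1-3
    for (k in 1:3) {
      mk <- sv[sv$month == k, , drop = FALSE]
      hy <- mk[mk$value_mgdl < hypo_below, c("member_id", "day")]
      hr <- mk[mk$value_mgdl > hyper_above, c("member_id", "day")]
      tab_h <- tapply(unique(hy)$day, factor(match(unique(hy)$member_id, ids),
                                             levels = seq_along(ids)), length)
      tab_r <- tapply(unique(hr)$day, factor(match(unique(hr)$member_id, ids),
                                             levels = seq_along(ids)), length)
      tab_h[is.na(tab_h)] <- 0L
      tab_r[is.na(tab_r)] <- 0L
      out[[paste0("hypo_days_month", k)]] <- as.integer(tab_h)
      out[[paste0("hyper_days_month", k)]] <- as.integer(tab_r)
    }
  }
  out$outcome_y <- out$ea1c_month4 - out$ea1c_month1
  out
}

#' Apply the study eligibility filter
#'
#' Retains members satisfying, in this fixed funnel order:
#' \enumerate{
#'   \item enrolled at least four months (`months_enrolled >= 4`),
#'   \item self-reported type 2 diabetes (`type2` truthy),
#'   \item no self-reported continuous glucose monitor use (`cgm_user` falsy),
#'   \item at least `min_readings` valid SMBG readings in month one AND month
#'     four (i.e. both eA1c values defined),
#'   \item baseline estimated A1c at 30 days post enrollment
#'     (`ea1c_month1`) >= `min_baseline`.
#' }
#' Each excluded member is counted once, at its first failing rule, and input
#' order is preserved in the retained set.
#'
#' @param members Member data frame with `months_enrolled`, `type2`,
#'   `cgm_user` columns.
#' @param outcomes Output of [compute_outcomes()] for the same members.
#' @param min_baseline Minimum baseline eA1c in percent (default 7.5).
#' @param min_readings Minimum valid readings per window (default 5; used only
#'   for the exclusion-reason label).
#' @return List with `members` and `outcomes` (retained rows, input order),
#'   `funnel` (data frame `rule`, `n_excluded` in funnel order), and
#'   `exclusion_reason` (per input member; `""` when retained).
#' @export
apply_eligibility <- function(members, outcomes, min_baseline = 7.5,
                              min_readings = 5) {
  .assert(identical(members$member_id, outcomes$member_id),
          "members and outcomes must align on member_id",
          "rdmprec_config_error")
  rules <- c("not_enrolled_4_months", "not_type2", "cgm_user",
             "insufficient_smbg", "baseline_below_7.5")
  fails <- cbind(
    members$months_enrolled < 4,
    !as.logical(members$type2),
    as.logical(members$cgm_user),
    is.na(outcomes$ea1c_month1) | is.na(outcomes$ea1c_month4),
    !is.na(outcomes$ea1c_month1) & outcomes$ea1c_month1 < min_baseline
  )
  first_fail <- apply(fails, 1, function(z) {
    w <- which(z)
    if (length(w) == 0) 0L else w[1]
  })
  reason <- ifelse(first_fail == 0L, "", rules[pmax(first_fail, 1L)])
  keep <- first_fail == 0L
  funnel <- data.frame(rule = rules,
                       n_excluded = as.integer(tabulate(first_fail, 5)),
                       stringsAsFactors = FALSE)
  list(members = members[keep, , drop = FALSE],
       outcomes = outcomes[keep, , drop = FALSE],
       funnel = funnel,
       exclusion_reason = reason)
}
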