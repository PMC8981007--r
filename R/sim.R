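# Synthetic cohort generator: members with covariates, confounded engagement,
# SMBG streams, and known ground-truth per-category treatment effects.

#' Default covariate specification for the synthetic cohort
#'
#' Twelve member-level variables mirroring the covariates a remote diabetes
#' monitoring program collects at enrollment: four demographic (age, gender,
#' BMI, race), six self-reported medical (baseline HbA1c, insulin use, oral
#' medication use, flu vaccination, smoking, self-efficacy in diabetes
#' management), and two preference variables (preferred communication channel,
#' interest in physical activity).
#'
#' Each entry is a list with `name`, `kind` (one of `"continuous"`, `"binary"`,
#' `"categorical"`, `"ordinal"`) and distribution parameters: continuous uses
#' `mean`/`sd` (normal), binary uses `prob`, categorical/ordinal use a named
#' `probs` vector.  The `mean`/`sd` (or the theoretical moments implied by
#' `probs` for ordinal variables) also define the standardization used when
#' coefficient vectors reference a variable as `z_<name>`.
#'
#' @return A list of covariate specification entries.
#' @export
default_covariate_spec <- function() {
  list(
    list(name = "age", kind = "continuous", mean = 55, sd = 10),
    list(name = "gender", kind = "categorical",
         probs = c(female = 0.55, male = 0.45)),
    list(name = "bmi", kind = "continuous", mean = 32, sd = 6),
    list(name = "race", kind = "categorical",
         probs = c(white = 0.60, black = 0.15, hispanic = 0.15,
                   asian = 0.06, other = 0.04)),
    list(name = "hba1c_baseline", kind = "continuous", mean = 8.6, sd = 1.0),
    list(name = "insulin_use", kind = "binary", prob = 0.35),
    list(name = "oral_meds", kind = "binary", prob = 0.70),
    list(name = "flu_vaccine", kind = "binary", prob = 0.50),
    list(name = "smoker", kind = "binary", prob = 0.15),
    list(name = "self_efficacy", kind = "ordinal",
         probs = c(`1` = 0.10, `2` = 0.20, `3` = 0.35, `4` = 0.25, `5` = 0.10)),
    list(name = "comms_pref", kind = "categorical",
         probs = c(email = 0.50, sms = 0.30, phone = 0.20)),
    list(name = "activity_interest", kind = "ordinal",
         probs = c(`1` = 0.15, `2` = 0.25, `3` = 0.30, `4` = 0.20, `5` = 0.10))
  )
}

#' Default engagement propensity coefficients (logit scale)
#'
#' One named coefficient vector per action category mapping standardized
#' covariates to the log-odds of being an "engager" in that category.
#' Engagement is deliberately confounded with the untreated outcome drift
#' (both load on baseline HbA1c and self-efficacy), so naive
#' treated-minus-control contrasts are biased and the doubly robust learner
#' has real work to do.  Coefficients are scaled so propensities span roughly
#' 0.1 to 0.9.
#'
#' @return Named list of named numeric vectors, one per category.
#' @export
default_propensity_coefs <- function() {
  list(
    coaching = c("(Intercept)" = -0.2, z_hba1c_baseline = -0.45, z_self_efficacy = 0.5,
                 insulin_use = 0.25, z_age = 0.2),
    monitoring = c("(Intercept)" = 0.1, z_hba1c_baseline = -0.35, z_self_efficacy = 0.55,
                   z_age = 0.35, oral_meds = 0.15),
    physical_activity = c("(Intercept)" = -0.4, z_activity_interest = 0.8,
                          z_bmi = -0.45, z_age = -0.3, smoker = -0.3),
    nutrition = c("(Intercept)" = -0.5, z_bmi = 0.35, z_self_efficacy = 0.35,
                  z_hba1c_baseline = -0.25, "gender:female" = 0.25),
    content = c("(Intercept)" = -0.3, z_self_efficacy = 0.4, z_age = 0.3,
                z_hba1c_baseline = -0.3, "comms_pref:email" = 0.3)
  )
}

#' Default ground-truth effect functions (eA1c percentage points)
#'
#' Per-category linear effect functions tau(x) on the estimated-A1c scale;
#' negative values mean the action improves (lowers) eA1c.  Each category's
#' heterogeneity loads on a different covariate so the per-member optimal
#' action varies across the cohort, with coaching and monitoring the largest
#' effects on average.
#'
#' @return Named list of named numeric vectors, one per category.
#' @export
default_effect_coefs <- function() {
  list(
    coaching = c("(Intercept)" = -0.9, z_hba1c_baseline = -0.7, insulin_use = -0.15),
    monitoring = c("(Intercept)" = -0.8, z_age = -0.7),
    physical_activity = c("(Intercept)" = -0.6, z_bmi = -0.6,
                          z_activity_interest = -0.35),
    nutrition = c("(Intercept)" = -0.5, z_bmi = -0.55, smoker = 0.3),
    content = c("(Intercept)" = -0.45, z_self_efficacy = 0.7)
  )
}

#' Default untreated outcome drift coefficients (eA1c percentage points)
#'
#' Linear model for the change in eA1c between month one and month four that a
#' member would experience with no above-threshold engagement: mild regression
#' toward better control on average, worse drift for members with higher
#' baseline HbA1c and insulin use.  Shares covariates with the engagement
#' propensities, which is what makes the synthetic cohort confounded.
#'
#' @return Named numeric coefficient vector.
#' @export
default_baseline_coefs <- function() {
  c("(Intercept)" = -0.2, z_hba1c_baseline = 0.55, insulin_use = 0.2,
    z_self_efficacy = -0.35)
}

#' Default engagement count distributions
#'
#' Given a member's latent engager indicator per category, observable
#' engagement counts are drawn from a "high" or "low" regime:
#' days-with-SMBG-checks and days-with-2000-steps are binomial over the 90-day
#' window, coaching sessions and food logs are Poisson, and nudge yes-responses
#' are binomial over the number of nudges delivered.  The regimes overlap, so
#' thresholding the counts yields treatment groups that track, but do not
#' equal, the latent propensity.
#'
#' @return Named list of per-category distribution parameter lists.
#' @export
default_engagement_dists <- function() {
  list(
    monitoring = list(days = 90, p_hi = 0.85, p_lo = 0.55),
    coaching = list(rate_hi = 5, rate_lo = 0.8, scheduled_frac = 0.6),
    physical_activity = list(days = 90, p_hi = 0.50, p_lo = 0.20),
    nutrition = list(rate_hi = 6, rate_lo = 0.5, n_nudges = 10,
                     p_yes_hi = 0.7, p_yes_lo = 0.2),
    content = list(n_nudges = 12, p_yes_hi = 0.7, p_yes_lo = 0.2)
  )
}

#' Configure a synthetic member cohort
#'
#' Bundles every knob of the data-generating process: cohort size, covariate
#' distributions, per-category engagement propensity coefficients, ground-truth
#' effect functions, untreated outcome drift, and noise levels.  The generative
#' model is the observational analogue of the causal setup Y = g(T, X),
#' T = f(X): covariates X drive both engagement (hence treatment membership)
#' and the untreated outcome drift, treatment effects are injected on the eA1c
#' scale, and SMBG streams are synthesized so that the month-four minus
#' month-one eA1c difference recovers drift + received effects in expectation.
#'
#' @param n_members Number of members to generate (>= 0).
#' @param seed Integer seed; each member uses the substream `seed + index`, so
#'   growing the cohort leaves earlier members unchanged.
#' @param covariate_spec See [default_covariate_spec()].
#' @param propensity_coefs See [default_propensity_coefs()]; must cover all
#'   five categories.
#' @param effect_fn_coefs See [default_effect_coefs()]; must cover all five
#'   categories.
#' @param baseline_outcome_coefs See [default_baseline_coefs()].
#' @param noise_sd Member-level outcome noise, eA1c percentage points.
#' @param bg_noise_sd Per-reading SMBG noise, mg/dL.
#' @param engagement_dists See [default_engagement_dists()].
#' @param thresholds Engagement thresholds defining which generated members
#'   actually "receive" each treatment (and hence whose outcomes carry the
#'   injected effect); defaults to the program's standard thresholds,
#'   [box2_thresholds()].
#' @param read_prob Daily probability that a member takes an SMBG reading.
#' @param months Enrollment length in 30-day months for retained members.
#' @param dropout_frac Fraction of members whose data stops before month four.
#' @param non_t2_frac Fraction without a type 2 diabetes self-report.
#' @param cgm_frac Fraction self-reporting continuous glucose monitor use.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_members = 2000,
                       seed = 1L,
                       covariate_spec = default_covariate_spec(),
                       propensity_coefs = default_propensity_coefs(),
                       effect_fn_coefs = default_effect_coefs(),
                       baseline_outcome_coefs = default_baseline_coefs(),
                       noise_sd = 0.3,
                       bg_noise_sd = 25,
                       engagement_dists = default_engagement_dists(),
                       thresholds = box2_thresholds(),
                       read_prob = 0.6,
                       months = 4L,
                       dropout_frac = 0.04,
                       non_t2_frac = 0.03,
                       cgm_frac = 0.04) {
  .assert(is.numeric(n_members) && length(n_members) == 1 && n_members >= 0,
          "n_members must be a single non-negative number",
          "rdmprec_config_error")
  .assert(noise_sd >= 0 && bg_noise_sd >= 0,
          "noise standard deviations must be non-negative",
          "rdmprec_config_error")
  .assert(read_prob > 0 && read_prob <= 1,
          "read_prob must be in (0, 1]", "rdmprec_config_error")
  for (nm in ACTION_CATEGORIES) {
    .assert(nm %in% names(propensity_coefs),
            paste0("propensity_coefs missing category '", nm, "'"),
            "rdmprec_config_error")
    .assert(nm %in% names(effect_fn_coefs),
            paste0("effect_fn_coefs missing category '", nm, "'"),
            "rdmprec_config_error")
  }
  for (cv in covariate_spec) {
    .assert(all(c("name", "kind") %in% names(cv)),
            "covariate_spec entries need 'name' and 'kind'",
            "rdmprec_config_error")
    ok <- switch(cv$kind,
      continuous = is.numeric(cv$mean) && is.numeric(cv$sd) && cv$sd > 0,
      binary = is.numeric(cv$prob) && cv$prob >= 0 && cv$prob <= 1,
      categorical = ,
      ordinal = is.numeric(cv$probs) && !is.null(names(cv$probs)) &&
        all(cv$probs >= 0) && abs(sum(cv$probs) - 1) < 1e-8,
      FALSE)
    .assert(isTRUE(ok),
            paste0("invalid distribution parameters for covariate '",
                   cv$name, "'"),
            "rdmprec_config_error")
  }
  structure(
    list(n_members = as.integer(n_members), seed = as.integer(seed),
         covariate_spec = covariate_spec,
         propensity_coefs = propensity_coefs,
         effect_fn_coefs = effect_fn_coefs,
         baseline_outcome_coefs = baseline_outcome_coefs,
         noise_sd = noise_sd, bg_noise_sd = bg_noise_sd,
         engagement_dists = engagement_dists, thresholds = thresholds,
         read_prob = read_prob, months = as.integer(months),
         dropout_frac = dropout_frac, non_t2_frac = non_t2_frac,
         cgm_frac = cgm_frac),
    class = "sim_config")
}

# Theoretical mean/sd of a covariate under its configured distribution;
# used for the z_<name> standardization in coefficient vectors.
.cov_moments <- function(cv) {
  switch(cv$kind,
    continuous = c(mean = cv$mean, sd = cv$sd),
    binary = c(mean = cv$prob, sd = sqrt(cv$prob * (1 - cv$prob))),
    ordinal = {
      lv <- as.numeric(names(cv$probs))
      m <- sum(lv * cv$probs)
      c(mean = m, sd = sqrt(sum((lv - m)^2 * cv$probs)))
    },
    stop("no moments for categorical covariate ", cv$name))
}

#' Evaluate a linear predictor over member covariates
#'
#' Coefficient names follow a small grammar: `(Intercept)`; `z_<name>` for a
#' covariate standardized by its configured theoretical mean and sd;
#' `<name>` for a raw binary/numeric covariate; `<name>:<level>` for a
#' categorical level indicator.
#'
#' @param members Member data frame (as produced by [generate_cohort()]).
#' @param coefs Named numeric coefficient vector.
#' @param covariate_spec Covariate specification used to generate `members`.
#' @return Numeric vector, one value per member.
#' @export
linear_predictor <- function(members, coefs, covariate_spec) {
  spec_by_name <- stats::setNames(covariate_spec,
                                  vapply(covariate_spec, `[[`, "", "name"))
  out <- rep(0, nrow(members))
  for (term in names(coefs)) {
    b <- coefs[[term]]
    if (term == "(Intercept)") {
      out <- out + b
    } else if (startsWith(term, "z_")) {
      nm <- substring(term, 3)
      .assert(nm %in% names(spec_by_name),
              paste0("unknown covariate in term '", term, "'"),
              "rdmprec_config_error")
      mo <- .cov_moments(spec_by_name[[nm]])
      out <- out + b * (members[[nm]] - mo[["mean"]]) / mo[["sd"]]
    } else if (grepl(":", term, fixed = TRUE)) {
      parts <- strsplit(term, ":", fixed = TRUE)[[1]]
      out <- out + b * as.numeric(members[[parts[1]]] == parts[2])
    } else {
      .assert(term %in% names(members),
              paste0("unknown covariate term '", term, "'"),
              "rdmprec_config_error")
      out <- out + b * as.numeric(members[[term]])
    }
  }
  out
}

# Draw one covariate for n members under its spec entry.
.draw_covariate <- function(cv, n) {
  switch(cv$kind,
    continuous = stats::rnorm(n, cv$mean, cv$sd),
    binary = as.integer(stats::runif(n) < cv$prob),
    categorical = names(cv$probs)[
      1L + findInterval(stats::runif(n), cumsum(cv$probs),
                        rightmost.closed = TRUE)
    ][seq_len(n)],
    ordinal = as.integer(names(cv$probs))[
      1L + findInterval(stats::runif(n), cumsum(cv$probs))
    ][seq_len(n)])
}

# Engagement counts for one member given latent engager indicators (named
# logical vector over categories). Returns a named list of count fields.
.draw_engagement <- function(engaged, dists) {
  dm <- dists$monitoring
  dc <- dists$coaching
  dp <- dists$physical_activity
  dn <- dists$nutrition
  dk <- dists$content
  smbg_days <- stats::rbinom(1, dm$days,
                             if (engaged[["monitoring"]]) dm$p_hi else dm$p_lo)
  sessions <- stats::rpois(1, if (engaged[["coaching"]]) dc$rate_hi else dc$rate_lo)
  scheduled <- stats::rbinom(1, sessions, dc$scheduled_frac)
  step_days <- stats::rbinom(1, dp$days,
                             if (engaged[["physical_activity"]]) dp$p_hi else dp$p_lo)
  food_logs <- stats::rpois(1, if (engaged[["nutrition"]]) dn$rate_hi else dn$rate_lo)
  nutr_yes <- stats::rbinom(1, dn$n_nudges,
                            if (engaged[["nutrition"]]) dn$p_yes_hi else dn$p_yes_lo)
  cont_yes <- stats::rbinom(1, dk$n_nudges,
                            if (engaged[["content"]]) dk$p_yes_hi else dk$p_yes_lo)
  list(smbg_check_days = smbg_days,
       coach_sessions_scheduled = scheduled,
       coach_sessions_chat = sessions - scheduled,
       steps2000_days = step_days,
       food_logs = food_logs,
       nutrition_nudge_frac = nutr_yes / dn$n_nudges,
       content_nudge_frac = cont_yes / dk$n_nudges)
}

#' Generate a synthetic member cohort
#'
#' Draws covariates, confounded engagement counts, and SMBG reading streams
#' for `config$n_members` members.  Each member's data comes from an
#' independent RNG substream keyed by `config$seed + member index`, so cohorts
#' are bitwise reproducible and extending `n_members` does not perturb
#' existing members.
#'
#' The SMBG stream encodes the outcome: the month-one mean blood glucose sits
#' at the member's baseline level, the untreated drift accrues linearly over
#' months two to four, and the received treatment effects (plus member-level
#' noise) appear in the month-four level, after the 90-day engagement window.
#' By month four the mean glucose has shifted by `28.7 *` (untreated drift +
#' sum of received treatment effects + noise) mg/dL — i.e. the month-four
#' minus month-one estimated A1c equals the injected effect in expectation —
#' while months two and three reflect drift only, so they remain valid model
#' covariates.  A member "receives" a treatment when their generated
#' engagement counts clear `config$thresholds` for that category.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `rdmp_cohort` with elements `members` (one row per
#'   member: covariates, enrollment/eligibility flags, engagement counts, and
#'   hidden ground-truth `true_cate_<category>` columns), `smbg` (long data
#'   frame `member_id`, `day`, `value_mgdl`), and `config`.
#' @export
generate_cohort <- function(config) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config object",
          "rdmprec_config_error")
  n <- config$n_members
  cov_names <- vapply(config$covariate_spec, `[[`, "", "name")
  if (n == 0) {
    members <- data.frame(member_id = character(0))
    smbg <- data.frame(member_id = character(0), day = integer(0),
                       value_mgdl = numeric(0))
    return(structure(list(members = members, smbg = smbg, config = config),
                     class = "rdmp_cohort"))
  }

  # Pass 1 (substream seed + i): covariates, flags, and the uniform draws
  # that decide latent engagement, plus the member-level noise terms.  The
  # covariate-dependent quantities (propensities, effects, drift) are then
  # evaluated vectorized over the whole cohort, and pass 2 (substream
  # seed + i + offset) draws engagement counts and the SMBG stream.  Both
  # substreams are keyed by member index, so growing the cohort leaves
  # existing members bitwise unchanged.
  ncat <- length(ACTION_CATEGORIES)
  cols <- list(member_id = sprintf("M%06d", seq_len(n)))
  cov_vals <- vector("list", length(cov_names))
  names(cov_vals) <- cov_names
  for (nm in cov_names) cov_vals[[nm]] <- vector("list", n)
  gap_app <- gap_web <- eps <- ea1c_noise <- numeric(n)
  type2 <- cgm <- months_enr <- integer(n)
  u_engage <- matrix(NA_real_, n, ncat,
                     dimnames = list(NULL, ACTION_CATEGORIES))
  for (i in seq_len(n)) {
    set.seed((config$seed + i) %% 2147483647L)
    for (cv in config$covariate_spec) {
      cov_vals[[cv$name]][[i]] <- .draw_covariate(cv, 1)
    }
    # app/web usage summaries (average days between uses)
    gap_app[i] <- stats::rlnorm(1, meanlog = 1.0, sdlog = 0.6)
    gap_web[i] <- stats::rlnorm(1, meanlog = 1.8, sdlog = 0.7)
    type2[i] <- as.integer(stats::runif(1) >= config$non_t2_frac)
    cgm[i] <- as.integer(stats::runif(1) < config$cgm_frac)
    months_enr[i] <- if (stats::runif(1) < config$dropout_frac)
      sample(2:3, 1) else config$months
    u_engage[i, ] <- stats::runif(ncat)
    eps[i] <- stats::rnorm(1, 0, config$noise_sd)
    ea1c_noise[i] <- stats::rnorm(1, 0, 0.25)
  }
  for (nm in cov_names) {
    cols[[nm]] <- unlist(cov_vals[[nm]], use.names = FALSE)
  }
  cols$avg_gap_app <- gap_app
  cols$avg_gap_web <- gap_web
  cols$type2 <- type2
  cols$cgm_user <- cgm
  cols$months_enrolled <- months_enr
  members <- as.data.frame(cols, stringsAsFactors = FALSE)

  tau <- vapply(ACTION_CATEGORIES, function(cat) {
    linear_predictor(members, config$effect_fn_coefs[[cat]],
                     config$covariate_spec)
  }, numeric(n))
  drift <- linear_predictor(members, config$baseline_outcome_coefs,
                            config$covariate_spec)
  engaged <- vapply(ACTION_CATEGORIES, function(cat) {
    p <- stats::plogis(linear_predictor(members,
                                        config$propensity_coefs[[cat]],
                                        config$covariate_spec))
    u_engage[, cat] < p
  }, logical(n))
  if (n == 1) {
    tau <- matrix(tau, 1, dimnames = list(NULL, ACTION_CATEGORIES))
    engaged <- matrix(engaged, 1, dimnames = list(NULL, ACTION_CATEGORIES))
  }

  eng_rows <- vector("list", n)
  smbg_id <- vector("list", n)
  smbg_day <- vector("list", n)
  smbg_val <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed((config$seed + i + 1048576L) %% 2147483647L)
    rec <- .draw_engagement(engaged[i, ], config$engagement_dists)
    received <- .metrics_clear_thresholds(rec, config$thresholds)
    total_change <- drift[i] + sum(tau[i, received]) + eps[i]

    # SMBG stream: month-one mean glucose sits at the member's baseline;
    # the untreated drift accrues linearly over months 2-4, while the
    # treatment effect (plus outcome noise) materializes in month four,
    # after the 90-day engagement window.  Months two and three therefore
    # reflect drift but not yet the effect, which keeps them usable as
    # model covariates.
    ea1c_base <- members$hba1c_baseline[i] + ea1c_noise[i]
    bg_base <- ADAG_SCALE * ea1c_base - ADAG_OFFSET
    n_days <- 30L * months_enr[i]
    days <- which(stats::runif(n_days) < config$read_prob)
    month <- ceiling(days / 30)
    level <- bg_base + ADAG_SCALE * (drift[i] * (month - 1) / 3 +
                                       (total_change - drift[i]) * (month == 4))
    eng_rows[[i]] <- rec
    smbg_id[[i]] <- rep.int(cols$member_id[i], length(days))
    smbg_day[[i]] <- days
    smbg_val[[i]] <- stats::rnorm(length(days), level, config$bg_noise_sd)
  }

  for (fld in names(eng_rows[[1]])) {
    members[[fld]] <- vapply(eng_rows, `[[`, numeric(1), fld)
  }
  for (cat in ACTION_CATEGORIES) {
    members[[paste0("true_cate_", cat)]] <- tau[, cat]
  }
  smbg <- data.frame(member_id = unlist(smbg_id), day = unlist(smbg_day),
                     value_mgdl = unlist(smbg_val),
                     stringsAsFactors = FALSE)
  structure(list(members = members, smbg = smbg, config = config),
            class = "rdmp_cohort")
}

# Which categories does a member's engagement clear? Works on a one-member
# record list or a members data frame (returns a matrix in that case).
.metrics_clear_thresholds <- function(rec, thresholds) {
  vapply(ACTION_CATEGORIES, function(cat) {
    th <- thresholds[[cat]]
    switch(cat,
      monitoring = rec$smbg_check_days >= th,
      coaching = (rec$coach_sessions_scheduled + rec$coach_sessions_chat) >= th,
      physical_activity = rec$steps2000_days >= th,
      nutrition = rec$food_logs >= th$food_logs |
        rec$nutrition_nudge_frac >= th$nudge_frac,
      content = rec$content_nudge_frac >= th)
  }, logical(length(rec$smbg_check_days)))
}

#' Look up a member's ground-truth treatment effect
#'
#' Pure lookup of the data-generating effect stored by [generate_cohort()];
#' available only for synthetic cohorts and hidden from the estimators.
#'
#' @param cohort An `rdmp_cohort` object.
#' @param category One of [ACTION_CATEGORIES].
#' @param member_id Optional member id(s); default all members, in cohort order.
#' @return Numeric vector of true effects in eA1c percentage points.
#' @export
true_cate <- function(cohort, category, member_id = NULL) {
  .assert(inherits(cohort, "rdmp_cohort"), "cohort must be an rdmp_cohort",
          "rdmprec_domain_error")
  .assert(category %in% ACTION_CATEGORIES,
          paste0("unknown action category '", category, "'"),
          "rdmprec_domain_error")
  col <- paste0("true_cate_", category)
  if (is.null(member_id)) return(cohort$members[[col]])
  idx <- match(member_id, cohort$members$member_id)
  .assert(!anyNA(idx), "unknown member_id", "rdmprec_domain_error")
  cohort$members[[col]][idx]
}

#' Ground-truth treatment probability P(T = 1 | X) for a category
#'
#' Closed-form marginal probability that a member's generated engagement
#' clears the category threshold, combining the latent engager propensity
#' with the binomial/Poisson count regimes.  An oracle utility for
#' bias/robustness checks on synthetic cohorts.
#'
#' @param config The `sim_config` used to generate the members.
#' @param members Member data frame.
#' @param category One of [ACTION_CATEGORIES].
#' @param thresholds Threshold list; defaults to the config's.
#' @return Numeric vector of probabilities.
#' @export
true_propensity <- function(config, members, category,
                            thresholds = config$thresholds) {
  .assert(category %in% ACTION_CATEGORIES,
          paste0("unknown action category '", category, "'"),
          "rdmprec_domain_error")
  p_eng <- stats::plogis(linear_predictor(members,
                                          config$propensity_coefs[[category]],
                                          config$covariate_spec))
  d <- config$engagement_dists[[category]]
  th <- thresholds[[category]]
  clear <- switch(category,
    monitoring = c(hi = 1 - stats::pbinom(th - 1, d$days, d$p_hi),
                   lo = 1 - stats::pbinom(th - 1, d$days, d$p_lo)),
    coaching = c(hi = 1 - stats::ppois(th - 1, d$rate_hi),
                 lo = 1 - stats::ppois(th - 1, d$rate_lo)),
    physical_activity = c(hi = 1 - stats::pbinom(th - 1, d$days, d$p_hi),
                          lo = 1 - stats::pbinom(th - 1, d$days, d$p_lo)),
    nutrition = {
      k <- ceiling(th$nudge_frac * d$n_nudges)
      c(hi = 1 - stats::ppois(th$food_logs - 1, d$rate_hi) *
          stats::pbinom(k - 1, d$n_nudges, d$p_yes_hi),
        lo = 1 - stats::ppois(th$food_logs - 1, d$rate_lo) *
          stats::pbinom(k - 1, d$n_nudges, d$p_yes_lo))
    },
    content = {
      k <- ceiling(th * d$n_nudges)
      c(hi = 1 - stats::pbinom(k - 1, d$n_nudges, d$p_yes_hi),
        lo = 1 - stats::pbinom(k - 1, d$n_nudges, d$p_yes_lo))
    })
  p_eng * clear[["hi"]] + (1 - p_eng) * clear[["lo"]]
}

#' Ground-truth outcome regression E[Y | T, X] for a category
#'
#' Closed-form conditional mean of the outcome given treatment status in one
#' category, marginalizing over the other categories' (conditionally
#' independent) treatment uptake: untreated drift + t * tau_category +
#' sum over other categories of tau * P(treated | X).  Oracle utility for
#' double-robustness checks on synthetic cohorts.
#'
#' @inheritParams true_propensity
#' @param t Treatment value, 0 or 1.
#' @return Numeric vector of expected outcomes (eA1c points).
#' @export
true_outcome_regression <- function(config, members, category, t,
                                    thresholds = config$thresholds) {
  drift <- linear_predictor(members, config$baseline_outcome_coefs,
                            config$covariate_spec)
  tau_cat <- linear_predictor(members, config$effect_fn_coefs[[category]],
                              config$covariate_spec)
  out <- drift + t * tau_cat
  for (other in setdiff(ACTION_CATEGORIES, category)) {
    tau_o <- linear_predictor(members, config$effect_fn_coefs[[other]],
                              config$covariate_spec)
    out <- out + tau_o * true_propensity(config, members, other, thresholds)
  }
  out
}

#' Write a cohort's CSV artifacts
#'
#' Writes `members.csv` (wide covariate/engagement columns, without the hidden
#' ground truth), `smbg.csv` (`member_id`, `day`, `value_mgdl`) and
#' `truth.csv` (`member_id`, `category`, `true_cate`) to a directory.
#'
#' @param cohort An `rdmp_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth_cols <- paste0("true_cate_", ACTION_CATEGORIES)
  mem <- cohort$members[, setdiff(names(cohort$members), truth_cols),
                        drop = FALSE]
  paths <- file.path(dir, c("members.csv", "smbg.csv", "truth.csv"))
  utils::write.csv(mem, paths[1], row.names = FALSE)
  utils::write.csv(cohort$smbg, paths[2], row.names = FALSE)
  if (nrow(cohort$members) > 0) {
    truth <- data.frame(
      member_id = rep(cohort$members$member_id, length(ACTION_CATEGORIES)),
      category = rep(ACTION_CATEGORIES, each = nrow(cohort$members)),
      true_cate = unlist(lapply(truth_cols, function(cl) cohort$members[[cl]]),
                         use.names = FALSE))
  } else {
    truth <- data.frame(member_id = character(0), category = character(0),
                        true_cate = numeric(0))
  }
  utils::write.csv(truth, paths[3], row.names = FALSE)
  invisible(paths)
}
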