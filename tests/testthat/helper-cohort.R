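# Shared test utilities: light learner settings and prepared cohorts.
# Simulation sizes here trade statistical resolution for runtime; the
# acceptance tests use the larger sizes stated for each property.

light_boost <- function() list(nrounds = 40, max_depth = 3, eta = 0.2)

fit_light <- function(X, treat, y, seed = 1L, ...) {
  fit_dr_learner(X, treat, y, seed = seed, k_folds = 2L,
                 outcome_params = light_boost(),
                 propensity_params = light_boost(),
                 final_params = list(num.trees = 150), ...)
}

# Per-category effect coefficient lists for controlled scenarios.
constant_effects <- function(values) {
  stats::setNames(lapply(ACTION_CATEGORIES, function(cat) {
    c("(Intercept)" = if (cat %in% names(values)) values[[cat]] else 0)
  }), ACTION_CATEGORIES)
}

zero_effects <- function() constant_effects(list())

# Generate, compute outcomes, filter, build features and flags in one go.
prepare_cohort <- function(n = 800, seed = 1L, ...) {
  cohort <- generate_cohort(sim_config(n_members = n, seed = seed, ...))
  outcomes <- compute_outcomes(cohort)
  elig <- apply_eligibility(cohort$members, outcomes)
  features <- build_feature_matrix(elig$members, elig$outcomes)
  flags <- assign_cohorts(elig$members)
  list(cohort = cohort, members = elig$members, outcomes = elig$outcomes,
       features = features, flags = flags)
}

# Hand-built one-row member engagement record.
toy_member <- function(smbg_days = 72, scheduled = 2, chat = 1,
                       step_days = 30, food_logs = 0, nutr_frac = 0,
                       cont_frac = 0.5) {
  data.frame(member_id = "T000001", smbg_check_days = smbg_days,
             coach_sessions_scheduled = scheduled,
             coach_sessions_chat = chat, steps2000_days = step_days,
             food_logs = food_logs, nutrition_nudge_frac = nutr_frac,
             content_nudge_frac = cont_frac, stringsAsFactors = FALSE)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "rdmprec", mustWork = TRUE)
}
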