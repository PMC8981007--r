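# End-to-end orchestration: simulate -> outcomes -> cohorts -> DR fits (x5)
# -> uplift evaluation -> recommendations, with CSV/JSON artifacts and a run
# report.

#' Build a full run configuration
#'
#' Collects every stage's parameters with complete defaults.  The global
#' `seed` drives the simulator and, offset per stage and category, every
#' other stochastic step, so a run is reproducible end to end.
#'
#' @param sim A [sim_config()]; its seed is overridden by `seed`.
#' @param thresholds `"box2"` for the standard thresholds, or a named list of
#'   sweep grids per category (e.g. `list(coaching = 1:8)`) to select
#'   thresholds by sweep.
#' @param model List of model options: `split_ratio`, `k_folds`, `clip`,
#'   `outcome_params`, `propensity_params`, `final_params`, `min_cohort`,
#'   `mse_band`.
#' @param eval List of evaluation options: `n_quantiles`, `n_permutations`.
#' @param seed Global integer seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), thresholds = "box2",
                       model = list(), eval = list(), seed = 1L) {
  model_def <- list(split_ratio = 0.65, k_folds = 5L, clip = c(0.01, 0.99),
                    outcome_params = list(), propensity_params = list(),
                    final_params = list(), min_cohort = 50, mse_band = 0.10)
  eval_def <- list(n_quantiles = 10, n_permutations = 200)
  model <- utils::modifyList(model_def, model)
  eval <- utils::modifyList(eval_def, eval)
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, thresholds = thresholds, model = model,
                 eval = eval, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Reads a YAML file whose top-level keys mirror [run_config()] (`sim`,
#' `thresholds`, `model`, `eval`, `seed`); anything omitted keeps its
#' default.  Within `sim`, scalar fields (`n_members`, `noise_sd`, ...) and
#' coefficient maps (`propensity_coefs`, `effect_fn_coefs`,
#' `baseline_outcome_coefs`) may be overridden.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  for (nm in c("propensity_coefs", "effect_fn_coefs")) {
    if (!is.null(sim_args[[nm]])) {
      sim_args[[nm]] <- lapply(sim_args[[nm]], unlist)
    }
  }
  if (!is.null(sim_args$baseline_outcome_coefs)) {
    sim_args$baseline_outcome_coefs <- unlist(sim_args$baseline_outcome_coefs)
  }
  sim <- do.call(sim_config, sim_args)
  run_config(sim = sim,
             thresholds = raw$thresholds %||% "box2",
             model = raw$model %||% list(),
             eval = raw$eval %||% list(),
             seed = raw$seed %||% 1L)
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> outcomes -> eligibility -> cohort assignment (with an
#' optional threshold sweep) -> doubly robust CATE fit per category -> uplift
#' evaluation against a random baseline -> action recommendation, writing
#' every stage artifact plus `report.json` to `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the run report list (also written as `report.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  .assert(inherits(config, "run_config"), "config must be a run_config",
          "rdmprec_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- generate_cohort(config$sim)
  write_cohort(cohort, out_dir)
  .log_stage("simulate", "generated %d members, %d SMBG readings",
             nrow(cohort$members), nrow(cohort$smbg))

  outcomes <- compute_outcomes(cohort)
  elig <- apply_eligibility(cohort$members, outcomes)
  utils::write.csv(outcomes, file.path(out_dir, "outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(elig$funnel, file.path(out_dir, "funnel.csv"),
                   row.names = FALSE)
  .log_stage("outcomes", "%d of %d members eligible",
             nrow(elig$members), nrow(cohort$members))
  .assert(nrow(elig$members) >= 2 * config$model$min_cohort,
          "eligible cohort too small to fit any category",
          "rdmprec_pipeline_error")

  members <- elig$members
  outc <- elig$outcomes
  features <- build_feature_matrix(members, outc)

  thresholds <- box2_thresholds()
  selected <- list()
  if (!identical(config$thresholds, "box2")) {
    for (cat in names(config$thresholds)) {
      sweep <- threshold_sweep(
        members, outc, cat, config$thresholds[[cat]],
        split_seed = config$seed, thresholds = thresholds,
        min_cohort = config$model$min_cohort, features = features,
        split_ratio = config$model$split_ratio,
        k_folds = config$model$k_folds, clip = config$model$clip,
        outcome_params = config$model$outcome_params,
        propensity_params = config$model$propensity_params,
        final_params = config$model$final_params)
      utils::write.csv(sweep,
                       file.path(out_dir, paste0("sweep_", cat, ".csv")),
                       row.names = FALSE)
      sel <- select_threshold(sweep, config$model$mse_band)
      thresholds <- .with_threshold(thresholds, cat, sel$threshold)
      selected[[cat]] <- sel$threshold
      .log_stage("sweep", "%s: selected threshold %g", cat, sel$threshold)
    }
  }

  flags <- assign_cohorts(members, thresholds)
  utils::write.csv(flags, file.path(out_dir, "cohorts.csv"),
                   row.names = FALSE)
  .log_stage("cohorts", "treatment sizes: %s",
             paste(sprintf("%s=%d", ACTION_CATEGORIES,
                           vapply(ACTION_CATEGORIES,
                                  function(cat) sum(flags[[cat]]), 0L)),
                   collapse = ", "))

  fits <- list()
  evals <- list()
  for (ci in seq_along(ACTION_CATEGORIES)) {
    cat_nm <- ACTION_CATEGORIES[ci]
    tr <- as.integer(flags[[cat_nm]])
    .assert(min(sum(tr), sum(1 - tr)) >= config$model$min_cohort,
            paste0("cohort too small for category '", cat_nm, "'"),
            "rdmprec_pipeline_error")
    fit <- fit_dr_learner(features$X, tr, outc$outcome_y,
                          split_ratio = config$model$split_ratio,
                          seed = config$seed,
                          k_folds = config$model$k_folds,
                          clip = config$model$clip,
                          outcome_params = config$model$outcome_params,
                          propensity_params = config$model$propensity_params,
                          final_params = config$model$final_params)
    fits[[cat_nm]] <- fit
    tau_all <- predict_cate(fit, features$X)
    split_lab <- rep("train", nrow(features$X))
    split_lab[fit$idx_validation] <- "validation"
    cate_df <- data.frame(member_id = tau_all$member_id,
                          tau_hat = tau_all$tau_hat, split = split_lab,
                          stringsAsFactors = FALSE)
    utils::write.csv(cate_df,
                     file.path(out_dir, paste0("cate_", cat_nm, ".csv")),
                     row.names = FALSE)

    iv <- fit$idx_validation
    curve <- cumulative_gain_curve(-fit$tau_validation, tr[iv],
                                   outc$outcome_y[iv],
                                   config$eval$n_quantiles)
    baseline <- random_auuc_baseline(tr[iv], outc$outcome_y[iv],
                                     config$eval$n_quantiles,
                                     config$eval$n_permutations,
                                     seed = config$seed + 1000L + ci)
    evals[[cat_nm]] <- list(auuc = curve$auuc,
                            random_mean = baseline$mean,
                            random_sd = baseline$sd)
    up_df <- data.frame(fraction = curve$fractions, gain = curve$gains,
                        ranking = "model")
    utils::write.csv(up_df,
                     file.path(out_dir, paste0("uplift_", cat_nm, ".csv")),
                     row.names = FALSE)
    .log_stage("fit", "%s: n_t=%d mse=%.3f auuc=%.3f (random %.3f)",
               cat_nm, sum(tr), fit$report$validation_mse,
               curve$auuc, baseline$mean)
  }

  # recommendations on the common validation split
  iv <- fits[[1]]$idx_validation
  tau_df <- data.frame(member_id = members$member_id[iv],
                       stringsAsFactors = FALSE)
  for (cat_nm in ACTION_CATEGORIES) {
    tau_df[[cat_nm]] <- fits[[cat_nm]]$tau_validation
  }
  recs <- recommend_actions(tau_df, flags)
  utils::write.csv(recs, file.path(out_dir, "recommendations.csv"),
                   row.names = FALSE)
  matched <- matched_outcome_analysis(recs, flags, outc)
  utils::write.csv(matched, file.path(out_dir, "matched_analysis.csv"),
                   row.names = FALSE)
  dist <- recommendation_distribution(recs)
  jsonlite::write_json(as.list(dist), file.path(out_dir, "distribution.json"),
                       auto_unbox = TRUE, digits = NA)
  perso <- personalization_effect(tau_df, flags)
  .log_stage("recommend", "distribution: %s",
             paste(sprintf("%s=%.2f", names(dist), dist), collapse = ", "))

  report <- list(
    seed = config$seed,
    n_members = nrow(cohort$members),
    n_eligible = nrow(members),
    funnel = stats::setNames(as.list(elig$funnel$n_excluded),
                             elig$funnel$rule),
    selected_thresholds = selected,
    fit = lapply(fits, function(f) f$report),
    auuc = evals,
    recommendation_distribution = as.list(dist),
    matched_vs_unmatched = matched,
    personalization = perso)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(report)
}
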