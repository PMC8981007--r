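# Uplift-by-quantile evaluation: cumulative gain curves and normalized AUUC
# against a random-ranking baseline.

#' Uplift within the top-ranked fraction of the population
#'
#' Ranks members by `scores` descending (ties broken by stable input order)
#' and, within the top `fraction`, returns the treated-minus-control
#' difference in mean sign-flipped outcome, `mean(-y | treated) -
#' mean(-y | control)`, so that positive uplift means the treatment lowered
#' eA1c more.  Pass `scores = -tau_hat` so that members with the most negative
#' predicted effect rank first.
#'
#' @param scores Numeric ranking scores, higher = ranked earlier.
#' @param treat Treatment indicator vector, 0/1.
#' @param y Outcome vector (eA1c points, negative = improvement).
#' @param fraction Population fraction in (0, 1].
#' @return Uplift in eA1c points, or `NA` when the top-fraction subset lacks
#'   one of the cohorts (undefined uplift).
#' @export
uplift_at_fraction <- function(scores, treat, y, fraction) {
  n <- length(scores)
  .assert(length(treat) == n && length(y) == n,
          "scores, treat, y must align", "rdmprec_config_error")
  .assert(fraction > 0 && fraction <= 1, "fraction must be in (0, 1]",
          "rdmprec_config_error")
  top <- order(-scores)[seq_len(ceiling(fraction * n))]
  t_top <- treat[top] == 1
  if (!any(t_top) || all(t_top)) return(NA_real_)
  mean(-y[top][t_top]) - mean(-y[top][!t_top])
}

#' Cumulative gain curve over population quantiles
#'
#' At each fraction k/n_quantiles the cumulative gain is the uplift within the
#' top fraction multiplied by the number of members covered:
#' `gain(f) = uplift(f) * f * n`.  The curve is prepended with (0, 0).
#' Quantiles whose top subset lacks a cohort have undefined uplift; they are
#' recorded (`n_undefined`) and skipped, which linearly interpolates across
#' them when the curve is integrated.
#'
#' @inheritParams uplift_at_fraction
#' @param n_quantiles Number of quantiles (default 10, i.e. deciles).
#' @return Object of class `uplift_curve`: `fractions`, `gains`, `n`,
#'   `n_undefined`, and `auuc` (the normalized area from [auuc()], `NA` when
#'   the total gain is zero).
#' @export
cumulative_gain_curve <- function(scores, treat, y, n_quantiles = 10) {
  .assert(n_quantiles >= 2, "n_quantiles must be >= 2", "rdmprec_config_error")
  n <- length(scores)
  fr <- seq_len(n_quantiles) / n_quantiles
  up <- vapply(fr, function(f) uplift_at_fraction(scores, treat, y, f),
               numeric(1))
  gains <- up * fr * n
  curve <- structure(
    list(fractions = c(0, fr), gains = c(0, gains), n = n,
         n_undefined = sum(is.na(up)), auuc = NA_real_),
    class = "uplift_curve")
  if (!is.na(gains[n_quantiles]) && gains[n_quantiles] != 0) {
    curve$auuc <- auuc(curve)
  }
  curve
}

#' Normalized area under the cumulative gain curve
#'
#' Trapezoidal area under the gain curve over fractions \[0, 1\], normalized
#' by the total gain (the gain at fraction 1).  Under this convention the
#' straight line from (0, 0) to (1, total gain) scores exactly 0.5 and a
#' random ranking has expected AUUC 0.5.
#' Undefined-uplift points are dropped before integration (linear
#' interpolation across them).
#'
#' @param curve An `uplift_curve` from [cumulative_gain_curve()].
#' @return Normalized AUUC (unitless); the unnormalized trapezoidal area is
#'   attached as attribute `"area"`.
#' @export
auuc <- function(curve) {
  .assert(inherits(curve, "uplift_curve"), "curve must be an uplift_curve",
          "rdmprec_config_error")
  ok <- !is.na(curve$gains)
  fr <- curve$fractions[ok]
  g <- curve$gains[ok]
  .assert(length(fr) >= 2, "curve needs at least two defined points",
          "rdmprec_config_error")
  total <- g[length(g)]
  .assert(total != 0,
          "total gain is zero; normalized AUUC is undefined",
          "rdmprec_normalization_error")
  area <- sum(diff(fr) * (utils::head(g, -1) + utils::tail(g, -1)) / 2)
  structure(area / total, area = area)
}

#' Random-ranking AUUC baseline
#'
#' Computes the normalized AUUC of `n_permutations` uniformly random rankings
#' of the same cohort; under the straight-line normalization its expectation
#' is 0.5.  Permutations with undefined AUUC (zero total gain cannot occur
#' here unless the cohort's overall uplift is zero) are dropped.
#'
#' @inheritParams cumulative_gain_curve
#' @param n_permutations Number of random rankings (default 200).
#' @param seed Integer seed.
#' @return List: `mean`, `sd`, `values` (per-permutation AUUC).
#' @export
random_auuc_baseline <- function(treat, y, n_quantiles = 10,
                                 n_permutations = 200, seed = 1L) {
  n <- length(treat)
  set.seed(seed)
  vals <- vapply(seq_len(n_permutations), function(i) {
    sc <- sample(n)
    cv <- cumulative_gain_curve(sc, treat, y, n_quantiles)
    cv$auuc
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  list(mean = mean(vals), sd = stats::sd(vals), values = vals)
}
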