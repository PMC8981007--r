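# Default end-to-end run configuration for rdmprec::read_run_config().
# Anything omitted falls back to the package defaults; this file spells out
# the main knobs in one place.
seed: 1
sim:
  n_members: 2000
  noise_sd: 0.3        # member-level outcome noise, eA1c percentage points
  bg_noise_sd: 25      # per-reading SMBG noise, mg/dL
  read_prob: 0.6       # daily probability of an SMBG reading
  months: 4
  dropout_frac: 0.04
  non_t2_frac: 0.03
  cgm_frac: 0.04
thresholds: box2        # standard engagement thresholds; replace with
                        # per-category grids to select by sweep, e.g.
                        # thresholds: { coaching: [1,2,3,4,5] }
model:
  split_ratio: 0.65     # 65:35 train/validation
  k_folds: 5            # nuisance cross-fitting folds
  clip: [0.01, 0.99]    # propensity clipping bounds
  min_cohort: 50
  mse_band: 0.10        # threshold-selection MSE band
eval:
  n_quantiles: 10       # deciles for the gain curve
  n_permutations: 200   # random-ranking baseline
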