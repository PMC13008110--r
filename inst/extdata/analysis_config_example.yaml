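# Annotated analysis configuration for dmconflict.
# Every section is optional; omitted keys take package defaults.

# Ground-truth / simulation parameters (dmc_parameters()).
parameters:
  drc: 0.5        # controlled drift, evidence units per ms
  amp: 20         # peak mean automatic activation, evidence units
  tau: 30         # automatic time scale, ms (peak at (aa_shape-1)*tau)
  aa_shape: 2     # gamma shape of the automatic pulse
  sigma: 4        # diffusion constant per sqrt(ms)
  bnds: 75        # boundary magnitude; responses at +/- bnds
  strp: 0         # relative start point, 0 = midway
  res: 300        # non-decision time, ms

# Forward-simulation settings (simulation_config()).
simulation:
  dt: 1           # integration step, ms
  max_time: 4000  # decision-time horizon, ms
  n_trials: 50000
  seed: 1
  crossing: bridge  # bridge | step

# Data-cleaning rules (preprocess_rules()).
rules:
  fast_threshold: 300      # remove trials with rt strictly below this, ms
  chance: 0.5              # chance level for the block binomial test
  alpha: 0.05
  binomial_mode: below     # below | not-above
  iqr_target: subject_condition_means  # or trial_rt
  exclude_subjects: []     # manual whole-subject exclusions

# Fitting settings (fit_config()); sigma, aa_shape, strp stay fixed.
fit:
  n_sim: 50000    # simulated trials per congruency per evaluation
  dt: 1
  max_time: 4000
  epsilon: ~      # predicted-proportion floor; null = 1/(2*n_sim)
  cost_form: squared       # squared | signed (audit only)
  bounds:                  # free-parameter box bounds [lower, upper]
    amp: [0, 60]
    tau: [5, 300]
    drc: [0.05, 1.5]
    bnds: [20, 160]
    res: [100, 600]
  de:                      # differential-evolution settings
    np: 75                 # population size (15 x dimension)
    F: 0.8
    CR: 0.9
    tol: 1.0e-6
    max_gen: 200

# End-to-end run (pipeline_config()); input is a trial-table path.
# pipeline:
#   task: navon
#   input: trials.tsv
#   out_dir: results/navon_run
#   seed: 1
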