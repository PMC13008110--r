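# dmconflict

Simulation, fitting and recovery analysis for the **diffusion model of
conflict (DMC)** — the evidence-accumulation model of two-choice conflict
tasks in which a controlled, task-relevant diffusion process with constant
drift is superimposed with an automatic, task-irrelevant process whose mean
state follows a scaled gamma pulse:

    dX_t = [mu_r + mu_i(t)] dt + sigma dW_t,
    E[X_a(t)] = A exp(-t/tau) * (t e / ((a-1) tau))^(a-1),

with `mu_i(t)` the time derivative of `E[X_a(t)]`. The pulse peaks at `A`
at time `(a-1) tau` and decays, so irrelevant information helps (congruent)
or hurts (incongruent) early and is compensated late — producing congruency
effects that shrink across the RT distribution (negative-going delta
functions). The package is written for researchers analyzing conflict
paradigms such as hierarchical (Navon) letters and composite faces.

It provides:

* a fast, bit-reproducible first-passage simulator of the DMC
  (`simulate_trials()`, Rcpp core) with closed-form oracles for the
  constant-drift limit;
* the quantile-binned chi-squared estimator: adaptive RT-quantile binning,
  simulation-based predicted proportions and differential-evolution search
  with the conventional parameter fixes (`fit_condition()`, `fit_study()`);
* the standard cleaning rules for these tasks — fast-trial cutoff,
  binomial sub-chance block exclusion, Tukey-fence screening — with exact
  exclusion reports (`preprocess_dataset()`);
* delta-function analysis and observed-vs-predicted diagnostics
  (`delta_function()`, `plot_observed_predicted()`);
* study-shaped synthetic data generators with ground-truth ledgers for
  parameter-recovery experiments (`navon_design()`, `composite_design()`,
  `generate_dataset()`, `make_paper_like_spec()`), and a one-call pipeline
  (`run_full_analysis()`).

## Worked example

Simulate both congruency conditions at the documentation's reference
parameterisation (`amp = 20`, `tau = 30`, `aa_shape = 2`, `drc = 0.5`,
`sigma = 4`, `bnds = 75`, `strp = 0`, `res = 300`) and inspect the
congruency effect:

```r
library(dmconflict)

p  <- dmc_parameters()          # reference parameter set above
cc <- simulate_trials(p, "congruent",
                      simulation_config(n_trials = 50000, seed = 3))
ii <- simulate_trials(p, "incongruent",
                      simulation_config(n_trials = 50000, seed = 4))

round(c(acc_congruent   = mean(cc$accuracy, na.rm = TRUE),
        acc_incongruent = mean(ii$accuracy, na.rm = TRUE),
        rt_congruent    = mean(cc$rt, na.rm = TRUE),
        rt_incongruent  = mean(ii$rt, na.rm = TRUE)), 3)
#>   acc_congruent acc_incongruent    rt_congruent  rt_incongruent
#>           0.993           0.982         430.371         456.198

delta_function(cc, ii)
#>   prob quantile_congruent quantile_incongruent mean_rt delta
#> 1  0.1                336                  374   355.0    38
#> 2  0.3                364                  404   384.0    40
#> 3  0.5                403                  434   418.5    31
#> 4  0.7                457                  477   467.0    20
#> 5  0.9                560                  571   565.5    11
```

Congruent trials are faster and more accurate, and the quantile
differences *fall* from ~38 ms early to ~10 ms late: the negative-going
delta function that distinguishes the DMC from models with sustained
interference. The mean automatic activation itself peaks at
`(aa_shape - 1) * tau` = 30 ms with value `amp` = 20:

```r
unlist(activation_peak(p, grid = TRUE))
#>  time value
#>    30    20
```

Fitting recovers the generating parameters from trial data (here at a
reduced search profile; defaults are fidelity-scale):

```r
trials <- rbind(cc[1:2000, ], ii[1:2000, ])
fit <- fit_condition(trials,
                     fit_config(n_sim = 5000, max_time = 1200,
                                de = list(np = 50, max_gen = 60)),
                     seed = 101)
round(unlist(fit$par[c("amp", "tau", "drc", "bnds", "res")]), 2)
#>    amp    tau    drc   bnds    res
#>  19.60  32.59   0.50  76.87 297.90
```

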