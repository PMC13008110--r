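---
title: "Modeling conflict tasks with the diffusion model of conflict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling conflict tasks with the diffusion model of conflict}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmconflict)
```

## The model

Two-choice conflict tasks — hierarchical (Navon) letters, composite faces,
flanker, Simon — confront a task-relevant stimulus dimension with a
task-irrelevant one. The diffusion model of conflict (DMC) explains the
resulting congruency effects by superimposing two evidence streams in one
accumulator:

$$dX_t = \left[\mu_r + \mu_i(t)\right]dt + \sigma\,dW_t,$$

where $\mu_r$ (`drc`) is the constant drift of the controlled, task-relevant
process, $\sigma$ the diffusion constant, and $\mu_i(t)$ the time-varying
drift of the automatic, task-irrelevant process. The automatic process's
*mean state* follows a scaled gamma pulse

$$E[X_a(t)] = A\,e^{-t/\tau}\left(\frac{te}{(a-1)\tau}\right)^{a-1},$$

which is zero at $t = 0$, peaks at exactly $A$ (`amp`) at $t = (a-1)\tau$,
and decays back to baseline; $\mu_i(t)$ is its time derivative, so early
automatic evidence is compensated later in the trial. On congruent trials
$\mu_i(t)$ pushes toward the correct boundary, on incongruent trials away
from it (the sign of $\mu_i$ is the *only* place congruency enters). The
response is given when $X_t$ first reaches $\pm$`bnds`; under accuracy
coding the upper boundary is the correct response and the start point
`strp` = 0 lies midway. Observed RT is the first-passage time plus a
constant non-decision time `res`.

Because the automatic pulse decays, the congruency effect is concentrated
in fast responses: plotting the incongruent-minus-congruent RT quantile
differences against the quantile means (a *delta function*) yields a
negative-going curve — the model's behavioral signature, which
`delta_function()` computes and criterion tests verify on simulated data.

## Parameters and defaults

| parameter  | meaning                                  | units            | default |
|------------|------------------------------------------|------------------|---------|
| `drc`      | controlled drift                         | evidence / ms    | 0.5     |
| `amp`      | peak mean automatic activation           | evidence         | 20      |
| `tau`      | automatic time scale (peak at $(a-1)\tau$) | ms             | 30      |
| `aa_shape` | gamma shape $a$                          | —                | 2       |
| `sigma`    | diffusion constant                       | evidence / √ms   | 4       |
| `bnds`     | boundary magnitude                       | evidence         | 75      |
| `strp`     | relative start point                     | —                | 0       |
| `res`      | non-decision time                        | ms               | 300     |

The defaults are the worked-example parameterisation used throughout the
documentation and tests. When fitting, `sigma` (the model's scaling
parameter), `aa_shape` (fixing the gamma shape at 2 improves recovery of
the remaining parameters) and `strp` are held fixed; `amp`, `tau`, `drc`,
`bnds`, `res` are free within bounds spanning the plausible range for
conflict tasks on a 1 ms time base (`amp` 0–60, `tau` 5–300 ms, `drc`
0.05–1.5/ms, `bnds` 20–160, `res` 100–600 ms), all overridable in
`fit_config()`.

## Simulation and numerical choices

`simulate_trials()` integrates the SDE by Euler–Maruyama with Gaussian
increments of variance $\sigma^2 dt$ at `dt` = 1 ms by default, the model's
native fitting resolution. Two numerical choices deserve note:

* **Boundary crossing.** Checking $|X| \ge$ `bnds` only at step ends
  misses within-step excursions and biases first-passage times upward by
  $O(\sigma\sqrt{dt})$ (about +1.9 ms in mean decision time at `dt` = 0.1
  with the default parameters — larger than the Monte-Carlo error of a
  100,000-trial validation run). The default crossing mode therefore adds a
  Brownian-bridge test: given the step endpoints, the continuous path
  crossed a boundary within the step with probability
  $\exp(-2 g_0 g_1 / \sigma^2 dt)$ (gaps $g_0, g_1$ to that boundary), and
  absorbed trials are still reported on the step grid. `crossing = "step"`
  restores the plain Euler check for comparison with pipelines that use
  it. With the bridge test the simulator matches the closed-form Wiener
  absorption probability and mean first-passage time (the `amp = 0`
  oracles `analytic_ddm_accuracy()` / `analytic_ddm_mean_dt()`) within
  Monte-Carlo error.
* **Time grid.** Drift is evaluated at step starts; the `t = 0` automatic
  drift uses the analytic right-limit ($A e/\tau$ for $a = 2$). Trials not
  absorbed by `max_time` (default 4000 ms, a typical response window) are
  flagged non-terminated and excluded from binning — the model does not
  describe omissions.

Random numbers come from a package-internal xoshiro256++ generator with
ziggurat normal deviates, seeded per call: trial streams are reproducible
bit-for-bit from an integer seed regardless of the R session's RNG state,
and fast enough for the simulation-based objective below. The generator is
validated against the standard normal in the test suite.

## Fitting

The estimator is the quantile-binned chi-squared method. For each
congruency condition, observed correct and error RTs are binned at
adaptive quantiles chosen by subset size — $(.1,.3,.5,.7,.9)$ for $n \ge
30$, $(.3,.5,.9)$ for 15–29, $(.5)$ for 6–14, a single bin below 6 —
with edges at observed order statistics (type-7 interpolation; the
estimator is fixed and documented for reproducibility). Proportions are
normalised over the whole condition, so error-bin proportions carry the
error rate. Predictions come from simulating `n_sim` trials (50,000 at
fidelity scale) at the candidate parameters and dropping simulated RTs
into the *observed* edges; each predicted proportion is floored at
$\varepsilon = 1/(2\,n_{sim})$ and renormalised so empty predicted bins
cannot divide the cost. The cost is

$$\chi^2 = \sum_{i=1}^{2} N_i \sum_{j=1}^{m}
  \frac{(p_{ij} - \pi_{ij})^2}{\pi_{ij}},$$

summed over the two congruency conditions fitted jointly within a design
cell. (A signed variant without the square, `cost_form = "signed"`, is
kept for audit; it is not a chi-squared statistic and is not recommended.)

Minimisation uses differential evolution (best/1/bin, $F = 0.8$,
$CR = 0.9$, population $15 \times$ dimension, up to 200 generations,
relative cost tolerance $10^{-6}$) — a global, derivative-free search
suited to a noisy simulation-based objective. One simulation seed per
congruency is drawn per fit and reused for every candidate (common random
numbers), which makes the objective deterministic for the optimizer and
the entire fit reproducible from its seed. Candidates for which no
simulated trial terminates receive infinite cost.

`fit_study()` applies `fit_condition()` to every design cell — subject ×
session × time × level for the hierarchical design, subject × session ×
alignment for the composite design — fitting congruency pairs jointly
within the cell and fitting each cell fully independently (no parameter
sharing across sessions), per the reading that each condition is fitted
individually. Cells emptied by preprocessing are reported, never silently
dropped.

## Preprocessing

`preprocess_dataset()` composes the conventional cleaning rules for these
tasks, in order:

1. manual subject exclusions from the rule set (judgment-based whole-subject
   removal is deliberately not automated);
2. removal of trials with RT strictly below 300 ms (fast guesses);
3. removal of blocks whose accuracy is significantly *below* chance by an
   exact one-sided binomial test at $\alpha = .05$ — the literal reading of
   "below chance" is the default, with a stricter "not significantly above
   chance" mode exposed because the direction of such screens is often
   ambiguous in method descriptions;
4. Tukey-fence screening ($[Q_1 - 1.5\,IQR,\ Q_3 + 1.5\,IQR]$, type-7
   quartiles, strict exceedance) of per-subject condition mean RT and mean
   accuracy across subjects — the variable such screens most plausibly
   target before condition-level analyses; a per-trial RT mode is exposed
   for sensitivity checks.

The exclusion report records counts at each stage and exact removed
fractions.

## Synthetic study designs

`navon_design()` (3 sessions × pre/post × 4 blocks of 48 trials, two
blocks per attentional level, each block split 24/24 between congruencies)
and `composite_design()` (3 sessions × 160 trials in 4 blocks, 10 per
congruency × alignment condition per block) reproduce the canonical trial
arithmetic of the two paradigms. `generate_dataset()` simulates every cell
from ground-truth parameters with optional between-subject jitter
(lognormal with 10% spread on positive parameters, normal on `res` — a
declared synthetic convention, not an inference from data), plus
contamination: fast guesses (uniform RT 100–299 ms, accuracy at chance)
and lapses (uniform RT over the response window, accuracy at chance). The
ledger labels every trial's origin, so preprocessing can be scored against
ground truth exactly.

`make_paper_like_spec()` encodes the qualitative effect structure reported
for these paradigms — stronger automatic activation, higher boundaries and
longer non-decision time in local than global cells; stronger automatic
activation in aligned than misaligned composite-face cells with longer
non-decision time when misaligned — anchored at the worked-example
parameter set. Effect magnitudes are caller-configurable and a null
configuration shares one parameter vector across cells.

What the generator does *not* emulate: sequential effects, practice and
fatigue drifts, RT-dependent lapse structure, response-alternative
asymmetries, or any stimulation-site effect (session labels carry no
effect by default). Passing recovery tests on this generator therefore
demonstrates that the estimation machinery works when the model is true;
it does not certify the model against real data's misspecifications.

## Problem sizes and test profiles

Fidelity-scale settings (1 ms steps, 50,000 simulated trials per
condition, population 75, 200 generations) are the package defaults. The
test suite and recovery harness run a desk-scale profile chosen as the
smallest at which recovery remains informative: 5,000 simulated trials,
population 50, 60 generations and a 1200 ms decision horizon for the
single-cell recovery study (2,000 trials per congruency, 10 seeds, median
recovered parameters within 15% relative error, `res` within 20 ms);
2,000 simulated trials with the same search settings for the study-shaped
contrast-recovery harness (500 trials per congruency per cell, 10
replicate studies, sign of each injected contrast recovered in at least
8 of 10). Parameter correlations (notably `amp`–`tau`) make single
fits noisier than the medians reported by the harness; at fidelity scale
the bounds tighten accordingly.

## Known limitations

* No closed-form likelihood: estimation is simulation-based throughout,
  and fitted values inherit Monte-Carlo noise of order the binomial error
  at `n_sim`.
* `res` is a constant; RT variability attributable to non-decision
  processes is absorbed by the diffusion parameters.
* Alternative conflict architectures (dual-stage two-phase, shrinking
  spotlight) are out of scope; no model comparison is provided.
* The inferential layer stops at descriptive contrasts with bootstrap
  intervals (`summarize_parameters()`); ANOVA-style inference on fitted
  parameters is intentionally left to general-purpose tools.
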