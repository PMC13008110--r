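# Shared fixtures: the worked-example parameterisation and small builders
# used across test files. Everything is generated in code at test time.

fig3_params <- function(...) {
  args <- utils::modifyList(
    list(drc = 0.5, amp = 20, tau = 30, aa_shape = 2, sigma = 4,
         bnds = 75, strp = 0, res = 300), list(...))
  do.call(dmc_parameters, args)
}

# paired congruent/incongruent sample from one parameter set
simulate_condition_pair <- function(p, n = 2000, seed = 1, dt = 1,
                                    max_time = 4000) {
  rbind(
    simulate_trials(p, "congruent",
                    simulation_config(dt = dt, max_time = max_time,
                                      n_trials = n, seed = seed)),
    simulate_trials(p, "incongruent",
                    simulation_config(dt = dt, max_time = max_time,
                                      n_trials = n, seed = seed + 131071)))
}

# minimal well-formed raw trial table for preprocessing tests
make_raw_trials <- function(rt, accuracy, block = 1L, subject = "S01",
                            session = "CZ", task = "navon",
                            level = if (task == "navon") "global"
                                    else "aligned",
                            congruency = "congruent",
                            time = if (task == "navon") "pre" else NULL) {
  n <- length(rt)
  tab <- data.frame(subject = subject, session = session, task = task,
                    block = block,
                    level_or_alignment = level, congruency = congruency,
                    rt = rt, accuracy = rep_len(accuracy, n),
                    stringsAsFactors = FALSE)
  if (!is.null(time)) tab$time <- time
  tab
}

# reduced-scale fitting profile used throughout the test suite; problem
# sizes chosen as the smallest at which recovery behaviour is still
# informative
test_fit_config <- function(n_sim = 2000, max_gen = 40, np = 40,
                            max_time = 2000, ...) {
  fit_config(n_sim = n_sim, max_time = max_time,
             de = list(np = np, max_gen = max_gen), ...)
}
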