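#' Hierarchical-letters (Navon) task design
#'
#' Per subject and stimulation session (`LPPC`, `RPPC`, `CZ`) and time
#' (`pre`, `post`): 4 blocks of 48 trials, two blocks per attentional level
#' (global / local), each block evenly split into 24 congruent and 24
#' incongruent trials — 192 trials per administration, 1152 per subject
#' across the 3 sessions x 2 times.
#'
#' @return A `dmc_task_design`: task name, factor sets and a per-cell trial
#'   count table (one row per session x time x block x level x congruency).
#' @export
navon_design <- function() {
  cells <- expand.grid(session = c("LPPC", "RPPC", "CZ"),
                       time = c("pre", "post"),
                       block = 1:4,
                       congruency = c("congruent", "incongruent"),
                       stringsAsFactors = FALSE)
  cells$level_or_alignment <- ifelse(cells$block <= 2, "global", "local")
  cells$n_trials <- 24L
  structure(list(task = "navon",
                 factors = navon_levels,
                 cells = cells[order(cells$session, cells$time, cells$block,
                                     cells$congruency), ]),
            class = "dmc_task_design")
}

#' Composite-face task design
#'
#' Per subject and stimulation session: 160 trials in 4 blocks, each block
#' holding 10 trials of each of the four conditions (congruency x
#' alignment) — 40 trials per condition cell per session.
#'
#' @return A `dmc_task_design` (see [navon_design()]).
#' @export
composite_design <- function() {
  cells <- expand.grid(session = c("LPPC", "RPPC", "CZ"),
                       block = 1:4,
                       level_or_alignment = c("aligned", "misaligned"),
                       congruency = c("congruent", "incongruent"),
                       stringsAsFactors = FALSE)
  cells$n_trials <- 10L
  structure(list(task = "composite",
                 factors = composite_levels,
                 cells = cells[order(cells$session, cells$block,
                                     cells$level_or_alignment,
                                     cells$congruency), ]),
            class = "dmc_task_design")
}

#' @export
print.dmc_task_design <- function(x, ...) {
  cat(sprintf("Task design '%s': %d cells, %d trials per subject\n",
              x$task, nrow(x$cells), sum(x$cells$n_trials)))
  invisible(x)
}

#' Restrict a task design to selected factor levels
#'
#' Convenience for reduced-scale runs: keeps only the design cells matching
#' the requested sessions / times / blocks, preserving within-cell trial
#' counts.
#'
#' @param design A `dmc_task_design`.
#' @param sessions,times,blocks Optional level subsets; `NULL` keeps all.
#' @return The restricted `dmc_task_design`.
#' @export
subset_design <- function(design, sessions = NULL, times = NULL,
                          blocks = NULL) {
  stopifnot(inherits(design, "dmc_task_design"))
  cells <- design$cells
  if (!is.null(sessions)) cells <- cells[cells$session %in% sessions, ]
  if (!is.null(times) && "time" %in% names(cells))
    cells <- cells[cells$time %in% times, ]
  if (!is.null(blocks)) cells <- cells[cells$block %in% blocks, ]
  if (!nrow(cells)) stop("subset leaves no design cells")
  design$cells <- cells
  design
}

#' Ground-truth generator specification
#'
#' Pairs a task design with true DMC parameters per design cell, a subject
#' count, between-subject parameter jitter, and contamination rates. The
#' generator is declared synthetic structure standing in for unreleased raw
#' behavioral data: the study itself has no subject-level parameter model.
#'
#' @param design A `dmc_task_design`.
#' @param cell_params Named list mapping parameter-cell labels (e.g.
#'   `"global"`, `"local"`, `"aligned"`, `"misaligned"`) to
#'   [dmc_parameters()] objects; the label is matched against the design's
#'   `level_or_alignment` factor.
#' @param n_subjects Number of simulated subjects.
#' @param jitter_sd Relative between-subject spread: lognormal multiplicative
#'   jitter with this log-sd on positive parameters (`drc, amp, tau, bnds`)
#'   and normal additive jitter of `jitter_sd * res` on `res`. 0 disables
#'   jitter.
#' @param p_fast Per-trial probability of a fast guess (uniform RT on
#'   100-299 ms, accuracy at chance).
#' @param p_lapse Per-trial probability of a lapse (uniform RT over the
#'   response window, accuracy at chance).
#' @param response_window Upper RT limit (ms) for lapse responses.
#' @param trials_scale Multiplier applied to every design cell's trial count
#'   (rounded); >1 inflates cells for recovery studies, <1 thins them.
#' @param seed Master seed; byte-identical output for identical seeds.
#' @return A list of class `dmc_generator_spec`.
#' @export
generator_spec <- function(design, cell_params, n_subjects = 6,
                           jitter_sd = 0.1, p_fast = 0, p_lapse = 0,
                           response_window = 4000, trials_scale = 1,
                           seed = 1) {
  stopifnot(inherits(design, "dmc_task_design"))
  if (p_fast < 0 || p_fast > 1 || p_lapse < 0 || p_lapse > 1)
    stop("contamination rates must lie in [0, 1]")
  if (p_fast + p_lapse > 1) stop("p_fast + p_lapse must not exceed 1")
  need <- unique(design$cells$level_or_alignment)
  miss <- setdiff(need, names(cell_params))
  if (length(miss))
    stop("cell_params lacks entries for: ", paste(miss, collapse = ", "))
  for (cp in cell_params) stopifnot(inherits(cp, "dmc_parameters"))
  if (trials_scale <= 0) stop("trials_scale must be positive")
  design$cells$n_trials <-
    pmax(1L, as.integer(round(design$cells$n_trials * trials_scale)))
  structure(list(design = design, cell_params = cell_params,
                 n_subjects = as.integer(n_subjects),
                 jitter_sd = jitter_sd, p_fast = p_fast, p_lapse = p_lapse,
                 response_window = response_window, seed = seed),
            class = "dmc_generator_spec")
}

jitter_params <- function(p, jitter_sd) {
  if (jitter_sd <= 0) return(p)
  mult <- function(v) v * exp(stats::rnorm(1, 0, jitter_sd))
  dmc_parameters(drc = mult(p$drc),
                 amp = if (p$amp > 0) mult(p$amp) else 0,
                 tau = mult(p$tau), aa_shape = p$aa_shape,
                 sigma = p$sigma, bnds = mult(p$bnds), strp = p$strp,
                 res = max(0, p$res + stats::rnorm(1, 0, jitter_sd * p$res)))
}

#' Generate a study-shaped synthetic dataset
#'
#' For each subject: jitter the cell parameters, simulate every design cell
#' with the DMC forward model, replace a random subset of trials with
#' contaminants (fast guesses and lapses, accuracy at chance), and shuffle
#' trial order within blocks. A ledger records each trial's ground-truth
#' origin (`model`, `fast_guess`, `lapse`) and each subject-cell's true
#' parameters, so preprocessing and recovery can be scored exactly.
#'
#' @param spec A [generator_spec()].
#' @return A list with `trials` (raw trial table: subject, session, task,
#'   block, level_or_alignment, congruency, and for hierarchical designs
#'   time, plus rt, accuracy), `ledger` (per-trial origin), and
#'   `true_params` (per subject x parameter-cell true parameter table).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "dmc_generator_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  design <- spec$design
  has_time <- "time" %in% names(design$cells)
  out <- list(); ledger <- list(); true_rows <- list()
  for (s in seq_len(spec$n_subjects)) {
    subj <- sprintf("S%02d", s)
    subj_params <- lapply(spec$cell_params, jitter_params, spec$jitter_sd)
    for (lab in names(subj_params)) {
      pr <- subj_params[[lab]]
      true_rows[[paste(subj, lab)]] <- data.frame(
        subject = subj, param_cell = lab,
        as.data.frame(unclass(pr)))
    }
    for (r in seq_len(nrow(design$cells))) {
      cell <- design$cells[r, ]
      p <- subj_params[[cell$level_or_alignment]]
      sim_seed <- sample.int(2147483647L, 1)
      sim <- simulate_trials(p, cell$congruency,
                             simulation_config(dt = 1,
                                               max_time = spec$response_window,
                                               n_trials = cell$n_trials,
                                               seed = sim_seed))
      n <- nrow(sim)
      u <- stats::runif(n)
      origin <- ifelse(u < spec$p_fast, "fast_guess",
                       ifelse(u < spec$p_fast + spec$p_lapse, "lapse",
                              "model"))
      # non-terminated model trials respond at the window edge, at chance
      open <- origin == "model" & !sim$terminated
      origin[open] <- "lapse"
      rt <- sim$rt
      acc <- sim$accuracy
      fg <- origin == "fast_guess"
      lp <- origin == "lapse"
      rt[fg] <- stats::runif(sum(fg), 100, 299)
      acc[fg] <- stats::rbinom(sum(fg), 1, 0.5)
      rt[lp] <- stats::runif(sum(lp), 300, spec$response_window)
      acc[lp] <- stats::rbinom(sum(lp), 1, 0.5)
      tab <- data.frame(subject = subj, session = cell$session,
                        task = design$task, block = cell$block,
                        level_or_alignment = cell$level_or_alignment,
                        congruency = cell$congruency,
                        rt = rt, accuracy = acc,
                        stringsAsFactors = FALSE)
      if (has_time) tab$time <- cell$time
      out[[length(out) + 1L]] <- tab
      ledger[[length(ledger) + 1L]] <-
        data.frame(subject = subj, session = cell$session,
                   block = cell$block, congruency = cell$congruency,
                   level_or_alignment = cell$level_or_alignment,
                   origin = origin, stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, out)
  ledger <- do.call(rbind, ledger)
  # shuffle within blocks (same permutation applied to trials and ledger)
  blk <- interaction(trials$subject, trials$session,
                     if (has_time) trials$time else "", trials$block,
                     drop = TRUE)
  perm <- unlist(lapply(split(seq_len(nrow(trials)), blk),
                        function(ix) ix[sample.int(length(ix))]),
                 use.names = FALSE)
  trials <- trials[perm, , drop = FALSE]
  ledger <- ledger[perm, , drop = FALSE]
  rownames(trials) <- rownames(ledger) <- NULL
  list(trials = trials, ledger = ledger,
       true_params = do.call(rbind, c(true_rows,
                                      list(make.row.names = FALSE))))
}

#' Study-shaped generator spec with the canonical effect structure
#'
#' Builds a [generator_spec()] whose between-cell contrasts mirror the
#' qualitative effect pattern such studies report: for the hierarchical
#' task, stronger automatic activation (`amp`), higher boundaries, longer
#' non-decision time and slower activation peak in local than global cells;
#' for the composite task, stronger `amp` and higher boundaries in aligned
#' than misaligned cells and longer non-decision time when misaligned. The
#' anchor cell (global / aligned, congruent) uses the worked-example
#' parameterisation `amp = 20, tau = 30, drc = 0.5, bnds = 75` with
#' `res = 300`.
#'
#' @param task `"navon"` or `"composite"`.
#' @param effects Named list of effect magnitudes overriding the defaults:
#'   for `"navon"` `amp_local_minus_global` (default 15),
#'   `bnds_local_minus_global` (10), `res_local_minus_global` (30),
#'   `tau_local_minus_global` (15); for `"composite"`
#'   `amp_aligned`, `amp_misaligned` (12, 3), `bnds_aligned_minus_misaligned`
#'   (4), `res_misaligned_minus_aligned` (30). Set all to 0 (or use
#'   `null_effects = TRUE`) for a single shared parameter vector.
#' @param null_effects If `TRUE`, all cells share the anchor parameters.
#' @param ... Passed on to [generator_spec()] (`n_subjects`, `jitter_sd`,
#'   contamination rates, `seed`).
#' @return A `dmc_generator_spec`.
#' @export
make_paper_like_spec <- function(task = c("navon", "composite"),
                                 effects = list(), null_effects = FALSE,
                                 ...) {
  task <- match.arg(task)
  anchor <- dmc_parameters(drc = 0.5, amp = 20, tau = 30, aa_shape = 2,
                           sigma = 4, bnds = 75, strp = 0, res = 300)
  if (task == "navon") {
    eff <- utils::modifyList(list(amp_local_minus_global = 15,
                                  bnds_local_minus_global = 10,
                                  res_local_minus_global = 30,
                                  tau_local_minus_global = 15), effects)
    if (null_effects) eff <- lapply(eff, function(x) 0)
    local <- dmc_parameters(drc = anchor$drc,
                            amp = anchor$amp + eff$amp_local_minus_global,
                            tau = anchor$tau + eff$tau_local_minus_global,
                            aa_shape = 2, sigma = 4,
                            bnds = anchor$bnds + eff$bnds_local_minus_global,
                            strp = 0,
                            res = anchor$res + eff$res_local_minus_global)
    generator_spec(navon_design(),
                   list(global = anchor, local = local), ...)
  } else {
    eff <- utils::modifyList(list(amp_aligned = 12, amp_misaligned = 3,
                                  bnds_aligned_minus_misaligned = 4,
                                  res_misaligned_minus_aligned = 30),
                             effects)
    aligned <- dmc_parameters(drc = anchor$drc, amp = eff$amp_aligned,
                              tau = anchor$tau, aa_shape = 2, sigma = 4,
                              bnds = anchor$bnds, strp = 0,
                              res = anchor$res)
    misaligned <- dmc_parameters(
      drc = anchor$drc,
      amp = if (null_effects) eff$amp_aligned else eff$amp_misaligned,
      tau = anchor$tau, aa_shape = 2, sigma = 4,
      bnds = anchor$bnds -
        (if (null_effects) 0 else eff$bnds_aligned_minus_misaligned),
      strp = 0,
      res = anchor$res +
        (if (null_effects) 0 else eff$res_misaligned_minus_aligned))
    generator_spec(composite_design(),
                   list(aligned = aligned, misaligned = misaligned), ...)
  }
}
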