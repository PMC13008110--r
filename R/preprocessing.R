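#' Remove implausibly fast trials
#'
#' Drops trials with response times strictly below a threshold (default
#' 300 ms, the conventional fast-guess cutoff for these tasks); a trial at
#' exactly the threshold is kept.
#'
#' @param trials Data.frame with at least an `rt` column (ms).
#' @param threshold Cutoff in ms; must be positive.
#' @return A list with `kept` and `removed` data.frames.
#' @export
exclude_fast_trials <- function(trials, threshold = 300) {
  stopifnot(is.data.frame(trials), "rt" %in% names(trials), threshold > 0)
  fast <- trials$rt < threshold
  list(kept = trials[!fast, , drop = FALSE],
       removed = trials[fast, , drop = FALSE])
}

#' Remove blocks whose accuracy is below chance
#'
#' Applies an exact binomial test to each block's correct count against
#' chance-level responding. Under the default mode `"below"` a block is
#' removed when its accuracy is significantly *below* chance (one-sided
#' `p < alpha`); mode `"not-above"` instead removes every block that is not
#' significantly above chance — a stricter screen exposed for sensitivity
#' analyses.
#'
#' @param trials Data.frame with an `accuracy` (0/1) column and the columns
#'   named in `block_by` identifying blocks.
#' @param chance Chance success probability, in (0, 1).
#' @param alpha Significance level of the test.
#' @param mode `"below"` (default) or `"not-above"`.
#' @param block_by Character vector of columns whose combination defines a
#'   block; defaults to the identifying columns present in `trials`.
#' @return A list with `kept` (data.frame), `removed_blocks` (data.frame of
#'   block keys with n, correct count and p-value), and `removed`
#'   (the removed trials).
#' @export
exclude_subchance_blocks <- function(trials, chance = 0.5, alpha = 0.05,
                                     mode = c("below", "not-above"),
                                     block_by = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(trials), "accuracy" %in% names(trials),
            chance > 0, chance < 1)
  if (is.null(block_by))
    block_by <- intersect(c("subject", "session", "time", "task", "block"),
                          names(trials))
  if (!length(block_by) || !all(block_by %in% names(trials)))
    stop("block_by columns not found in trials")
  if (nrow(trials) == 0L) stop("no trials supplied")
  key <- interaction(trials[block_by], drop = TRUE, lex.order = TRUE)
  stats_by_block <- lapply(split(seq_len(nrow(trials)), key), function(idx) {
    n <- length(idx)
    k <- sum(trials$accuracy[idx])
    pv <- if (mode == "below")
      stats::binom.test(k, n, chance, alternative = "less")$p.value
    else
      stats::binom.test(k, n, chance, alternative = "greater")$p.value
    c(n = n, correct = k, p = pv)
  })
  tab <- do.call(rbind, stats_by_block)
  drop_block <- if (mode == "below") tab[, "p"] < alpha else tab[, "p"] >= alpha
  bad_keys <- rownames(tab)[drop_block]
  in_bad <- as.character(key) %in% bad_keys
  removed_blocks <- data.frame(block_key = bad_keys,
                               n = tab[drop_block, "n"],
                               n_correct = tab[drop_block, "correct"],
                               p_value = tab[drop_block, "p"],
                               row.names = NULL)
  list(kept = trials[!in_bad, , drop = FALSE],
       removed_blocks = removed_blocks,
       removed = trials[in_bad, , drop = FALSE])
}

#' Tukey-fence outlier flags
#'
#' Flags values strictly outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, with
#' quartiles computed by linear interpolation of order statistics
#' (`type = 7`). With fewer than 4 values the fences are not identifiable
#' and nothing is flagged (with a warning).
#'
#' @param values Numeric vector of summary statistics (e.g. per-subject
#'   condition means).
#' @param k Fence multiplier (1.5 is the conventional value).
#' @return Logical vector, `TRUE` where a value is an outlier.
#' @export
iqr_outlier_filter <- function(values, k = 1.5) {
  stopifnot(is.numeric(values))
  if (length(values) < 4L) {
    warning("fewer than 4 values: IQR fences not computed, nothing flagged")
    return(rep(FALSE, length(values)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7,
                       na.rm = TRUE)
  iqr <- q[2] - q[1]
  values < q[1] - k * iqr | values > q[2] + k * iqr
}

#' Preprocessing rule set
#'
#' @param fast_threshold Fast-guess cutoff in ms.
#' @param chance Chance level for the block test.
#' @param alpha Significance level for the block test.
#' @param binomial_mode `"below"` or `"not-above"` (see
#'   [exclude_subchance_blocks()]).
#' @param iqr_target `"subject_condition_means"` (default: screen per-subject
#'   condition mean RT and mean accuracy across subjects) or `"trial_rt"`
#'   (screen raw RTs within each subject-condition cell).
#' @param exclude_subjects Manual list of subject ids to drop before any
#'   automatic rule.
#' @return A list of class `dmc_preprocess_rules`.
#' @export
preprocess_rules <- function(fast_threshold = 300, chance = 0.5,
                             alpha = 0.05,
                             binomial_mode = c("below", "not-above"),
                             iqr_target = c("subject_condition_means",
                                            "trial_rt"),
                             exclude_subjects = character()) {
  structure(list(fast_threshold = fast_threshold, chance = chance,
                 alpha = alpha, binomial_mode = match.arg(binomial_mode),
                 iqr_target = match.arg(iqr_target),
                 exclude_subjects = exclude_subjects),
            class = "dmc_preprocess_rules")
}

navon_levels <- list(session = c("LPPC", "RPPC", "CZ"),
                     time = c("pre", "post"),
                     level_or_alignment = c("global", "local"),
                     congruency = c("congruent", "incongruent"))
composite_levels <- list(session = c("LPPC", "RPPC", "CZ"),
                         level_or_alignment = c("aligned", "misaligned"),
                         congruency = c("congruent", "incongruent"))

#' Validate a raw trial table
#'
#' Checks the column contract for raw behavioral trial tables (`subject`,
#' `session`, `task`, `block`, `level_or_alignment`, `congruency`, `rt`,
#' `accuracy`, plus `time` for hierarchical designs) and that every factor
#' label belongs to its task's factor set; the first offending row is named
#' in the error.
#'
#' @param trials A data.frame of raw trials.
#' @return The table, invisibly, if valid.
#' @export
validate_raw_trials <- function(trials) {
  need <- c("subject", "session", "task", "block", "level_or_alignment",
            "congruency", "rt", "accuracy")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trial table lacks columns: ", paste(miss, collapse = ", "))
  if (any(trials$rt <= 0)) stop("rt must be positive for all trials")
  if (!all(trials$accuracy %in% c(0, 1)))
    stop("accuracy must be 0/1")
  bad_task <- !trials$task %in% c("navon", "composite")
  if (any(bad_task))
    stop("unknown task label in row ", which(bad_task)[1], ": ",
         trials$task[which(bad_task)[1]])
  for (tk in unique(trials$task)) {
    lv <- if (tk == "navon") navon_levels else composite_levels
    rows <- which(trials$task == tk)
    for (col in names(lv)) {
      if (col == "time" && !"time" %in% names(trials)) next
      bad <- rows[!trials[[col]][rows] %in% lv[[col]]]
      if (length(bad))
        stop("unknown ", col, " label in row ", bad[1], ": ",
             trials[[col]][bad[1]])
    }
  }
  invisible(trials)
}

#' Apply the full cleaning pipeline to a raw trial table
#'
#' Composes, in order: manual subject exclusion, fast-trial removal
#' (strictly below the threshold), sub-chance block exclusion (exact
#' binomial test per block), and Tukey-fence screening of per-subject
#' condition summaries (mean RT and mean accuracy per subject x task x
#' session x condition cell, screened across subjects; flagged cells are
#' removed). Deterministic and idempotent on clean data.
#'
#' @param trials A raw trial data.frame (see [validate_raw_trials()] fields).
#' @param rules A [preprocess_rules()] object.
#' @return A list with `trials` (clean data) and `report` (an
#'   `dmc_exclusion_report`: counts removed at each stage plus the overall
#'   fraction removed per task).
#' @export
preprocess_dataset <- function(trials, rules = preprocess_rules()) {
  stopifnot(inherits(rules, "dmc_preprocess_rules"))
  validate_raw_trials(trials)
  n_total <- nrow(trials)
  total_by_task <- list(navon = sum(trials$task == "navon"),
                        composite = sum(trials$task == "composite"))

  manual <- trials$subject %in% rules$exclude_subjects
  n_subjects_removed <- length(unique(trials$subject[manual]))
  trials <- trials[!manual, , drop = FALSE]

  fast <- exclude_fast_trials(trials, rules$fast_threshold)
  trials <- fast$kept

  blk <- exclude_subchance_blocks(trials, chance = rules$chance,
                                  alpha = rules$alpha,
                                  mode = rules$binomial_mode)
  trials <- blk$kept

  n_outlier_removed <- 0L
  if (nrow(trials)) {
    cond_cols <- intersect(c("task", "session", "time",
                             "level_or_alignment", "congruency"),
                           names(trials))
    if (rules$iqr_target == "subject_condition_means") {
      cell <- interaction(trials[c("subject", cond_cols)], drop = TRUE,
                          lex.order = TRUE)
      agg <- do.call(rbind, lapply(split(seq_len(nrow(trials)), cell),
        function(idx) c(rt = mean(trials$rt[idx]),
                        acc = mean(trials$accuracy[idx]))))
      cond_of_cell <- vapply(split(seq_len(nrow(trials)), cell), function(idx)
        paste(unlist(trials[idx[1], cond_cols]), collapse = "."), "")
      flagged_cells <- character()
      for (cond in unique(cond_of_cell)) {
        rows <- which(cond_of_cell == cond)
        if (length(rows) < 4L) next
        bad <- iqr_outlier_filter(agg[rows, "rt"]) |
          iqr_outlier_filter(agg[rows, "acc"])
        flagged_cells <- c(flagged_cells, rownames(agg)[rows][bad])
      }
      drop <- as.character(cell) %in% flagged_cells
    } else {
      cell <- interaction(trials[c("subject", cond_cols)], drop = TRUE,
                          lex.order = TRUE)
      drop <- unsplit(lapply(split(trials$rt, cell), function(v) {
        if (length(v) < 4L) rep(FALSE, length(v)) else iqr_outlier_filter(v)
      }), cell)
    }
    n_outlier_removed <- sum(drop)
    trials <- trials[!drop, , drop = FALSE]
  }

  report <- structure(list(
    n_total = n_total,
    n_subjects_removed = n_subjects_removed,
    n_manual_trials_removed = sum(manual),
    n_fast_trials_removed = nrow(fast$removed),
    n_blocks_removed = nrow(blk$removed_blocks),
    n_block_trials_removed = nrow(blk$removed),
    n_outlier_trials_removed = n_outlier_removed,
    n_kept = nrow(trials),
    fraction_removed = if (n_total) 1 - nrow(trials) / n_total else 0,
    fraction_removed_by_task = vapply(
      c("navon", "composite"), function(tk) {
        tot <- total_by_task[[tk]]
        if (tot) 1 - sum(trials$task == tk) / tot else 0
      }, numeric(1))
  ), class = "dmc_exclusion_report")
  list(trials = trials, report = report)
}

#' @export
print.dmc_exclusion_report <- function(x, ...) {
  cat("Exclusion report:\n")
  cat(sprintf("  total trials          %d\n", x$n_total))
  cat(sprintf("  subjects removed      %d (%d trials)\n",
              x$n_subjects_removed, x$n_manual_trials_removed))
  cat(sprintf("  fast trials removed   %d\n", x$n_fast_trials_removed))
  cat(sprintf("  blocks removed        %d (%d trials)\n",
              x$n_blocks_removed, x$n_block_trials_removed))
  cat(sprintf("  outlier trials removed %d\n", x$n_outlier_trials_removed))
  cat(sprintf("  kept                  %d (%.2f%% removed)\n",
              x$n_kept, 100 * x$fraction_removed))
  invisible(x)
}

#' Serialize an exclusion report
#'
#' @param report A `dmc_exclusion_report`.
#' @param path Output file (YAML).
#' @export
write_exclusion_report <- function(report, path) {
  yaml::write_yaml(unclass(report), path)
  invisible(path)
}
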