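# Data-cleaning rules: fast-trial cutoff, sub-chance block exclusion,
# Tukey-fence screening, and their composition.

test_that("fast-trial exclusion uses a strict 300 ms cutoff", {
  tab <- make_raw_trials(rt = c(250, 300, 800), accuracy = 1)
  out <- exclude_fast_trials(tab)
  expect_equal(out$removed$rt, 250)
  expect_equal(sort(out$kept$rt), c(300, 800))
  # all at or above threshold: identity
  tab2 <- make_raw_trials(rt = c(300, 400, 500), accuracy = 1)
  expect_equal(exclude_fast_trials(tab2)$kept, tab2)
})

test_that("fast-trial exclusion removes exactly the planted contaminants", {
  spec <- make_paper_like_spec("navon", n_subjects = 1, jitter_sd = 0,
                               p_fast = 0.05, seed = 303)
  spec$design <- subset_design(spec$design, sessions = "CZ", times = "pre")
  d <- generate_dataset(spec)
  out <- exclude_fast_trials(d$trials)
  expect_equal(nrow(out$removed), sum(d$ledger$origin == "fast_guess"))
  # generated fast guesses all sit below 300 ms, model trials above
  expect_true(all(out$removed$rt < 300))
})

test_that("sub-chance blocks are removed by an exact binomial test", {
  mk <- function(correct, n = 48, block = 1L)
    make_raw_trials(rt = rep(500, n),
                    accuracy = c(rep(1, correct), rep(0, n - correct)),
                    block = block)
  tab <- rbind(mk(10, block = 1L), mk(24, block = 2L), mk(48, block = 3L))
  out <- exclude_subchance_blocks(tab)
  expect_equal(nrow(out$removed_blocks), 1L)
  expect_equal(unique(out$removed$block), 1L)
  expect_setequal(unique(out$kept$block), c(2L, 3L))
  # summation oracle for the one-sided tail the test uses
  expect_equal(out$removed_blocks$p_value,
               sum(stats::dbinom(0:10, 48, 0.5)), tolerance = 1e-12)
  expect_lt(sum(stats::dbinom(0:10, 48, 0.5)), 0.05)
  expect_gt(sum(stats::dbinom(0:24, 48, 0.5)), 0.05)
  # stricter mode: a chance-level block is also dropped
  out2 <- exclude_subchance_blocks(tab, mode = "not-above")
  expect_setequal(unique(out2$removed$block), c(1L, 2L))
})

test_that("Tukey fences flag strict outliers with type-7 quartiles", {
  # hand computation: Q1=2, Q3=4, IQR=2, fences [-1, 7]
  expect_equal(iqr_outlier_filter(c(1, 2, 3, 4, 100)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(iqr_outlier_filter(rep(7, 10))))
  expect_warning(flags <- iqr_outlier_filter(c(1, 2, 3)), "fewer than 4")
  expect_false(any(flags))
  # a value exactly on the fence is kept (strict inequality)
  expect_false(iqr_outlier_filter(c(1, 2, 3, 4, 7))[5])
})

test_that("Tukey fences flag ~0.7% of a Gaussian sample", {
  rates <- vapply(1:5, function(s) {
    set.seed(1000 + s)
    mean(iqr_outlier_filter(stats::rnorm(1000)))
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.007), 0.005)
})

test_that("full preprocessing reproduces generator ground truth", {
  spec <- make_paper_like_spec("navon", n_subjects = 2, jitter_sd = 0,
                               p_fast = 0.04, seed = 71)
  spec$design <- subset_design(spec$design, sessions = "CZ")
  d <- generate_dataset(spec)
  out <- preprocess_dataset(d$trials)
  expect_equal(out$report$n_fast_trials_removed,
               sum(d$ledger$origin == "fast_guess"))
  expect_equal(out$report$n_total, nrow(d$trials))
  expect_equal(out$report$fraction_removed,
               1 - nrow(out$trials) / nrow(d$trials))
})

test_that("clean data pass through preprocessing untouched", {
  spec <- make_paper_like_spec("composite", n_subjects = 2, jitter_sd = 0,
                               seed = 5)
  spec$design <- subset_design(spec$design, sessions = "CZ")
  d <- generate_dataset(spec)
  out <- preprocess_dataset(d$trials)
  expect_equal(nrow(out$trials), nrow(d$trials))
  expect_equal(out$report$n_fast_trials_removed, 0L)
  expect_equal(out$report$n_blocks_removed, 0L)
  expect_equal(out$report$fraction_removed, 0)
})

test_that("an all-guessing block disappears from the output", {
  spec <- make_paper_like_spec("navon", n_subjects = 1, jitter_sd = 0,
                               seed = 17)
  spec$design <- subset_design(spec$design, sessions = "CZ", times = "pre")
  d <- generate_dataset(spec)
  guess <- d$trials$block == 2
  set.seed(1)
  d$trials$accuracy[guess] <- stats::rbinom(sum(guess), 1, 0.12)
  out <- preprocess_dataset(d$trials)
  expect_false(any(out$trials$block == 2))
  expect_equal(out$report$n_blocks_removed, 1L)
})

test_that("preprocessing is order-invariant and idempotent", {
  spec <- make_paper_like_spec("navon", n_subjects = 2, jitter_sd = 0,
                               p_fast = 0.05, seed = 29)
  spec$design <- subset_design(spec$design, sessions = "CZ", times = "pre")
  d <- generate_dataset(spec)
  out1 <- preprocess_dataset(d$trials)
  set.seed(2)
  shuffled <- d$trials[sample.int(nrow(d$trials)), ]
  out2 <- preprocess_dataset(shuffled)
  key <- function(x) do.call(paste,
    x[order(x$subject, x$session, x$block, x$rt), ])
  expect_setequal(key(out1$trials), key(out2$trials))
  # second pass removes nothing further
  again <- preprocess_dataset(out1$trials)
  expect_equal(nrow(again$trials), nrow(out1$trials))
  expect_equal(again$report$fraction_removed, 0)
})

test_that("malformed tables are rejected with the offending row", {
  tab <- make_raw_trials(rt = c(400, 500), accuracy = 1)
  tab$congruency[2] <- "weird"
  expect_error(preprocess_dataset(tab), "row 2")
  tab2 <- make_raw_trials(rt = c(400, 500), accuracy = 1)
  tab2$task <- "stroop"
  expect_error(preprocess_dataset(tab2), "task")
})

test_that("manual subject exclusion is honoured and reported", {
  tab <- rbind(make_raw_trials(rt = rep(500, 20), accuracy = 1,
                               subject = "S01"),
               make_raw_trials(rt = rep(500, 20), accuracy = 1,
                               subject = "S02"))
  out <- preprocess_dataset(tab, preprocess_rules(exclude_subjects = "S02"))
  expect_false("S02" %in% out$trials$subject)
  expect_equal(out$report$n_subjects_removed, 1L)
})
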