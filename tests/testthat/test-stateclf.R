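# Feature assembly, dimensionality reduction, block-grouped classification,
# permutation chance, prediction of unlabeled trials.

toy_features <- function(n = 120, p = 10, effect = 3, seed = 1,
                         blocks = 6) {
  set.seed(seed)
  y <- rep(c("ON", "MW", "MB"), each = n / 3)
  X <- matrix(rnorm(n * p), n, p)
  if (effect > 0) {
    X[, 1] <- X[, 1] + ifelse(y == "ON", effect, ifelse(y == "MW", 0, -effect))
    X[, 2] <- X[, 2] + ifelse(y == "MW", effect, 0)
  }
  ft <- data.frame(trial_id = paste0("t", seq_len(n)),
                   onset_sample = seq_len(n) * 100,
                   block = rep(seq_len(blocks), length.out = n),
                   state_label = y, stringsAsFactors = FALSE)
  ft <- cbind(ft, as.data.frame(X))
  attr(ft, "feature_cols") <- paste0("V", seq_len(p))
  class(ft) <- c("feature_table", "data.frame")
  ft
}

test_that("feature table assembly aligns blocks and rejects mismatches", {
  rec <- small_session()
  stim <- label_trials(baseline_correct(epoch_stimuli(rec)), rec$probes)
  stim <- subset_epochs(stim, 1:12)
  mk <- marker_features(compute_marker_matrix(stim))
  cf <- connectivity_features(stim, rec$channels)
  ef <- erp_features(stim)
  ft <- build_feature_table(stim, mk, cf, ef)
  expect_equal(nrow(ft), 12)
  expect_length(attr(ft, "feature_cols"),
                (ncol(mk) - 1) + (ncol(cf) - 1) + (ncol(ef) - 1))
  expect_equal(ncol(mk) - 1, 32 * 7)
  expect_equal(ncol(cf) - 1, 6 * 3)
  expect_equal(ncol(ef) - 1, 32 * 3)
  bad <- mk; bad$trial_id[1] <- "nope"
  expect_error(build_feature_table(stim, bad, cf, ef), "mismatch")
  expect_error(build_feature_table(stim), "no feature blocks")
})

test_that("feature columns are deterministic across recomputation", {
  rec <- small_session()
  stim <- subset_epochs(
    label_trials(baseline_correct(epoch_stimuli(rec)), rec$probes), 1:8)
  f1 <- compute_features(stim, rec$channels)
  f2 <- compute_features(stim, rec$channels)
  expect_identical(attr(f1, "feature_cols"), attr(f2, "feature_cols"))
  expect_identical(f1, f2)
})

test_that("reduce_dim: fitted once, applied without refitting", {
  set.seed(51)
  X <- matrix(rnorm(60 * 12), 60, 12)
  X[, 12] <- 1                                       # constant feature
  expect_warning(red <- reduce_dim(X), "constant")
  Z1 <- red$transform(X)
  expect_identical(Z1, red$transform(X))             # deterministic
  expect_lte(ncol(Z1), 25)
  # new rows do not change the fitted transform of old rows
  Xnew <- matrix(rnorm(10 * 12), 10, 12)
  Zn <- red$transform(Xnew)
  expect_identical(red$transform(X), Z1)
  expect_equal(ncol(Zn), ncol(Z1))
  # kernel variant obeys the same contract
  redk <- reduce_dim(X[, 1:11], method = "kpca")
  Zk <- redk$transform(X[, 1:11])
  expect_identical(Zk, redk$transform(X[, 1:11]))
  # NA features are imputed by the training median
  Xna <- X[, 1:11]; Xna[3, 4] <- NA
  redn <- reduce_dim(Xna)
  expect_true(all(is.finite(redn$transform(Xna))))
})

test_that("balanced accuracy and chance behavior of the classifier", {
  expect_equal(balanced_accuracy(c("a", "a", "b"), c("a", "a", "b")), 1)
  expect_equal(balanced_accuracy(c("a", "a", "b", "b"),
                                 c("a", "a", "a", "a")), 0.5)
  ft <- toy_features(n = 180, effect = 8)
  fit <- fit_crossval(ft, seed = 1)
  expect_gt(fit$balanced_accuracy, 0.95)
  # label shuffling collapses to the 3-class chance level
  ft0 <- ft
  set.seed(2)
  ft0$state_label <- sample(ft0$state_label)
  attr(ft0, "feature_cols") <- attr(ft, "feature_cols")
  fit0 <- fit_crossval(ft0, seed = 1)
  expect_lt(abs(fit0$balanced_accuracy - 1 / 3), 0.12)
  # shifting every feature by a constant changes nothing
  ft_shift <- ft
  ft_shift[attr(ft, "feature_cols")] <- ft[attr(ft, "feature_cols")] + 100
  attr(ft_shift, "feature_cols") <- attr(ft, "feature_cols")
  expect_equal(fit_crossval(ft_shift, seed = 1)$balanced_accuracy,
               fit$balanced_accuracy)
})

test_that("permutation chance is calibrated and bounded", {
  ft <- toy_features(effect = 0, seed = 3)
  pc <- permutation_chance(ft, n_perm = 120, seed = 2)
  expect_gte(pc$p, 1 / 121)
  expect_lt(abs(median(pc$null) - 1 / 3), 0.1)
  # informative features give a small p
  ft1 <- toy_features(effect = 3, seed = 4)
  pc1 <- permutation_chance(ft1, n_perm = 120, seed = 2)
  expect_lt(pc1$p, 0.02)
})

test_that("no leakage: a test-block-only artifact cannot inflate accuracy", {
  ft <- toy_features(effect = 0.8, seed = 5)
  base <- fit_crossval(ft, seed = 1)$balanced_accuracy
  # inject a feature perfectly predictive inside block 3 only
  ft2 <- ft
  art <- rnorm(nrow(ft2))
  in3 <- ft2$block == 3
  art[in3] <- as.integer(factor(ft2$state_label[in3]))
  ft2$artifact <- art
  attr(ft2, "feature_cols") <- c(attr(ft, "feature_cols"), "artifact")
  with_art <- fit_crossval(ft2, seed = 1)$balanced_accuracy
  expect_lt(with_art, base + 0.1)
})

test_that("unlabeled prediction covers all rows with unit-sum probabilities", {
  ft <- toy_features(effect = 3, seed = 6)
  unl <- ft$block == 6
  ft$state_label[unl] <- "unlabeled"
  attr(ft, "feature_cols") <- paste0("V", 1:10)
  pipe <- fit_full(ft, seed = 2)
  preds <- predict_unlabeled(pipe, ft)
  expect_equal(nrow(preds), sum(unl))
  expect_true(all(abs(rowSums(preds[, c("ON", "MW", "MB")]) - 1) < 1e-9))
  expect_true(all(preds$predicted %in% c("ON", "MW", "MB")))
  expect_error(predict_unlabeled(pipe, toy_features(effect = 3)), "no unlabeled")
})

test_that("validation with perfect predictions equals labeled summaries", {
  rec <- generate_session(session_config(
    n_blocks = 1, block_duration = 400, seed = 60, synth_eeg = FALSE))
  stim <- rec$events[rec$events$kind == "stimulus", ]
  truth <- as.character(rec$truth_states[stim$onset_sample])
  tab <- behavior_table(rec$events, rec$fs,
                        labels = data.frame(onset_sample = stim$onset_sample,
                                            state_label = truth))
  preds <- data.frame(trial_id = paste0("stim_", seq_len(nrow(stim))),
                      onset_sample = stim$onset_sample,
                      predicted = truth, stringsAsFactors = FALSE)
  val <- validate_predictions(preds, tab)
  direct <- summarize_behavior(tab[tab$state_label %in% c("ON", "MW", "MB"), ])
  expect_equal(val$summary$miss_rate, direct$miss_rate)
  expect_equal(val$summary$rt_median, direct$rt_median)
})
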