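# ERP averages/contrasts and temporal decoding.

# small labeled epoch set built directly (no session machinery)
fake_epochs <- function(n_per = 30, n_ch = 6, n_t = 50, fs = 100,
                        labels = c("ON", "MB"), effect = 0, t_on = NULL,
                        seed = 1) {
  set.seed(seed)
  n <- n_per * length(labels)
  data <- array(rnorm(n * n_ch * n_t), c(n, n_ch, n_t))
  lab <- rep(labels, each = n_per)
  if (effect != 0 && !is.null(t_on))
    data[lab == labels[1], , t_on] <- data[lab == labels[1], , t_on] + effect
  md <- data.frame(trial_id = paste0("t", seq_len(n)), state_label = lab,
                   stimulus_category = rep(c("face", "digit"), n / 2),
                   block = rep(1:5, length.out = n),
                   stringsAsFactors = FALSE)
  mindstate:::new_epoch_set(data, fs, c(0, n_t / fs), md)
}

test_that("ERP means: single-trial group equals that trial", {
  ep <- fake_epochs(n_per = 1, labels = c("ON", "MB"))
  er <- compute_erp(ep)
  expect_equal(er$means$ON, ep$data[1, , ], tolerance = 1e-12)
  expect_equal(er$counts[["MB"]], 1)
})

test_that("synthetic ON shows the late central positivity, MB does not", {
  on <- state_session("ON", seed = 301)
  mb <- state_session("MB", seed = 304)
  erp_of <- function(rec) {
    ep <- baseline_correct(epoch_stimuli(rec))
    ep$metadata$state_label <- rec$config$fixed_state
    compute_erp(ep)
  }
  eon <- erp_of(on); emb <- erp_of(mb)
  cent <- row_channels(on$channels, "central")
  tt <- eon$times
  late <- tt >= 0.40 & tt <= 0.65
  on_late <- colMeans(eon$means$ON[cent, ])
  mb_late <- colMeans(emb$means$MB[cent, ])
  expect_gt(max(on_late[late]), 2)
  # no MB deflection beyond 3x the baseline SD
  base_sd <- sd(mb_late[tt < 0])
  expect_lt(max(abs(mb_late[late])), 3 * base_sd + 0.5)
})

test_that("ERP contrasts: sign flip, null control, planted recovery", {
  ep0 <- fake_epochs(effect = 0, seed = 2)
  ab <- erp_state_contrast(ep0, c("ON", "MB"))
  ba <- erp_state_contrast(ep0, c("MB", "ON"))
  expect_equal(ab$effect, -ba$effect, tolerance = 1e-12)
  # identical distributions: raw positives near alpha, none post-FDR
  expect_lt(mean(ab$p < 0.05), 0.12)
  expect_equal(sum(ab$mask), 0)
  # planted difference at known timepoints is flagged there
  ep1 <- fake_epochs(effect = 1.5, t_on = 20:30, seed = 3)
  ct <- erp_state_contrast(ep1, c("ON", "MB"))
  expect_gt(mean(ct$mask[, 20:30]), 0.8)
  expect_lt(mean(ct$mask[, c(1:15, 40:50)]), 0.05)
  expect_error(erp_state_contrast(ep1, c("ON", "MW")), "absent")
})

test_that("balanced subsampling hits the min-count rule deterministically", {
  ep <- fake_epochs(n_per = 40, labels = c("ON", "MW", "MB"))
  keep <- c(rep(TRUE, 120))
  ep2 <- subset_epochs(ep, c(1:40, 41:70, 81:95))  # 40 / 30 / 15
  bal <- balance_subsample(ep2, seed = 5)
  expect_equal(as.integer(table(bal$metadata$state_label)), rep(15L, 3))
  bal2 <- balance_subsample(ep2, seed = 5)
  expect_identical(bal$metadata$trial_id, bal2$metadata$trial_id)
  expect_true(all(bal$metadata$trial_id %in% ep2$metadata$trial_id))
  expect_error(balance_subsample(fake_epochs(labels = "ON")), "two")
})

test_that("pooled decoding AUC matches a direct Mann-Whitney count", {
  set.seed(41)
  for (i in 1:20) {
    scores <- rnorm(40)
    y <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(y) || all(y)) next
    direct <- mean(outer(scores[y], scores[!y], function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(mindstate:::auc_rank(scores, y), direct, tolerance = 1e-12)
  }
})

test_that("decoding is at chance for label-independent data", {
  ep <- fake_epochs(n_per = 100, n_ch = 8, n_t = 30, seed = 6)
  cv <- temporal_decode(ep, seed = 2)
  expect_true(mean(cv$auc) > 0.45 && mean(cv$auc) < 0.55)
})

test_that("a class step at one timepoint decodes there and only there", {
  ep <- fake_epochs(n_per = 100, n_ch = 8, n_t = 30, seed = 7)
  t_star <- 15
  faces <- ep$metadata$stimulus_category == "face"
  ep$data[faces, , t_star] <- ep$data[faces, , t_star] + 2
  cv <- temporal_decode(ep, seed = 2)
  expect_gt(cv$auc[t_star], 0.9)
  expect_lt(max(cv$auc[-t_star]), 0.65)
  # invariance to channel-wise affine rescaling
  ep2 <- ep
  for (ch in 1:8) ep2$data[, ch, ] <- ep2$data[, ch, ] * (ch + 1) + 3 * ch
  cv2 <- temporal_decode(ep2, seed = 2)
  expect_equal(cv2$auc, cv$auc, tolerance = 1e-6)
})

test_that("permutation significance: add-one bound, null control, recovery", {
  ep <- fake_epochs(n_per = 60, n_ch = 8, n_t = 20, seed = 8)
  t_star <- 10
  faces <- ep$metadata$stimulus_category == "face"
  ep$data[faces, , t_star] <- ep$data[faces, , t_star] + 2
  cv <- temporal_decode(ep, seed = 2)
  cv <- decode_significance(cv, ep, n_perm = 200, seed = 3)
  expect_true(all(cv$p >= 1 / 201))
  expect_true(cv$significant[t_star])
  expect_lt(sum(cv$significant[-t_star]), 3)
  expect_equal(dim(cv$null_quantiles), c(20, 3))
  # null data: nothing survives FDR
  ep0 <- fake_epochs(n_per = 60, n_ch = 8, n_t = 20, seed = 9)
  cv0 <- temporal_decode(ep0, seed = 2)
  cv0 <- decode_significance(cv0, ep0, n_perm = 200, seed = 3)
  expect_equal(sum(cv0$significant), 0)
  expect_warning(decode_significance(cv0, ep0, n_perm = 50, seed = 1),
                 "unstable")
})
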