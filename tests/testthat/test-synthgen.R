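# Synthetic SART-session generator: configuration contracts, latent-state
# schedule, task timing, planted signatures, determinism.

test_that("configuration invariants are enforced", {
  expect_error(session_config(soa_range = c(1250, 750)), "soa_range")
  expect_error(session_config(nogo_rate = 0), "nogo_rate")
  expect_error(session_config(nogo_rate = 1), "nogo_rate")
  expect_error(session_config(probe_interval_range = c(70, 40)),
               "probe_interval_range")
  expect_error(session_config(state_dwell = -1), "state_dwell")
  expect_error(session_config(block_duration = 0.5), "shorter than one SOA")
  expect_error(signal_params(linear_coupling = 1.5), "coupling")
  expect_error(behavior_params(miss_prob = 2), "probabilities")
  expect_error(behavior_params(rt_mu = 0), "rt_mu")
})

test_that("state timecourse: degenerate dwell pins the initial state", {
  cfg <- session_config(n_blocks = 2, block_duration = 20, state_dwell = Inf,
                        seed = 1)
  tc <- generate_state_timecourse(cfg, init = "ON")
  expect_true(all(tc == "ON"))
  expect_length(tc, 2 * 20 * 250)
})

test_that("state timecourse is deterministic and piecewise over ON/MW/MB", {
  cfg <- session_config(n_blocks = 2, block_duration = 30, seed = 7)
  tc1 <- generate_state_timecourse(cfg)
  tc2 <- generate_state_timecourse(cfg)
  expect_identical(tc1, tc2)
  expect_true(all(levels(tc1) == c("ON", "MW", "MB")))
  expect_gte(length(rle(as.character(tc1))$lengths), 2)
})

test_that("empirical dwell matches the exponential mean within 10%", {
  # 100 long blocks; exclude block-truncated segments from the estimate
  cfg <- session_config(n_blocks = 100, block_duration = 60, state_dwell = 5,
                        seed = 11, fs = 100)
  tc <- generate_state_timecourse(cfg)
  n_block <- 60 * 100
  per_block <- split(as.character(tc),
                     rep(seq_len(100), each = n_block))
  dwells <- unlist(lapply(per_block, function(b) {
    r <- rle(b)$lengths
    if (length(r) > 1) r[-length(r)] else integer(0)  # drop truncated tail
  }))
  expect_gt(length(dwells), 300)
  expect_lt(abs(mean(dwells) / 100 - 5) / 5, 0.10)
})

test_that("identical config and seed give a bit-identical session", {
  cfg <- session_config(n_blocks = 1, block_duration = 45, seed = 33)
  r1 <- generate_session(cfg)
  r2 <- generate_session(cfg)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$probes, r2$probes)
  expect_identical(r1$truth_states, r2$truth_states)
})

test_that("probe timing respects the configured jitter window", {
  rec <- small_session()
  pr <- rec$probes
  for (b in unique(pr$block)) {
    b0 <- (b - 1) * 90
    onsets <- pr$onset_s[pr$block == b]
    gaps <- diff(c(b0, onsets))
    expect_true(all(gaps >= 40 - 1e-9 & gaps <= 70 + 1e-9))
  }
})

test_that("a probe interval longer than the block yields zero probes", {
  cfg <- session_config(n_blocks = 1, block_duration = 30,
                        probe_interval_range = c(40, 70), seed = 2,
                        synth_eeg = FALSE)
  rec <- generate_session(cfg)
  expect_equal(nrow(rec$probes), 0)
})

test_that("No-Go fraction matches 1-in-9 within a binomial 99.9% interval", {
  cfg <- session_config(n_blocks = 6, block_duration = 1000, seed = 5,
                        synth_eeg = FALSE)
  rec <- generate_session(cfg)
  stim <- rec$events[rec$events$kind == "stimulus", ]
  n <- nrow(stim)
  expect_gte(n, 5000)
  p_hat <- mean(stim$go_nogo == "nogo")
  se <- sqrt((1 / 9) * (8 / 9) / n)
  expect_lt(abs(p_hat - 1 / 9), 3.29 * se)
})

test_that("planted P3b appears in the ON-minus-MB average at the right place", {
  # low-noise parameters so the template recovery is tight
  quiet <- lapply(default_state_params(), function(p) {
    p$noise_sd <- 0.2
    p
  })
  mk <- function(state, seed) generate_session(session_config(
    n_blocks = 1, block_duration = 80, seed = seed, fixed_state = state,
    state_params = quiet, bg_amp = 1, base_band_amp = rep(0.3, 5),
    couple_amp = 0.5))
  on <- mk("ON", 71); mb <- mk("MB", 72)
  eon <- baseline_correct(epoch_stimuli(on))
  emb <- baseline_correct(epoch_stimuli(mb))
  cent <- row_channels(on$channels, "central")
  diff_wave <- apply(eon$data[, cent, ], 3, mean) -
    apply(emb$data[, cent, ], 3, mean)
  tt <- eon$times
  inside <- tt >= 0.40 & tt <= 0.65
  p3b_amp <- default_state_params()$ON$p3b_amp
  expect_lt(abs(max(diff_wave[inside]) - p3b_amp) / p3b_amp, 0.20)
  expect_lt(max(abs(diff_wave[tt < 0.3 & tt > 0.28])), 0.5)
})

test_that("behavioral rates land inside binomial 99% intervals per state", {
  bp <- default_behavior_params()
  for (state in c("ON", "MW", "MB")) {
    rec <- generate_session(session_config(
      n_blocks = 2, block_duration = 600,
      seed = 80 + match(state, c("ON", "MW", "MB")),
      fixed_state = state, synth_eeg = FALSE))
    stim <- rec$events[rec$events$kind == "stimulus", ]
    go <- stim$go_nogo == "go"
    miss_hat <- mean(is.na(stim$rt_ms[go]))
    fa_hat <- mean(!is.na(stim$rt_ms[!go]))
    p <- bp[[state]]
    expect_lt(abs(miss_hat - p$miss_prob),
              2.58 * sqrt(p$miss_prob * (1 - p$miss_prob) / sum(go)) + 1e-9)
    expect_lt(abs(fa_hat - p$fa_prob),
              2.58 * sqrt(p$fa_prob * (1 - p$fa_prob) / sum(!go)) + 1e-9)
  }
})

test_that("front-back spectral gradient is planted with the right sign", {
  mb <- state_session("MB", seed = 301)
  mw <- state_session("MW", seed = 302)
  fast_frac <- function(rec) {
    pre <- epoch_preprobe(rec)
    mk <- compute_marker_matrix(pre)
    colMeans(mk$values[, , "psd_beta"] + mk$values[, , "psd_gamma"])
  }
  d <- fast_frac(mb) - fast_frac(mw)
  lay <- mb$channels
  expect_gt(mean(d[row_channels(lay, "frontal")]), 0)
  expect_lt(mean(d[row_channels(lay, "occipital")]), 0)
})
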