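# Synthetic SART-session generator.
#
# The generative model is deliberately minimal but rich enough that every
# downstream stage (PSD/SampEn/KC, wSMI/PLV, ERP, temporal decoding,
# behavior, state classification) has a planted, recoverable signal:
#   EEG = 1/f background (1-45 Hz)
#       + band-limited oscillations whose amplitude per band x channel-row
#         depends on the latent mind state (front-back gradients)
#       + additive raised-cosine ERP templates per stimulus (P1 in all
#         states; P3b present in ON, reduced/delayed in MW, absent in MB;
#         category-dependent early and late components for decoding)
#       + long-range coupling on designated fronto-parietal pairs: a shared
#         narrowband source injected at zero lag (linear, phase-aligning,
#         what PLV sees) and a lagged rank-preserving cubic distortion of a
#         shared source (nonlinear, what wSMI sees)
#       + white sensor noise.
# Latent states follow a semi-Markov schedule with exponential dwell times,
# truncated at block boundaries; probes report the latent state exactly
# unless report noise is enabled.

#' Per-state signal parameters for the synthetic generator
#'
#' @param band_power_map 5 x 4 matrix of relative oscillatory power
#'   (rows = delta/theta/alpha/beta/gamma, columns = frontal/central/
#'   parietal/occipital channel rows). Multiplies the squared base band
#'   amplitudes; this is where the front-back gradient is planted.
#' @param p1_amp posterior P1 peak amplitude, uV.
#' @param p3b_amp central P3b peak amplitude, uV; 0 encodes "absent".
#' @param p3b_latency,p3b_duration P3b onset and duration, ms.
#' @param linear_coupling,nonlinear_coupling coupling strengths in \[0, 1\]
#'   for the planted fronto-parietal pairs (see [planted_pairs()]).
#' @param cat_early_amp,cat_late_amp stimulus-category (face vs digit)
#'   response difference, uV, for the early (~200 ms, posterior) and late
#'   (central) components; what temporal decoding can recover.
#' @param cat_late_window start/end of the late category window, s.
#' @param noise_sd white sensor noise SD, uV.
#' @return object of class `signal_params`.
#' @export
signal_params <- function(band_power_map = matrix(1, 5, 4),
                          p1_amp = 3, p3b_amp = 4.5,
                          p3b_latency = 400, p3b_duration = 250,
                          linear_coupling = 0.1, nonlinear_coupling = 0.6,
                          cat_early_amp = 4, cat_late_amp = 3,
                          cat_late_window = c(0.35, 0.65),
                          noise_sd = 2) {
  stopifnot(is.matrix(band_power_map), nrow(band_power_map) == 5,
            ncol(band_power_map) == 4, all(band_power_map >= 0))
  if (linear_coupling < 0 || linear_coupling > 1 ||
      nonlinear_coupling < 0 || nonlinear_coupling > 1)
    stopf("coupling strengths must lie in [0, 1]")
  if (p3b_duration <= 0 || p3b_latency < 0)
    stopf("p3b_latency must be >= 0 and p3b_duration > 0")
  dimnames(band_power_map) <- list(default_bands()$name,
                                   c("frontal", "central", "parietal", "occipital"))
  structure(list(band_power_map = band_power_map, p1_amp = p1_amp,
                 p3b_amp = p3b_amp, p3b_latency = p3b_latency,
                 p3b_duration = p3b_duration,
                 linear_coupling = linear_coupling,
                 nonlinear_coupling = nonlinear_coupling,
                 cat_early_amp = cat_early_amp, cat_late_amp = cat_late_amp,
                 cat_late_window = cat_late_window, noise_sd = noise_sd),
            class = "signal_params")
}

#' Per-state behavioral parameters
#'
#' Reaction times are log-normal: `rt_mu` is the median RT and `rt_sigma`
#' approximately the RT standard deviation (the log-sd used is
#' `rt_sigma / rt_mu`).
#'
#' @param miss_prob probability of no response on a Go trial.
#' @param fa_prob probability of a response on a No-Go trial.
#' @param rt_mu median reaction time, ms (> 0).
#' @param rt_sigma RT spread, ms.
#' @return object of class `behavior_params`.
#' @export
behavior_params <- function(miss_prob = 0.05, fa_prob = 0.25,
                            rt_mu = 520, rt_sigma = 130) {
  if (miss_prob < 0 || miss_prob > 1 || fa_prob < 0 || fa_prob > 1)
    stopf("probabilities must lie in [0, 1]")
  if (rt_mu <= 0) stopf("rt_mu must be > 0")
  structure(list(miss_prob = miss_prob, fa_prob = fa_prob,
                 rt_mu = rt_mu, rt_sigma = rt_sigma),
            class = "behavior_params")
}

#' Default planted signal parameters per mind state
#'
#' ON is the reference state. Relative to it, MB plants faster oscillatory
#' activity over frontal rows and slower over posterior rows, an absent P3b
#' and strong zero-lag (linear) coupling with almost no nonlinear coupling;
#' MW plants the opposite front-back tilt of fast activity, a reduced and
#' delayed P3b, weak late category information, and intermediate coupling.
#'
#' @return named list of [signal_params()] for ON, MW, MB.
#' @export
default_state_params <- function() {
  base <- matrix(1, 5, 4)
  base[3, ] <- c(0.7, 0.9, 1.3, 1.6)            # posterior alpha gradient

  on_map <- base
  on_map[3, ] <- c(0.45, 0.55, 0.80, 0.95)      # task-engagement alpha block

  mw_map <- base
  mw_map[1, ] <- mw_map[1, ] * c(1.30, 1.10, 1.00, 1.00)   # frontal delta
  mw_map[2, ] <- mw_map[2, ] * 1.60                        # theta increase
  mw_map[3, ] <- mw_map[3, ] * c(1.00, 1.15, 1.50, 1.60)   # posterior alpha
  mw_map[4, ] <- mw_map[4, ] * c(0.50, 1.35, 1.25, 1.20)   # beta
  mw_map[5, ] <- mw_map[5, ] * c(0.50, 1.35, 1.25, 1.20)   # gamma

  mb_map <- base
  mb_map[4, ] <- mb_map[4, ] * c(1.80, 1.40, 0.50, 0.40)
  mb_map[5, ] <- mb_map[5, ] * c(1.80, 1.40, 0.50, 0.40)
  mb_map[1, 3:4] <- mb_map[1, 3:4] * 1.50                  # posterior delta

  list(
    ON = signal_params(on_map, p1_amp = 3, p3b_amp = 4.5, p3b_latency = 400,
                       p3b_duration = 250, linear_coupling = 0.10,
                       nonlinear_coupling = 0.60, cat_early_amp = 4,
                       cat_late_amp = 3, cat_late_window = c(0.35, 0.65)),
    MW = signal_params(mw_map, p1_amp = 3, p3b_amp = 1.5, p3b_latency = 500,
                       p3b_duration = 140, linear_coupling = 0.30,
                       nonlinear_coupling = 0.35, cat_early_amp = 5.5,
                       cat_late_amp = 2, cat_late_window = c(0.40, 0.55)),
    MB = signal_params(mb_map, p1_amp = 2.5, p3b_amp = 0, p3b_latency = 400,
                       p3b_duration = 250, linear_coupling = 0.85,
                       nonlinear_coupling = 0.05, cat_early_amp = 0,
                       cat_late_amp = 0, cat_late_window = c(0.35, 0.65))
  )
}

#' Default planted behavioral parameters per mind state
#'
#' Plants the qualitative profile reported for SART experience sampling:
#' mind blanking is "absent" (most misses, slowest RTs), mind wandering is
#' "impulsive" (most false alarms, fastest RTs).
#'
#' @return named list of [behavior_params()] for ON, MW, MB.
#' @export
default_behavior_params <- function() {
  list(
    ON = behavior_params(miss_prob = 0.04, fa_prob = 0.20, rt_mu = 520, rt_sigma = 130),
    MW = behavior_params(miss_prob = 0.08, fa_prob = 0.52, rt_mu = 440, rt_sigma = 120),
    MB = behavior_params(miss_prob = 0.20, fa_prob = 0.40, rt_mu = 640, rt_sigma = 160)
  )
}

#' Configuration of one synthetic SART session
#'
#' Task-structure defaults follow the experience-sampling SART design: SOA
#' uniform in 750-1250 ms with null inter-stimulus interval, 1-in-9 No-Go
#' trials, probes every 40-70 s, six blocks.
#'
#' @param n_channels channel count (multiple of 4; default 32).
#' @param fs sampling rate, Hz.
#' @param n_blocks number of task blocks.
#' @param block_duration block length, s.
#' @param soa_range stimulus onset asynchrony range, ms.
#' @param nogo_rate fraction of No-Go trials, in (0, 1).
#' @param probe_interval_range inter-probe interval range, s.
#' @param state_dwell mean latent-state dwell time, s (may be `Inf`).
#' @param state_params named list (ON/MW/MB) of [signal_params()].
#' @param behavior_params named list (ON/MW/MB) of [behavior_params()].
#' @param seed integer seed; the config plus seed fully determines the session.
#' @param fixed_state if non-NULL, the latent state is pinned to this value
#'   for the whole session (used to manufacture single-state sessions).
#' @param report_noise probability that a probe answer is replaced by a
#'   uniform draw from ON/MW/MB/DR (default 0: probes report the exact
#'   latent state so that generator truth is recoverable).
#' @param synth_eeg set `FALSE` to skip EEG synthesis (events/behavior only).
#' @param bg_amp 1/f background RMS amplitude, uV.
#' @param base_band_amp base RMS amplitude per band, uV (length 5).
#' @param couple_amp full-strength RMS amplitude of the planted coupling
#'   sources, uV.
#' @return object of class `session_config`.
#' @export
session_config <- function(n_channels = 32, fs = 250, n_blocks = 6,
                           block_duration = 600,
                           soa_range = c(750, 1250), nogo_rate = 1 / 9,
                           probe_interval_range = c(40, 70),
                           state_dwell = 30,
                           state_params = default_state_params(),
                           behavior_params = default_behavior_params(),
                           seed = 1L, fixed_state = NULL,
                           report_noise = 0, synth_eeg = TRUE,
                           bg_amp = 5,
                           base_band_amp = c(4, 3, 3, 2, 1.5),
                           couple_amp = 5) {
  if (length(soa_range) != 2 || soa_range[1] <= 0 || soa_range[1] > soa_range[2])
    stopf("soa_range must be positive with lo <= hi")
  if (nogo_rate <= 0 || nogo_rate >= 1) stopf("nogo_rate must lie in (0, 1)")
  if (length(probe_interval_range) != 2 ||
      probe_interval_range[1] <= 0 ||
      probe_interval_range[1] > probe_interval_range[2])
    stopf("probe_interval_range must be positive with lo <= hi")
  if (!is.infinite(state_dwell) && state_dwell <= 0)
    stopf("state_dwell must be > 0")
  if (block_duration * 1000 < soa_range[2])
    stopf("block_duration shorter than one SOA")
  stopifnot(setequal(names(state_params), MIND_STATES),
            setequal(names(behavior_params), MIND_STATES))
  if (!is.null(fixed_state)) fixed_state <- match.arg(fixed_state, MIND_STATES)
  structure(list(
    n_channels = n_channels, fs = fs, n_blocks = n_blocks,
    block_duration = block_duration, soa_range = soa_range,
    nogo_rate = nogo_rate, probe_interval_range = probe_interval_range,
    state_dwell = state_dwell, state_params = state_params,
    behavior_params = behavior_params, seed = as.integer(seed),
    fixed_state = fixed_state, report_noise = report_noise,
    synth_eeg = synth_eeg, bg_amp = bg_amp,
    base_band_amp = base_band_amp, couple_amp = couple_amp
  ), class = "session_config")
}

# band-limited Gaussian noise with unit RMS, via FFT masking (exponent 0)
# or 1/f amplitude shaping (exponent > 0); zero outside [f_lo, f_hi]
spectral_noise <- function(n, fs, f_lo, f_hi, exponent = 0) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- abs(seq(0, fs, length.out = n + 1)[seq_len(n)])
  f <- pmin(f, fs - f)                       # fold to physical frequency
  gain <- numeric(n)
  sel <- f >= f_lo & f <= f_hi
  gain[sel] <- if (exponent > 0) f[sel]^(-exponent / 2) else 1
  x <- Re(stats::fft(W * gain, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

# rank-preserving cubic distortion, rescaled to unit RMS
cubic_distort <- function(x) {
  y <- x^3
  s <- stats::sd(y)
  if (s == 0) y else y / s
}

# raised-cosine bump of given peak amplitude over [t0, t0 + width] (seconds)
erp_bump <- function(t, t0, width, amp) {
  u <- (t - t0) / width
  out <- numeric(length(t))
  sel <- u >= 0 & u <= 1
  out[sel] <- amp * 0.5 * (1 - cos(2 * pi * u[sel]))
  out
}

#' Generate the latent mind-state timecourse of a session
#'
#' Semi-Markov schedule over ON/MW/MB: dwell times are exponential with mean
#' `state_dwell` seconds, truncated at block boundaries; at each switch the
#' next state is drawn uniformly from the other two. Each block starts from
#' a freshly drawn state (or `init`/`fixed_state` when given).
#'
#' @param config [session_config()].
#' @param init optional initial state for every block.
#' @return factor vector, one latent state per sample.
#' @export
generate_state_timecourse <- function(config, init = NULL) {
  if (!is.infinite(config$state_dwell) && config$state_dwell <= 0)
    stopf("state_dwell must be > 0")
  fs <- config$fs
  n_block <- round(config$block_duration * fs)
  init <- init %||% config$fixed_state
  with_seed(child_seed(config$seed, 1L), {
    per_block <- lapply(seq_len(config$n_blocks), function(b) {
      states <- character(0)
      cur <- init %||% sample(MIND_STATES, 1)
      left <- n_block
      while (left > 0) {
        dwell <- if (is.infinite(config$state_dwell) ||
                     !is.null(config$fixed_state)) left
          else max(1L, round(stats::rexp(1, 1 / config$state_dwell) * fs))
        take <- min(dwell, left)
        states <- c(states, rep(cur, take))
        left <- left - take
        cur <- if (!is.null(config$fixed_state)) cur
          else sample(setdiff(MIND_STATES, cur), 1)
      }
      states
    })
    factor(unlist(per_block), levels = MIND_STATES)
  })
}

# stimulus / response / probe event tables for one session
generate_events <- function(config, truth) {
  fs <- config$fs
  n_block <- round(config$block_duration * fs)
  soa_s <- config$soa_range / 1000
  state_at <- function(t_s) as.character(truth[pmin(length(truth), pmax(1L, round(t_s * fs) + 1L))])

  with_seed(child_seed(config$seed, 2L), {
    ev <- list(); pr <- list()
    for (b in seq_len(config$n_blocks)) {
      b0 <- (b - 1) * config$block_duration
      b1 <- b0 + config$block_duration
      # stimulus train: null ISI, SOA ~ U(soa_range)
      t <- b0 + 0.5
      onsets <- numeric(0)
      while (t + 0.8 < b1) {
        onsets <- c(onsets, t)
        t <- t + stats::runif(1, soa_s[1], soa_s[2])
      }
      n_stim <- length(onsets)
      if (n_stim == 0) next
      nogo <- stats::runif(n_stim) < config$nogo_rate
      category <- ifelse(stats::runif(n_stim) < 0.5, "face", "digit")
      st <- state_at(onsets)
      bp <- config$behavior_params
      responded <- logical(n_stim); rt <- rep(NA_real_, n_stim)
      for (i in seq_len(n_stim)) {
        p <- bp[[st[i]]]
        respond <- if (nogo[i]) stats::runif(1) < p$fa_prob
                   else stats::runif(1) >= p$miss_prob
        if (respond) {
          responded[i] <- TRUE
          rt[i] <- min(1500, max(150, stats::rlnorm(
            1, meanlog = log(p$rt_mu), sdlog = p$rt_sigma / p$rt_mu)))
        }
      }
      ev[[b]] <- data.frame(
        onset_s = onsets, kind = "stimulus", category = category,
        go_nogo = ifelse(nogo, "nogo", "go"), rt_ms = rt,
        responded = responded, block = b, stringsAsFactors = FALSE)
      resp <- ev[[b]][responded, , drop = FALSE]
      if (nrow(resp)) {
        ev[[b]] <- rbind(ev[[b]], data.frame(
          onset_s = resp$onset_s + resp$rt_ms / 1000, kind = "response",
          category = NA, go_nogo = NA, rt_ms = NA, responded = NA,
          block = b, stringsAsFactors = FALSE))
      }
      # probes every U(probe_interval_range) seconds
      tp <- b0 + stats::runif(1, config$probe_interval_range[1],
                              config$probe_interval_range[2])
      probes <- numeric(0)
      while (tp < b1 - 1) {
        probes <- c(probes, tp)
        tp <- tp + stats::runif(1, config$probe_interval_range[1],
                                config$probe_interval_range[2])
      }
      if (length(probes)) {
        ans <- state_at(probes)
        if (config$report_noise > 0) {
          flip <- stats::runif(length(ans)) < config$report_noise
          ans[flip] <- sample(c(MIND_STATES, "DR"), sum(flip), replace = TRUE)
        }
        vig_probs <- list(ON = c(0.02, 0.08, 0.30, 0.60),
                          MW = c(0.05, 0.25, 0.45, 0.25),
                          MB = c(0.15, 0.35, 0.35, 0.15),
                          DR = c(0.15, 0.35, 0.35, 0.15))
        vig <- vapply(ans, function(a) sample(1:4, 1, prob = vig_probs[[a]]), 1L)
        pr[[b]] <- data.frame(
          onset_s = probes, answer = ans, vigilance = vig, block = b,
          stringsAsFactors = FALSE)
      }
    }
    events <- do.call(rbind, ev)
    probes <- if (length(pr)) do.call(rbind, pr) else
      data.frame(onset_s = numeric(0), answer = character(0),
                 vigilance = integer(0), block = integer(0))
    events <- events[order(events$onset_s), , drop = FALSE]
    events$onset_sample <- round(events$onset_s * fs) + 1L
    probes$onset_sample <- round(probes$onset_s * fs) + 1L
    rownames(events) <- rownames(probes) <- NULL
    list(events = events, probes = probes)
  })
}

#' Generate a complete synthetic SART session
#'
#' @param config [session_config()].
#' @return object of class `mind_recording`: a list with `data` (channels x
#'   samples matrix, uV), `fs`, `channels` (layout data.frame), `events`,
#'   `probes`, `truth_states` (per-sample latent state; generator ground
#'   truth, not consumed by any analysis stage) and `config`.
#' @examples
#' cfg <- session_config(n_blocks = 1, block_duration = 30, seed = 7)
#' rec <- generate_session(cfg)
#' dim(rec$data)
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  fs <- config$fs
  n <- round(config$block_duration * fs) * config$n_blocks
  layout <- channel_layout(config$n_channels)
  truth <- generate_state_timecourse(config)
  evp <- generate_events(config, truth)

  data <- NULL
  if (isTRUE(config$synth_eeg)) {
    data <- with_seed(child_seed(config$seed, 3L), {
      bands <- default_bands()
      n_ch <- config$n_channels
      X <- matrix(0, n_ch, n)
      state_idx <- as.integer(truth)              # 1=ON 2=MW 3=MB per sample
      row_idx <- as.integer(layout$row)
      f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
      f <- pmin(f, fs - f)                        # physical frequency per bin
      bg_gain <- numeric(n)
      sel <- f >= 1 & f <= 45
      bg_gain[sel] <- f[sel]^(-0.5)               # 1/f power background
      band_sel <- lapply(seq_len(nrow(bands)), function(b)
        f >= bands$f_lo[b] & f <= bands$f_hi[b])
      # per-band per-sample gain, per channel row:
      # gain = base_amp[b] * sqrt(band_power_map[state, b, row])
      for (ch in seq_len(n_ch)) {
        # disjoint frequency bands of one white-noise draw are independent,
        # so a single FFT supplies all five band-limited oscillations
        W <- stats::fft(stats::rnorm(n))
        x <- Re(stats::fft(stats::fft(stats::rnorm(n)) * bg_gain,
                           inverse = TRUE)) / n
        x <- config$bg_amp * x / stats::sd(x)
        for (b in seq_len(nrow(bands))) {
          osc <- Re(stats::fft(W * band_sel[[b]], inverse = TRUE)) / n
          osc <- osc / stats::sd(osc)
          relp <- vapply(MIND_STATES, function(s)
            config$state_params[[s]]$band_power_map[b, row_idx[ch]], 1.0)
          gain <- config$base_band_amp[b] * sqrt(relp)[state_idx]
          x <- x + osc * gain
        }
        nsd <- vapply(MIND_STATES, function(s)
          config$state_params[[s]]$noise_sd, 1.0)[state_idx]
        X[ch, ] <- x + stats::rnorm(n) * nsd
      }
      # planted fronto-parietal coupling (alpha-band sources)
      pairs <- planted_pairs(layout)
      lag_nl <- max(1L, round(fs * 0.025))        # quarter cycle at 10 Hz
      lin_g <- vapply(MIND_STATES, function(s)
        config$state_params[[s]]$linear_coupling, 1.0)[state_idx]
      nl_g <- vapply(MIND_STATES, function(s)
        config$state_params[[s]]$nonlinear_coupling, 1.0)[state_idx]
      for (p in seq_len(nrow(pairs))) {
        s_lin <- spectral_noise(n, fs, 8, 12)
        g <- config$couple_amp * lin_g
        X[pairs[p, 1], ] <- X[pairs[p, 1], ] + s_lin * g
        X[pairs[p, 2], ] <- X[pairs[p, 2], ] + s_lin * g
        s_nl <- spectral_noise(n, fs, 8, 12)
        s_nl_lag <- c(rep(0, lag_nl), s_nl[seq_len(n - lag_nl)])
        g <- config$couple_amp * nl_g
        X[pairs[p, 1], ] <- X[pairs[p, 1], ] + s_nl * g
        X[pairs[p, 2], ] <- X[pairs[p, 2], ] + cubic_distort(s_nl_lag) * g
      }
      # stimulus-locked ERP templates, precomputed per state x category
      stim <- evp$events[evp$events$kind == "stimulus", , drop = FALSE]
      post <- c(row_channels(layout, "parietal"), row_channels(layout, "occipital"))
      cent <- row_channels(layout, "central")
      t_rel <- seq(0, 0.8, by = 1 / fs)
      tmpl <- list()
      for (s in MIND_STATES) for (cat in c("face", "digit")) {
        sp <- config$state_params[[s]]
        csign <- if (cat == "face") 0.5 else -0.5
        tmpl[[paste0(s, cat)]] <- list(
          post = erp_bump(t_rel, 0.07, 0.10, sp$p1_amp) +
            erp_bump(t_rel, 0.15, 0.10, csign * sp$cat_early_amp),
          cent = erp_bump(t_rel, sp$p3b_latency / 1000,
                          sp$p3b_duration / 1000, sp$p3b_amp) +
            erp_bump(t_rel, sp$cat_late_window[1],
                     diff(sp$cat_late_window), csign * sp$cat_late_amp))
      }
      for (i in seq_len(nrow(stim))) {
        s0 <- stim$onset_sample[i]
        idx <- s0:min(n, s0 + length(t_rel) - 1L)
        tm <- tmpl[[paste0(truth[s0], stim$category[i])]]
        X[post, idx] <- X[post, idx] +
          matrix(tm$post[seq_along(idx)], length(post), length(idx),
                 byrow = TRUE)
        X[cent, idx] <- X[cent, idx] +
          matrix(tm$cent[seq_along(idx)], length(cent), length(idx),
                 byrow = TRUE)
      }
      rownames(X) <- layout$name
      X
    })
  }

  structure(list(data = data, fs = fs, channels = layout,
                 events = evp$events, probes = evp$probes,
                 truth_states = truth, n_samples = n, config = config),
            class = "mind_recording")
}

#' @export
print.mind_recording <- function(x, ...) {
  cat(sprintf(
    "<mind_recording> %d ch x %d samples @ %g Hz (%.1f min), %d stimuli, %d probes\n",
    nrow(x$channels), x$n_samples, x$fs, x$n_samples / x$fs / 60,
    sum(x$events$kind == "stimulus"), nrow(x$probes)))
  invisible(x)
}
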