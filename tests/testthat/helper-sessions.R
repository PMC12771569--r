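# Shared synthetic sessions, generated once per test run and memoized.
# Keep these small: most tests need only a handful of epochs.

.session_cache <- new.env(parent = emptyenv())

cached_session <- function(key, config) {
  if (is.null(.session_cache[[key]]))
    .session_cache[[key]] <- generate_session(config)
  .session_cache[[key]]
}

small_session <- function(seed = 101, ...) {
  cached_session(paste0("small_", seed),
                 session_config(n_blocks = 2, block_duration = 90,
                                seed = seed, ...))
}

state_session <- function(state, seed = 202, block_duration = 100) {
  cached_session(paste0(state, "_", seed, "_", block_duration),
                 session_config(n_blocks = 2, block_duration = block_duration,
                                seed = seed, fixed_state = state))
}

# deterministic hand-built recording for event-logic tests: stimuli and
# probes at exactly known times, no EEG realism needed
toy_recording <- function(fs = 100, dur = 60,
                          stim_s = c(2, 10, 20, 24.8, 31, 44, 55),
                          probe_s = c(28, 50),
                          probe_answer = c("MW", "DR")) {
  n <- dur * fs
  events <- data.frame(
    onset_s = stim_s, kind = "stimulus",
    category = rep(c("face", "digit"), length.out = length(stim_s)),
    go_nogo = rep("go", length(stim_s)),
    rt_ms = 400, responded = TRUE, block = 1L, stringsAsFactors = FALSE)
  events$onset_sample <- round(events$onset_s * fs) + 1L
  probes <- data.frame(
    onset_s = probe_s, answer = probe_answer,
    vigilance = 3L, block = 1L, stringsAsFactors = FALSE)
  probes$onset_sample <- round(probes$onset_s * fs) + 1L
  structure(list(
    data = matrix(stats::rnorm(4 * n), 4, n,
                  dimnames = list(c("F1", "C1", "P1", "O1"), NULL)),
    fs = fs, channels = channel_layout(4),
    events = events, probes = probes,
    truth_states = factor(rep("ON", n), levels = c("ON", "MW", "MB")),
    n_samples = n, config = NULL), class = "mind_recording")
}
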