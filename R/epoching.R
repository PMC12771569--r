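# Epoching and the 5-second trial-labeling rule.
#
# Window convention: half-open [lo, hi) seconds relative to the anchor;
# a window of w seconds spans round(w * fs) samples, the anchor sample
# being the first sample at or after the anchor time. The 5-s labeling
# boundary is inclusive (a stimulus exactly 5 s before a probe is labeled).

new_epoch_set <- function(data, fs, window, metadata) {
  stopifnot(length(dim(data)) == 3, nrow(metadata) == dim(data)[1])
  structure(list(data = data, fs = fs, window = window,
                 times = window[1] + (seq_len(dim(data)[3]) - 1) / fs,
                 metadata = metadata),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples, window [%g, %g) s\n",
              d[1], d[2], d[3], x$window[1], x$window[2]))
  if ("state_label" %in% names(x$metadata))
    print(table(x$metadata$state_label, useNA = "ifany"))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param epochs `epoch_set`.
#' @return integer trial count.
#' @export
n_epochs <- function(epochs) dim(epochs$data)[1]

#' Subset an epoch set by trial index
#' @param epochs `epoch_set`.
#' @param i trial indices (logical or integer).
#' @return `epoch_set` with the selected trials.
#' @export
subset_epochs <- function(epochs, i) {
  md <- epochs$metadata[i, , drop = FALSE]
  rownames(md) <- NULL
  new_epoch_set(epochs$data[i, , , drop = FALSE], epochs$fs, epochs$window, md)
}

# merge rule for probe answers: "don't remember" is counted as mind blanking
merge_dr <- function(answers) ifelse(answers == "DR", "MB", answers)

#' Cut one epoch per probe from the preceding window
#'
#' Each probe yields an epoch covering `[probe_onset - window_s,
#' probe_onset)` labeled with the probe's (merged) answer; "don't remember"
#' answers are merged into MB. Probes too close to the recording start are
#' skipped with a warning.
#'
#' @param recording `mind_recording`.
#' @param window_s pre-probe window length, s (default 5).
#' @return `epoch_set` with metadata columns `state_label`, `vigilance`,
#'   `block`, `probe_onset_sample`.
#' @export
epoch_preprobe <- function(recording, window_s = 5) {
  if (is.null(recording$data)) stopf("recording has no EEG data")
  pr <- recording$probes
  if (nrow(pr) == 0) stopf("recording has no probes")
  w <- round(window_s * recording$fs)
  starts <- pr$onset_sample - w
  keep <- starts >= 1
  if (any(!keep))
    warnf("%d probe(s) too close to recording start; skipped", sum(!keep))
  pr <- pr[keep, , drop = FALSE]
  starts <- starts[keep]
  if (nrow(pr) == 0) stopf("no probe window fits within the recording")
  data <- array(NA_real_, c(nrow(pr), nrow(recording$data), w))
  for (i in seq_len(nrow(pr)))
    data[i, , ] <- recording$data[, starts[i]:(pr$onset_sample[i] - 1L)]
  md <- data.frame(
    trial_id = paste0("probe_", seq_len(nrow(pr))),
    state_label = merge_dr(pr$answer),
    vigilance = pr$vigilance, block = pr$block,
    probe_onset_sample = pr$onset_sample, stringsAsFactors = FALSE)
  new_epoch_set(data, recording$fs, c(-window_s, 0), md)
}

#' Cut stimulus-centered epochs
#'
#' One epoch per stimulus covering `[window[1], window[2])` seconds around
#' stimulus onset; trials whose window does not fit in the recording are
#' skipped. Metadata carries stimulus category, Go/No-Go, RT, response flag
#' and block.
#'
#' @param recording `mind_recording`.
#' @param window epoch window in s relative to stimulus onset,
#'   default `c(-0.25, 0.75)`.
#' @return `epoch_set`; `state_label` initialized to `"unlabeled"` (fill it
#'   with [label_trials()]).
#' @export
epoch_stimuli <- function(recording, window = c(-0.25, 0.75)) {
  if (is.null(recording$data)) stopf("recording has no EEG data")
  stim <- recording$events[recording$events$kind == "stimulus", , drop = FALSE]
  if (nrow(stim) == 0) stopf("recording has no stimulus events")
  fs <- recording$fs
  n_time <- round((window[2] - window[1]) * fs)
  starts <- stim$onset_sample + round(window[1] * fs)
  keep <- starts >= 1 & (starts + n_time - 1L) <= ncol(recording$data)
  stim <- stim[keep, , drop = FALSE]
  starts <- starts[keep]
  data <- array(NA_real_, c(nrow(stim), nrow(recording$data), n_time))
  for (i in seq_len(nrow(stim)))
    data[i, , ] <- recording$data[, starts[i]:(starts[i] + n_time - 1L)]
  md <- data.frame(
    trial_id = paste0("stim_", seq_len(nrow(stim))),
    onset_sample = stim$onset_sample,
    stimulus_category = stim$category, go_nogo = stim$go_nogo,
    rt_ms = stim$rt_ms,
    responded = if ("responded" %in% names(stim)) stim$responded
                else !is.na(stim$rt_ms),
    block = stim$block,
    state_label = "unlabeled", time_to_probe = NA_real_,
    stringsAsFactors = FALSE)
  new_epoch_set(data, fs, window, md)
}

#' Label stimulus trials from the following probe (5-second rule)
#'
#' A stimulus trial receives the next probe's merged answer iff
#' `0 < probe_onset - stimulus_onset <= window_s` seconds; all other trials
#' stay `"unlabeled"`. When probe windows overlap (inter-probe interval
#' below `window_s`) the nearest following probe wins, with a warning.
#'
#' @param stim_epochs `epoch_set` from [epoch_stimuli()].
#' @param probes probe table with `onset_sample` and `answer` (e.g.
#'   `recording$probes`).
#' @param fs sampling rate, Hz (defaults to the epoch set's).
#' @param window_s labeling window, s (default 5, inclusive).
#' @return `epoch_set` with `state_label` and `time_to_probe` filled.
#' @export
label_trials <- function(stim_epochs, probes, fs = stim_epochs$fs,
                         window_s = 5) {
  stopifnot(inherits(stim_epochs, "epoch_set"))
  md <- stim_epochs$metadata
  probes <- probes[order(probes$onset_sample), , drop = FALSE]
  if (nrow(probes) > 1 &&
      any(diff(probes$onset_sample) < window_s * fs))
    warnf("probe windows overlap; nearest-following probe wins")
  w <- window_s * fs
  md$state_label <- "unlabeled"
  md$time_to_probe <- NA_real_
  if (nrow(probes)) {
    # index of the first probe at or after each stimulus onset
    nxt <- findInterval(md$onset_sample - 0.5, probes$onset_sample) + 1L
    ok <- nxt <= nrow(probes)
    gap <- rep(NA_real_, nrow(md))
    gap[ok] <- probes$onset_sample[nxt[ok]] - md$onset_sample[ok]
    lab <- ok & !is.na(gap) & gap > 0 & gap <= w
    md$state_label[lab] <- merge_dr(probes$answer[nxt[lab]])
    md$time_to_probe[lab] <- gap[lab] / fs
  }
  out <- stim_epochs
  out$metadata <- md
  out
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window
#' (half-open, in epoch-relative seconds). Idempotent.
#'
#' @param epochs `epoch_set`.
#' @param baseline window in s, default `c(-0.25, 0)`.
#' @return baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, baseline = c(-0.25, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (baseline[1] < epochs$window[1] || baseline[2] > epochs$window[2])
    stopf("baseline window outside epoch window")
  sel <- epochs$times >= baseline[1] & epochs$times < baseline[2]
  if (!any(sel)) stopf("empty baseline window")
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  out <- epochs
  out$data <- epochs$data - array(bl, dim(epochs$data))
  out
}
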