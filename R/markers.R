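# Per-trial, per-channel spectral and complexity markers.

#' Welch power spectral density estimate
#'
#' Hann-windowed, mean-detrended, 50%-overlapping segments; one-sided
#' density scaled so that `sum(psd) * df` approximates the signal variance
#' (Parseval).
#'
#' @param x numeric time series.
#' @param fs sampling rate, Hz.
#' @param nperseg segment length in samples (default: one second of data,
#'   capped at the series length).
#' @param overlap fractional overlap between segments, default 0.5.
#' @return list with `freq` (Hz) and `psd` (uV^2/Hz), class `welch_psd`.
#' @examples
#' sp <- psd_welch(sin(2 * pi * 10 * seq(0, 5, by = 1/250)), fs = 250)
#' sp$freq[which.max(sp$psd)]   # 10 Hz
#' @export
psd_welch <- function(x, fs, nperseg = min(length(x), round(fs)),
                      overlap = 0.5) {
  n <- length(x)
  if (n < nperseg)
    stopf("series length %d below nperseg = %d", n, nperseg)
  step <- max(1L, round(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nperseg) / (nperseg + 1)))  # Hann
  u <- sum(w^2)
  nf <- floor(nperseg / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / (fs * u)
    acc <- acc + p[seq_len(nf)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nperseg even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nperseg %% 2 == 0) dbl[nf] <- 1
  psd <- psd * dbl
  structure(list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = psd,
                 df = fs / nperseg, n_segments = length(starts)),
            class = "welch_psd")
}

#' Normalized band power fractions
#'
#' Integrates the PSD over each band (bins with `f_lo <= f < f_hi`) and
#' divides by the integral over the union of all bands, so fractions sum
#' to one.
#'
#' @param spectrum `welch_psd` from [psd_welch()].
#' @param bands band data.frame (see [default_bands()]).
#' @return named numeric vector of fractions summing to 1.
#' @export
normalized_band_power <- function(spectrum, bands = default_bands()) {
  validate_bands(bands)
  sel <- lapply(seq_len(nrow(bands)), function(i)
    spectrum$freq >= bands$f_lo[i] & spectrum$freq < bands$f_hi[i])
  if (any(vapply(sel, sum, 1L) == 0))
    stopf("band with no spectral bins (frequency resolution %g Hz)",
          spectrum$df)
  pw <- vapply(sel, function(s) sum(spectrum$psd[s]), 1.0)
  tot <- sum(pw)
  out <- if (tot > 0) pw / tot else rep(1 / length(pw), length(pw))
  names(out) <- bands$name
  out
}

#' Sample entropy
#'
#' `SE = -ln(A/B)` where `B` counts template pairs of length `m` within
#' Chebyshev distance `r_factor * SD(x)` and `A` the same pairs still
#' matching at length `m + 1`; self-matches excluded, both counts taken
#' over templates starting at `1 .. n - m`. Degenerate inputs (no matches)
#' return `NA` (a flagged sentinel, excluded from aggregation downstream).
#'
#' @param x numeric series (length >= 10 * m).
#' @param m template length, default 2.
#' @param r_factor tolerance as a fraction of the series SD, default 0.2.
#' @param r absolute tolerance; overrides `r_factor` when given.
#' @return sample entropy in nats (>= 0), or `NA` if degenerate.
#' @export
sample_entropy <- function(x, m = 2, r_factor = 0.2, r = NULL) {
  if (length(x) < 10 * m)
    stopf("series length %d below minimum %d (= 10 * m)", length(x), 10 * m)
  if (is.null(r)) r <- r_factor * stats::sd(x)
  .sampen_cpp(as.numeric(x), as.integer(m), as.numeric(r))
}

#' Compression-based Kolmogorov complexity proxy
#'
#' Binarizes the series around its median (`>= median` maps to 1), packs
#' the bits into bytes and compresses with gzip (DEFLATE); the returned
#' ratio `compressed_bytes / packed_bytes` is small for regular signals and
#' close to (or above) 1 for incompressible ones.
#'
#' @param x numeric series (length >= 64).
#' @return positive compression ratio.
#' @export
kolmogorov_complexity <- function(x) {
  if (length(x) < 64) stopf("series length %d below minimum 64", length(x))
  bits <- as.integer(x >= stats::median(x))
  pad <- (8 - length(bits) %% 8) %% 8
  packed <- packBits(as.raw(c(bits, rep(0L, pad))), type = "raw")
  length(memCompress(packed, type = "gzip")) / length(packed)
}

# batched Welch PSD over the rows of a channels x time matrix; same
# estimator as psd_welch() but with one mvfft per segment
psd_welch_matrix <- function(X, fs, nperseg, overlap = 0.5) {
  n <- ncol(X)
  step <- max(1L, round(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nperseg) / (nperseg + 1)))
  u <- sum(w^2)
  nf <- floor(nperseg / 2) + 1L
  acc <- matrix(0, nrow(X), nf)
  for (s in starts) {
    seg <- t(X[, s:(s + nperseg - 1L), drop = FALSE])
    seg <- sweep(seg, 2, colMeans(seg)) * w
    P <- Mod(stats::mvfft(seg))^2 / (fs * u)
    acc <- acc + t(P[seq_len(nf), , drop = FALSE])
  }
  acc <- acc / length(starts)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nperseg %% 2 == 0) dbl[nf] <- 1
  sweep(acc, 2, dbl, "*")
}

#' Compute the per-trial, per-channel marker matrix
#'
#' For every trial and channel: normalized PSD fractions in the five bands
#' (Welch, 1-s Hann segments with 50% overlap, halved to 0.5 s for epochs
#' shorter than 2 s), sample entropy and compression complexity.
#'
#' @param epochs `epoch_set`.
#' @param bands band data.frame, default [default_bands()].
#' @param sampen_m,sampen_r_factor sample-entropy parameters.
#' @return object of class `marker_matrix`: list with `values` (trials x
#'   channels x markers array), `marker_names`, `channels`, `metadata`.
#' @export
compute_marker_matrix <- function(epochs, bands = default_bands(),
                                  sampen_m = 2, sampen_r_factor = 0.2) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  if (d[1] == 0) stopf("empty epoch set")
  validate_bands(bands, epochs$fs)
  nper <- if (d[3] >= 2 * epochs$fs) round(epochs$fs) else round(epochs$fs / 2)
  marker_names <- c(paste0("psd_", bands$name), "sampen", "kc")
  vals <- array(NA_real_, c(d[1], d[2], length(marker_names)),
                dimnames = list(NULL, NULL, marker_names))
  nb <- nrow(bands)
  nper <- min(nper, d[3])
  freqs <- (seq_len(floor(nper / 2) + 1L) - 1L) * epochs$fs / nper
  band_bins <- lapply(seq_len(nb), function(b)
    which(freqs >= bands$f_lo[b] & freqs < bands$f_hi[b]))
  if (any(lengths(band_bins) == 0))
    stopf("band with no spectral bins (frequency resolution %g Hz)",
          epochs$fs / nper)
  for (i in seq_len(d[1])) {
    X <- epochs$data[i, , , drop = FALSE]
    dim(X) <- d[2:3]
    P <- psd_welch_matrix(X, epochs$fs, nper)
    bp <- vapply(band_bins, function(bi)
      rowSums(P[, bi, drop = FALSE]), numeric(d[2]))
    vals[i, , seq_len(nb)] <- bp / rowSums(bp)
    for (ch in seq_len(d[2])) {
      vals[i, ch, nb + 1L] <- sample_entropy(X[ch, ], m = sampen_m,
                                             r_factor = sampen_r_factor)
      vals[i, ch, nb + 2L] <- kolmogorov_complexity(X[ch, ])
    }
  }
  n_flag <- sum(is.na(vals))
  if (n_flag / length(vals) > 0.2)
    warnf("flagged-sentinel fraction %.1f%% exceeds 20%%",
          100 * n_flag / length(vals))
  structure(list(values = vals, marker_names = marker_names,
                 channels = if (!is.null(rownames(epochs$data)))
                   rownames(epochs$data) else paste0("ch", seq_len(d[2])),
                 metadata = epochs$metadata, bands = bands),
            class = "marker_matrix")
}

#' Tidy export of a marker matrix
#'
#' @param markers `marker_matrix`.
#' @return data.frame with one row per trial x channel x marker.
#' @export
marker_long <- function(markers) {
  d <- dim(markers$values)
  out <- expand.grid(trial = seq_len(d[1]), channel = seq_len(d[2]),
                     marker = markers$marker_names,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$value <- as.vector(markers$values)
  out$trial_id <- markers$metadata$trial_id[out$trial]
  if ("state_label" %in% names(markers$metadata))
    out$state_label <- markers$metadata$state_label[out$trial]
  out
}
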