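# Symbolic transform, weighted symbolic mutual information (wSMI),
# phase-locking value (PLV), and ROI aggregation.
#
# Symbol alphabet (k = 3): the six rank-order patterns of the triple
# (x[t], x[t + tau], x[t + 2 tau]), identified in lexicographic order of
# their rank vectors:
#   1 = (1,2,3)  2 = (1,3,2)  3 = (2,1,3)  4 = (2,3,1)  5 = (3,1,2)  6 = (3,2,1)
# Ties break earlier-index-smaller. The "opposite" of a pattern is its
# rank-reversed partner (the pattern of -x), i.e. opposite(i) = 7 - i.
# wSMI assigns weight 0 to identical and opposite symbol pairs (the pairs
# that trivially arise from volume conduction) and weight 1 otherwise.

SYMBOL_CODES <- c(123, 132, 213, 231, 312, 321)

wsmi_weight_matrix <- function() {
  w <- matrix(1, 6, 6)
  diag(w) <- 0
  for (i in 1:6) w[i, 7 - i] <- 0
  w
}
WSMI_W <- wsmi_weight_matrix()

#' Symbolic (rank-pattern) transform of a time series
#'
#' @param x numeric series.
#' @param k kernel size; only `k = 3` is supported.
#' @param tau lag between kernel samples, in samples.
#' @return integer vector of symbols in 1..6, length `length(x) - (k-1)*tau`,
#'   with attributes `k` and `tau`.
#' @examples
#' symbolic_transform(c(3, 1, 2, 5, 4, 0), tau = 1)
#' @export
symbolic_transform <- function(x, k = 3, tau = 1) {
  if (k != 3) stopf("only k = 3 is supported")
  n <- length(x)
  need <- (k - 1) * tau + 1
  if (n < need)
    stopf("series too short: need >= %d samples for tau = %d", need, tau)
  m <- n - (k - 1) * tau
  a <- x[seq_len(m)]
  b <- x[seq_len(m) + tau]
  c_ <- x[seq_len(m) + 2L * tau]
  # ranks with earlier-index-smaller tie-break
  ra <- 1L + (b < a) + (c_ < a)
  rb <- 1L + (a <= b) + (c_ < b)
  rc <- 1L + (a <= c_) + (b <= c_)
  sym <- match(100L * ra + 10L * rb + rc, SYMBOL_CODES)
  attr(sym, "k") <- k
  attr(sym, "tau") <- tau
  sym
}

# wSMI from two symbol sequences (both 1..6, equal length)
wsmi_from_symbols <- function(sx, sy) {
  n <- length(sx)
  joint <- matrix(tabulate(6L * (sx - 1L) + sy, 36L), 6, 6, byrow = TRUE) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  if (sum(px > 0) < 2 || sum(py > 0) < 2) return(0)  # degenerate
  sel <- joint > 0 & WSMI_W > 0
  sum(joint[sel] * log(joint[sel] / outer(px, py)[sel])) / log(6)
}

#' Weighted symbolic mutual information between two series
#'
#' Symbolizes both series (same `tau`), estimates the joint symbol
#' distribution by maximum likelihood and computes
#' `wSMI = (1/ln 6) * sum w(i,j) p(i,j) ln(p(i,j) / (p(i) p(j)))` with
#' weight 0 for identical or rank-reversed symbol pairs. Degenerate inputs
#' (a single symbol on either side) return 0.
#'
#' @param x,y numeric series of equal length.
#' @param k kernel size (3).
#' @param tau lag in samples.
#' @return wSMI in normalized nats (<= 1); exactly 0 for `y = x` or `y = -x`.
#' @export
wsmi <- function(x, y, k = 3, tau = 1) {
  if (length(x) != length(y)) stopf("series lengths differ")
  wsmi_from_symbols(symbolic_transform(x, k, tau),
                    symbolic_transform(y, k, tau))
}

# zero-phase FIR band-pass (Hamming-design via signal::fir1), reflection
# padding; filter order = 3 cycles of f_lo, capped to fit the series
band_filter <- function(x, band, fs) {
  n <- length(x)
  ord <- round(3 * fs / band$f_lo[1])
  ord <- min(ord, floor((n - 1) / 3))
  ord <- max(10L, ord - ord %% 2L)               # even order, >= 10
  b <- signal::fir1(ord, c(band$f_lo[1], band$f_hi[1]) / (fs / 2),
                    type = "pass")
  pad <- min(n - 1L, 3L * ord)
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1L):n]))
  yp <- signal::filtfilt(b, xp)   # fir1 returns an Ma object
  yp[(pad + 1L):(pad + n)]
}

# analytic signal via FFT (Hilbert transform)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Phase-locking value between two series in a band
#'
#' Band-passes both series (zero-phase FIR), extracts instantaneous phase
#' from the analytic signal, discards 10% of samples at each edge and
#' returns the resultant length of the phase difference.
#'
#' @param x,y numeric series of equal length.
#' @param band one-row band data.frame or band name.
#' @param fs sampling rate, Hz.
#' @param filter set `FALSE` if the inputs are already narrowband.
#' @return PLV in \[0, 1\]; `NA` for zero-variance input.
#' @export
plv <- function(x, y, band = "alpha", fs, filter = TRUE) {
  if (length(x) != length(y)) stopf("series lengths differ")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  if (is.character(band)) band <- default_bands(band)
  if (filter) {
    x <- band_filter(x, band, fs)
    y <- band_filter(y, band, fs)
  }
  phx <- Arg(analytic_signal(x))
  phy <- Arg(analytic_signal(y))
  n <- length(x)
  trim <- floor(0.1 * n)
  keep <- (trim + 1L):(n - trim)
  Mod(mean(exp(1i * (phx[keep] - phy[keep]))))
}

#' Per-trial band-limited connectivity over an epoch set
#'
#' Band-passes every channel (zero-phase FIR), then computes the requested
#' metric for each channel pair: wSMI with the band's symbolization lag
#' (see [tau_for_band()]) or PLV.
#'
#' @param epochs `epoch_set`.
#' @param band band name or one-row band data.frame.
#' @param metric `"wsmi"` or `"plv"`.
#' @param pairs optional two-column matrix of channel index pairs; default
#'   all pairs.
#' @param filter band-pass before symbolizing (default TRUE; set FALSE to
#'   rely on tau-selection alone, e.g. for short epochs).
#' @return object of class `connectivity_result`: `matrices` is a
#'   trials x channels x channels array, symmetric with zero (wsmi) or
#'   unit (plv) diagonal; entries outside `pairs` are `NA` when `pairs`
#'   is given.
#' @export
band_connectivity <- function(epochs, band, metric = c("wsmi", "plv"),
                              pairs = NULL, filter = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  metric <- match.arg(metric)
  if (is.character(band)) band <- default_bands(band)
  validate_bands(band, epochs$fs)
  d <- dim(epochs$data)
  tau <- tau_for_band(band, epochs$fs)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(d[2], 2))
  }
  mats <- array(NA_real_, c(d[1], d[2], d[2]))
  for (i in seq_len(d[1])) {
    sig <- lapply(seq_len(d[2]), function(ch) {
      x <- epochs$data[i, ch, ]
      if (filter) band_filter(x, band, epochs$fs) else x
    })
    m <- matrix(NA_real_, d[2], d[2])
    diag(m) <- if (metric == "wsmi") 0 else 1
    if (metric == "wsmi") {
      syms <- lapply(sig, symbolic_transform, k = 3, tau = tau)
      for (p in seq_len(nrow(pairs))) {
        v <- wsmi_from_symbols(syms[[pairs[p, 1]]], syms[[pairs[p, 2]]])
        m[pairs[p, 1], pairs[p, 2]] <- m[pairs[p, 2], pairs[p, 1]] <- v
      }
    } else {
      for (p in seq_len(nrow(pairs))) {
        v <- plv(sig[[pairs[p, 1]]], sig[[pairs[p, 2]]], band,
                 epochs$fs, filter = FALSE)
        m[pairs[p, 1], pairs[p, 2]] <- m[pairs[p, 2], pairs[p, 1]] <- v
      }
    }
    mats[i, , ] <- m
  }
  structure(list(band = band, metric = metric, matrices = mats,
                 node_kind = "channel",
                 nodes = if (!is.null(rownames(epochs$data)))
                   rownames(epochs$data) else paste0("ch", seq_len(d[2])),
                 metadata = epochs$metadata, tau = tau),
            class = "connectivity_result")
}

#' Band-limited wSMI over an epoch set
#' @inheritParams band_connectivity
#' @return `connectivity_result` with `metric = "wsmi"`.
#' @export
band_wsmi <- function(epochs, band, pairs = NULL, filter = TRUE)
  band_connectivity(epochs, band, "wsmi", pairs, filter)

#' Band-limited PLV over an epoch set
#' @inheritParams band_connectivity
#' @return `connectivity_result` with `metric = "plv"`.
#' @export
band_plv <- function(epochs, band, pairs = NULL, filter = TRUE)
  band_connectivity(epochs, band, "plv", pairs, filter)

#' Source-to-ROI assignment scheme
#'
#' Ten regions of interest: five lobes (frontal, limbic, temporal,
#' parietal, occipital) by hemisphere (left/right), over `n_sources`
#' cortical sources (default 68), yielding 45 unordered ROI pairs.
#'
#' @param n_sources number of source signals (default 68).
#' @return list with `roi_names` (length 10) and `assignment` (integer ROI
#'   index per source), class `roi_scheme`.
#' @export
roi_scheme <- function(n_sources = 68) {
  lobes <- c("frontal", "limbic", "temporal", "parietal", "occipital")
  roi_names <- as.vector(outer(lobes, c("L", "R"), paste, sep = "_"))
  # fixed per-lobe counts per hemisphere summing to n_sources / 2
  half <- n_sources / 2
  if (half < 5 || n_sources %% 2 != 0)
    stopf("n_sources must be even with at least 5 sources per hemisphere")
  base <- c(8, 6, 7, 7, 6)
  counts <- pmax(1, floor(base / sum(base) * half))
  while (sum(counts) < half) {
    i <- which.max(base / sum(base) * half - counts)
    counts[i] <- counts[i] + 1
  }
  while (sum(counts) > half) {
    i <- which.max(counts)
    counts[i] <- counts[i] - 1
  }
  assignment <- c(rep(1:5, counts), rep(6:10, counts))
  structure(list(roi_names = roi_names, assignment = assignment,
                 n_sources = n_sources), class = "roi_scheme")
}

#' Aggregate a source-level connectivity matrix to ROI pairs
#'
#' ROI-pair value = mean of all source-pair values with one endpoint in
#' each ROI; the diagonal holds within-ROI means but is excluded from the
#' 45-connection set reported by [roi_pairs_long()].
#'
#' @param source_mat symmetric sources x sources matrix.
#' @param scheme `roi_scheme`.
#' @return 10 x 10 symmetric matrix with ROI names.
#' @export
roi_aggregate <- function(source_mat, scheme) {
  stopifnot(inherits(scheme, "roi_scheme"),
            nrow(source_mat) == scheme$n_sources)
  k <- length(scheme$roi_names)
  out <- matrix(NA_real_, k, k, dimnames = list(scheme$roi_names,
                                                scheme$roi_names))
  for (i in seq_len(k)) for (j in i:k) {
    si <- which(scheme$assignment == i)
    sj <- which(scheme$assignment == j)
    block <- source_mat[si, sj, drop = FALSE]
    if (i == j) block <- block[upper.tri(block)]
    out[i, j] <- out[j, i] <- mean(block, na.rm = TRUE)
  }
  out
}

#' The 45 off-diagonal ROI connections as a long table
#' @param roi_mat 10 x 10 matrix from [roi_aggregate()].
#' @return data.frame with `roi_a`, `roi_b`, `value` (45 rows).
#' @export
roi_pairs_long <- function(roi_mat) {
  idx <- which(upper.tri(roi_mat), arr.ind = TRUE)
  data.frame(roi_a = rownames(roi_mat)[idx[, 1]],
             roi_b = colnames(roi_mat)[idx[, 2]],
             value = roi_mat[idx], stringsAsFactors = FALSE)
}

#' PLV / wSMI state-contrast tables (dissociation check)
#'
#' For each metric and connection, the mean difference between two states'
#' per-trial connectivity. On sessions with the planted mind-blanking
#' coupling profile (strong zero-lag linear coupling, little nonlinear
#' coupling), the MB-vs-ON contrast is positive for PLV and negative for
#' wSMI on the planted pairs.
#'
#' @param epochs labeled `epoch_set` (metadata column `state_label`).
#' @param band band name or one-row data.frame.
#' @param pairs two-column matrix of channel pairs to evaluate (default:
#'   all pairs).
#' @param state_pairs list of length-2 state vectors to contrast, default
#'   `list(c("MB", "ON"))`.
#' @return data.frame with columns `metric`, `state_a`, `state_b`,
#'   `node_a`, `node_b`, `delta` (mean a - mean b).
#' @export
plv_wsmi_dissociation_check <- function(epochs, band = "alpha", pairs = NULL,
                                        state_pairs = list(c("MB", "ON"))) {
  labs <- epochs$metadata$state_label
  present <- intersect(MIND_STATES, unique(labs))
  if (length(present) < 2) stopf("need at least two states present, have: %s",
                                 paste(present, collapse = ", "))
  if (is.null(pairs)) pairs <- t(utils::combn(dim(epochs$data)[2], 2))
  res <- list()
  for (metric in c("plv", "wsmi")) {
    conn <- band_connectivity(epochs, band, metric, pairs = pairs)
    for (sp in state_pairs) {
      if (!all(sp %in% present)) {
        ms_log("state pair ", paste(sp, collapse = "-"),
               " not fully present; contrast skipped")
        next
      }
      ma <- apply(conn$matrices[labs == sp[1], , , drop = FALSE], c(2, 3),
                  mean, na.rm = TRUE)
      mb <- apply(conn$matrices[labs == sp[2], , , drop = FALSE], c(2, 3),
                  mean, na.rm = TRUE)
      delta <- ma - mb
      res[[length(res) + 1L]] <- data.frame(
        metric = metric, state_a = sp[1], state_b = sp[2],
        node_a = conn$nodes[pairs[, 1]], node_b = conn$nodes[pairs[, 2]],
        delta = delta[pairs], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}
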