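# ERP averages/contrasts and per-timepoint MVPA decoding of stimulus
# category with a permutation chance distribution.

#' Grand-average ERPs by group
#'
#' @param epochs baseline-corrected `epoch_set`.
#' @param group_by metadata column to average within, default
#'   `"state_label"`.
#' @param category optional stimulus-category filter (`"face"`/`"digit"`).
#' @return object of class `erp_result`: list of per-group mean waveforms
#'   (channels x time), trial counts, times.
#' @export
compute_erp <- function(epochs, group_by = "state_label", category = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  md <- epochs$metadata
  keep <- rep(TRUE, nrow(md))
  if (!is.null(category)) keep <- md$stimulus_category == category
  groups <- setdiff(unique(md[[group_by]][keep]), NA)
  means <- list(); counts <- integer(0)
  for (g in groups) {
    sel <- keep & md[[group_by]] == g
    if (!any(sel)) { warnf("group %s empty; omitted", g); next }
    means[[g]] <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
    counts[g] <- sum(sel)
  }
  structure(list(means = means, counts = counts, times = epochs$times,
                 channels = if (!is.null(rownames(epochs$data)))
                   rownames(epochs$data) else NULL),
            class = "erp_result")
}

# vectorized Welch two-sample t over the trial dimension of two
# trials x channels x time arrays; returns list(effect, p)
welch_t_arrays <- function(A, B) {
  na <- dim(A)[1]; nb <- dim(B)[1]
  mA <- apply(A, c(2, 3), mean); mB <- apply(B, c(2, 3), mean)
  vA <- apply(A, c(2, 3), stats::var); vB <- apply(B, c(2, 3), stats::var)
  se2 <- vA / na + vB / nb
  tstat <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / na)^2 / (na - 1) + (vB / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(effect = mA - mB, p = p)
}

#' Channel x time ERP contrast between two states
#'
#' With multiple subjects: subject-level trial means per state, then a
#' paired t-test across subjects per channel x timepoint. With a single
#' subject (synthetic mode): Welch t-test over trials. P-values are
#' BH-FDR corrected jointly over channels x timepoints; `mask = q < 0.05`.
#'
#' @param epochs baseline-corrected, labeled `epoch_set`.
#' @param pair character vector of two states, e.g. `c("ON", "MB")`;
#'   effect sign is `pair[1] - pair[2]`.
#' @param min_trials minimum trials per state, default 20.
#' @param q FDR level, default 0.05.
#' @return list with `effect`, `p`, `q_values`, `mask` (channels x time
#'   matrices), `times`, `pair`.
#' @export
erp_state_contrast <- function(epochs, pair, min_trials = 20, q = 0.05) {
  labs <- epochs$metadata$state_label
  missing_states <- setdiff(pair, labs)
  if (length(missing_states))
    stopf("state(s) %s absent; present: %s",
          paste(missing_states, collapse = ", "),
          paste(unique(labs), collapse = ", "))
  if (min(sum(labs == pair[1]), sum(labs == pair[2])) < min_trials)
    stopf("fewer than %d trials in one of the states", min_trials)
  subj <- epochs$metadata$subject %||% rep("s1", length(labs))
  if (length(unique(subj)) >= 2) {
    subs <- unique(subj)
    diffs <- array(NA_real_, c(length(subs), dim(epochs$data)[2],
                               dim(epochs$data)[3]))
    for (k in seq_along(subs)) {
      a <- epochs$data[labs == pair[1] & subj == subs[k], , , drop = FALSE]
      b <- epochs$data[labs == pair[2] & subj == subs[k], , , drop = FALSE]
      diffs[k, , ] <- apply(a, c(2, 3), mean) - apply(b, c(2, 3), mean)
    }
    ns <- length(subs)
    m <- apply(diffs, c(2, 3), mean)
    s <- apply(diffs, c(2, 3), stats::sd)
    tstat <- m / (s / sqrt(ns))
    p <- 2 * stats::pt(-abs(tstat), ns - 1)
    res <- list(effect = m, p = p)
  } else {
    res <- welch_t_arrays(epochs$data[labs == pair[1], , , drop = FALSE],
                          epochs$data[labs == pair[2], , , drop = FALSE])
  }
  fdr <- fdr_bh(as.vector(res$p), q = q)
  dims <- dim(res$p)
  list(effect = res$effect, p = res$p,
       q_values = matrix(fdr$q_values, dims[1], dims[2]),
       mask = matrix(fdr$mask, dims[1], dims[2]),
       times = epochs$times, pair = pair)
}

#' Balanced subsampling of trials across groups
#'
#' Downsamples every group, without replacement, to the minimum group
#' size, so downstream comparisons see identical trial counts per group.
#'
#' @param epochs `epoch_set`.
#' @param by metadata grouping column, default `"state_label"`.
#' @param seed integer seed.
#' @return `epoch_set` with balanced groups.
#' @export
balance_subsample <- function(epochs, by = "state_label", seed = 1) {
  g <- epochs$metadata[[by]]
  groups <- setdiff(unique(g), NA)
  if (length(groups) < 2) stopf("need at least two non-empty groups")
  sizes <- table(g)
  if (any(sizes == 0)) stopf("empty group")
  n_min <- min(sizes)
  keep <- with_seed(seed, {
    sort(unlist(lapply(groups, function(gr)
      sample(which(g == gr), n_min))))
  })
  subset_epochs(epochs, keep)
}

# rank-based ROC AUC (equivalent to the Mann-Whitney statistic)
auc_rank <- function(scores, y_pos) {
  r <- rank(scores)
  n_pos <- sum(y_pos); n_neg <- length(y_pos) - n_pos
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  (sum(r[y_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# stratified fold assignment (seeded)
stratified_folds <- function(y, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

# core decoding engine: per-timepoint ridge classifier, stratified CV.
# For each timepoint and fold a linear read-out projector is built from the
# (label-free) training features; scores for the observed labels and any
# number of label permutations then cost one matrix product each, which is
# what makes the permutation null affordable. Y: n x m matrix of +/-1.
decode_engine <- function(data3d, Y, fold, lambda, timepoints) {
  n <- dim(data3d)[1]
  m <- ncol(Y)
  n_folds <- max(fold)
  aucs <- matrix(NA_real_, length(timepoints), m)
  for (ti in seq_along(timepoints)) {
    t <- timepoints[ti]
    X <- data3d[, , t, drop = FALSE]
    dim(X) <- dim(data3d)[1:2]
    scores <- matrix(NA_real_, n, m)
    for (f in seq_len(n_folds)) {
      tr <- fold != f; te <- !tr
      mu <- colMeans(X[tr, , drop = FALSE])
      sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sdv[sdv == 0] <- 1
      Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
      Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sdv, "/")
      ntr <- nrow(Xtr)
      G <- crossprod(Xtr) + lambda * ntr * diag(ncol(Xtr))
      P <- Xte %*% solve(G, t(Xtr))            # nte x ntr projector
      Ytr <- Y[tr, , drop = FALSE]
      Ytr <- sweep(Ytr, 2, colMeans(Ytr))      # center labels per column
      scores[te, ] <- P %*% Ytr
    }
    for (j in seq_len(m))
      aucs[ti, j] <- auc_rank(scores[, j], Y[, j] > 0)
  }
  aucs
}

#' Temporal decoding of a binary trial label
#'
#' At each timepoint, channel amplitudes are the features of a ridge-
#' regularized linear classifier (standardized within training folds,
#' fixed regularization), evaluated by stratified k-fold cross-validated
#' ROC AUC on the pooled held-out scores.
#'
#' @param epochs `epoch_set`.
#' @param label metadata column with exactly two classes, default
#'   `"stimulus_category"`.
#' @param n_folds folds, default 5.
#' @param lambda ridge penalty (per-sample), default 1.
#' @param stride evaluate every `stride`-th timepoint, default 1.
#' @param seed integer seed (fold assignment).
#' @return object of class `decoding_curve`: `times`, `auc`,
#'   `n_per_class`, plus fold/config details used by
#'   [decode_significance()].
#' @export
temporal_decode <- function(epochs, label = "stimulus_category",
                            n_folds = 5, lambda = 1, stride = 1, seed = 1) {
  y <- factor(epochs$metadata[[label]])
  if (nlevels(y) != 2) stopf("label must have exactly 2 classes, has %d",
                             nlevels(y))
  if (min(table(y)) < n_folds)
    stopf("each class needs at least n_folds = %d trials", n_folds)
  fold <- stratified_folds(y, n_folds, seed)
  timepoints <- seq(1L, dim(epochs$data)[3], by = stride)
  Y <- matrix(ifelse(y == levels(y)[2], 1, -1), ncol = 1)
  aucs <- decode_engine(epochs$data, Y, fold, lambda, timepoints)
  structure(list(times = epochs$times[timepoints], auc = aucs[, 1],
                 timepoints = timepoints, fold = fold, lambda = lambda,
                 label = label, y = y, n_per_class = as.vector(table(y)),
                 null_quantiles = NULL, p = NULL, q_values = NULL,
                 significant = NULL),
            class = "decoding_curve")
}

#' Permutation chance level and significance mask for a decoding curve
#'
#' Re-runs the cross-validated decoding with label permutations (folds and
#' standardization fixed, labels shuffled for both training and scoring),
#' computes per-timepoint empirical p-values
#' `p = (1 + #[null >= observed]) / (n_perm + 1)`, BH-FDR across
#' timepoints, and a `q < 0.05` significance mask.
#'
#' @param curve `decoding_curve` from [temporal_decode()].
#' @param epochs the same `epoch_set` the curve was computed from.
#' @param n_perm number of permutations, default 500 (values below 100
#'   warn: unstable tails).
#' @param seed integer seed for the permutations.
#' @param q FDR level, default 0.05.
#' @return the curve with `null_quantiles` (2.5/50/97.5% per timepoint),
#'   `p`, `q_values` and `significant` filled.
#' @export
decode_significance <- function(curve, epochs, n_perm = 500, seed = 1,
                                q = 0.05) {
  stopifnot(inherits(curve, "decoding_curve"))
  if (n_perm < 100) warnf("n_perm = %d < 100: unstable null tails", n_perm)
  y <- curve$y
  y_num <- ifelse(y == levels(y)[2], 1, -1)
  Y <- with_seed(seed, {
    cbind(y_num, vapply(seq_len(n_perm), function(i) sample(y_num),
                        numeric(length(y_num))))
  })
  aucs <- decode_engine(epochs$data, Y, curve$fold, curve$lambda,
                        curve$timepoints)
  obs <- aucs[, 1]
  null <- aucs[, -1, drop = FALSE]
  stopifnot(max(abs(obs - curve$auc)) < 1e-9)
  p <- vapply(seq_along(obs), function(t)
    (1 + sum(null[t, ] >= obs[t])) / (n_perm + 1), 1.0)
  fdr <- fdr_bh(p, q = q)
  curve$null_quantiles <- t(apply(null, 1, stats::quantile,
                                  probs = c(0.025, 0.5, 0.975)))
  curve$p <- p
  curve$q_values <- fdr$q_values
  curve$significant <- fdr$mask
  curve
}
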