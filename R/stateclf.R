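# Trial-by-trial mind-state prediction from the multivariate marker set:
# feature assembly, kernel-PCA reduction, random-forest classification with
# block-grouped cross-validation, permutation chance level, prediction of
# unlabeled trials and behavioral validation.

#' Flatten a marker matrix into per-trial feature columns
#' @param markers `marker_matrix` from [compute_marker_matrix()].
#' @return data.frame with `trial_id` and one column per channel x marker.
#' @export
marker_features <- function(markers) {
  d <- dim(markers$values)
  flat <- matrix(markers$values, d[1], d[2] * d[3])
  colnames(flat) <- as.vector(outer(markers$channels, markers$marker_names,
                                    function(ch, m) paste(m, ch, sep = ".")))
  cbind(data.frame(trial_id = markers$metadata$trial_id,
                   stringsAsFactors = FALSE), as.data.frame(flat))
}

#' Row-aggregated wSMI features per band
#'
#' Channels are averaged within each layout row (frontal/central/parietal/
#' occipital) and wSMI is computed between the four row signals for each
#' requested band using the band's symbolization lag without band-pass
#' filtering (tau-selection alone; stimulus epochs are too short for a
#' delta-band FIR).
#'
#' @param epochs stimulus `epoch_set`.
#' @param layout channel layout matching the epochs.
#' @param bands band names, default delta/theta/alpha.
#' @return data.frame with `trial_id` and one column per row-pair x band.
#' @export
connectivity_features <- function(epochs, layout = channel_layout(dim(epochs$data)[2]),
                                  bands = c("delta", "theta", "alpha")) {
  d <- dim(epochs$data)
  rows <- levels(layout$row)
  pair_idx <- t(utils::combn(length(rows), 2))
  out <- list(trial_id = epochs$metadata$trial_id)
  rowsig <- lapply(rows, function(r) {
    ch <- row_channels(layout, r)
    acc <- epochs$data[, ch[1], ]
    for (c2 in ch[-1]) acc <- acc + epochs$data[, c2, ]
    acc / length(ch)
  })
  for (bn in bands) {
    tau <- tau_for_band(bn, epochs$fs)
    vals <- matrix(NA_real_, d[1], nrow(pair_idx))
    for (i in seq_len(d[1])) {
      syms <- lapply(rowsig, function(s) symbolic_transform(s[i, ], tau = tau))
      for (p in seq_len(nrow(pair_idx)))
        vals[i, p] <- wsmi_from_symbols(syms[[pair_idx[p, 1]]],
                                        syms[[pair_idx[p, 2]]])
    }
    colnames(vals) <- paste0("wsmi_", bn, ".",
                             rows[pair_idx[, 1]], "_", rows[pair_idx[, 2]])
    out[[bn]] <- vals
  }
  cbind(data.frame(trial_id = out$trial_id, stringsAsFactors = FALSE),
        do.call(cbind, lapply(bands, function(b) as.data.frame(out[[b]]))))
}

#' Windowed ERP amplitude features
#' @param epochs baseline-corrected stimulus `epoch_set`.
#' @param windows list of time windows, s, default the early/intermediate/
#'   late split `[0.08, 0.15]`, `[0.15, 0.35]`, `[0.35, 0.7]`.
#' @return data.frame with `trial_id` and one column per channel x window.
#' @export
erp_features <- function(epochs, windows = list(c(0.08, 0.15),
                                                c(0.15, 0.35),
                                                c(0.35, 0.7))) {
  d <- dim(epochs$data)
  cols <- list()
  for (w in windows) {
    sel <- epochs$times >= w[1] & epochs$times < w[2]
    m <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
    colnames(m) <- paste0("erp_", w[1] * 1000, "_", w[2] * 1000, ".",
                          if (!is.null(rownames(epochs$data)))
                            rownames(epochs$data) else paste0("ch", seq_len(d[2])))
    cols[[length(cols) + 1L]] <- m
  }
  cbind(data.frame(trial_id = epochs$metadata$trial_id,
                   stringsAsFactors = FALSE),
        as.data.frame(do.call(cbind, cols)))
}

#' Assemble the classifier feature table
#'
#' Row-aligned concatenation of marker, connectivity and ERP feature
#' blocks, joined on `trial_id`; metadata (block, state label, response
#' info) is carried from the epoch set. Labeled rows are those the
#' 5-second rule could label; everything else is `"unlabeled"`.
#'
#' @param stim_epochs labeled stimulus `epoch_set` (see [label_trials()]).
#' @param markers `marker_features()` data.frame (or NULL to skip).
#' @param connectivity `connectivity_features()` data.frame (or NULL).
#' @param erp_summaries `erp_features()` data.frame (or NULL).
#' @return data.frame of class `feature_table` with attribute
#'   `feature_cols`; metadata columns `trial_id`, `block`, `state_label`,
#'   `onset_sample`.
#' @export
build_feature_table <- function(stim_epochs, markers = NULL,
                                connectivity = NULL, erp_summaries = NULL) {
  md <- stim_epochs$metadata
  out <- md[, intersect(c("trial_id", "onset_sample", "block", "state_label",
                          "go_nogo", "responded", "rt_ms"), names(md))]
  blocks <- list(markers = markers, connectivity = connectivity,
                 erp = erp_summaries)
  feature_cols <- character(0)
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (is.null(b)) next
    if (!identical(b$trial_id, md$trial_id)) {
      bad <- union(setdiff(b$trial_id, md$trial_id),
                   setdiff(md$trial_id, b$trial_id))
      stopf("trial-id mismatch in %s block: %s", nm,
            paste(utils::head(bad, 5), collapse = ", "))
    }
    fc <- setdiff(names(b), "trial_id")
    feature_cols <- c(feature_cols, fc)
    out <- cbind(out, b[, fc, drop = FALSE])
  }
  if (!length(feature_cols)) stopf("no feature blocks supplied")
  attr(out, "feature_cols") <- feature_cols
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Compute the full default feature set for stimulus epochs
#'
#' Convenience wrapper: spectral/complexity markers, row-pair wSMI and
#' windowed ERP amplitudes, assembled with [build_feature_table()].
#'
#' @param stim_epochs labeled, baseline-corrected stimulus `epoch_set`.
#' @param layout channel layout.
#' @return `feature_table`.
#' @export
compute_features <- function(stim_epochs,
                             layout = channel_layout(dim(stim_epochs$data)[2])) {
  mk <- compute_marker_matrix(stim_epochs)
  build_feature_table(stim_epochs,
                      markers = marker_features(mk),
                      connectivity = connectivity_features(stim_epochs, layout),
                      erp_summaries = erp_features(stim_epochs))
}

# --- preprocessing + reduction pipeline (fitted on training rows only) ---

#' Fit a standardize + principal-component reduction on training rows
#'
#' Features are median-imputed and standardized on the training rows;
#' constant features are dropped with a warning. Components are kept up to
#' `target_var` cumulative variance, capped at `n_rows - 1` and at
#' `max_components`. The default is linear PCA; `method = "kpca"` gives a
#' radial-basis kernel principal-component transform (kernel width from
#' the median pairwise squared-distance heuristic). With the trial counts
#' a single session yields, the trailing components are essentially noise
#' and diluting the forest with them costs accuracy, hence the default
#' component cap.
#'
#' @param X numeric matrix (training rows x features).
#' @param target_var cumulative variance target, default 0.95.
#' @param method `"pca"` (default) or `"kpca"`.
#' @param max_components hard cap on components (default 25).
#' @return object of class `dim_reducer` with a `$transform(newX)` closure;
#'   never refits on new data.
#' @export
reduce_dim <- function(X, target_var = 0.95, method = c("pca", "kpca"),
                       max_components = 25) {
  method <- match.arg(method)
  if (nrow(X) < 2) stopf("need at least 2 rows")
  med <- apply(X, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  impute <- function(M) {
    for (j in seq_len(ncol(M))) M[!is.finite(M[, j]), j] <- med[j]
    M
  }
  X <- impute(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- sdv > 0
  if (!all(keep)) warnf("%d constant feature(s) dropped", sum(!keep))
  mu <- colMeans(X[, keep, drop = FALSE])
  sdv <- sdv[keep]
  std <- function(M) sweep(sweep(impute(M)[, keep, drop = FALSE], 2, mu),
                           2, sdv, "/")
  Xs <- std(X)
  cap <- min(nrow(X) - 1L, max_components %||% (nrow(X) - 1L))
  if (method == "kpca") {
    d2 <- stats::dist(Xs)^2
    sigma <- 0.25 / max(stats::median(d2), .Machine$double.eps)
    kp <- kernlab::kpca(Xs, kernel = "rbfdot", kpar = list(sigma = sigma),
                        features = 0)
    ev <- kernlab::eig(kp)
    n_comp <- min(cap, max(1L, which(cumsum(ev) / sum(ev) >= target_var)[1]))
    project <- function(M) kernlab::predict(kp, std(M))[, seq_len(n_comp),
                                                        drop = FALSE]
  } else {
    pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
    ev <- pc$sdev^2
    n_comp <- min(cap, max(1L, which(cumsum(ev) / sum(ev) >= target_var)[1]))
    project <- function(M) (std(M) %*% pc$rotation)[, seq_len(n_comp),
                                                    drop = FALSE]
  }
  structure(list(transform = function(newX) project(as.matrix(newX)),
                 n_components = n_comp, method = method),
            class = "dim_reducer")
}

#' Balanced accuracy (mean per-class recall)
#' @param true,pred factors or character vectors.
#' @return balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(true, pred) {
  classes <- unique(as.character(true))
  mean(vapply(classes, function(cl)
    mean(as.character(pred)[true == cl] == cl), 1.0))
}

# fit impute->standardize->reduce->random-forest on given rows
fit_pipeline <- function(X, y, target_var = 0.95, method = "pca",
                         n_trees = 300, seed = 1, max_components = 25) {
  red <- reduce_dim(X, target_var = target_var, method = method,
                    max_components = max_components)
  Z <- red$transform(X)
  y <- factor(y, levels = intersect(MIND_STATES, unique(y)))
  # class-balanced sampling: every tree bootstraps the same number of
  # trials from each class, so minority states keep their vote share
  sf <- rep(min(table(y)) / length(y), nlevels(y))
  rf <- ranger::ranger(x = as.data.frame(Z), y = y, num.trees = n_trees,
                       probability = TRUE, seed = seed, num.threads = 1,
                       replace = TRUE, sample.fraction = sf)
  structure(list(reducer = red, forest = rf, classes = levels(y)),
            class = "state_pipeline")
}

predict_pipeline <- function(pipeline, X) {
  Z <- pipeline$reducer$transform(X)
  stats::predict(pipeline$forest, data = as.data.frame(Z),
                 num.threads = 1)$predictions
}

# Precompute per-fold embeddings for leave-one-block-out CV. The
# imputation, standardization and dimensionality reduction are fitted on
# the training blocks only and are label-free, so the same embeddings are
# reused exactly by the label-permutation null.
prepare_cv <- function(features, target_var = 0.95, method = "pca",
                       max_components = 25) {
  fc <- attr(features, "feature_cols")
  lab <- features$state_label %in% MIND_STATES
  ft <- features[lab, , drop = FALSE]
  if (nrow(ft) == 0) stopf("no labeled rows")
  blocks <- unique(ft$block)
  if (length(blocks) < 2) stopf("need at least 2 blocks")
  y <- ft$state_label
  if (length(unique(y)) < 2)
    stopf("class(es) absent from every training fold: only %s labeled",
          paste(unique(y), collapse = ", "))
  X <- as.matrix(ft[, fc, drop = FALSE])
  folds <- lapply(blocks, function(b) {
    tr <- ft$block != b
    red <- reduce_dim(X[tr, , drop = FALSE], target_var = target_var,
                      method = method, max_components = max_components)
    list(block = b, tr = which(tr), te = which(!tr),
         Ztr = red$transform(X[tr, , drop = FALSE]),
         Zte = red$transform(X[!tr, , drop = FALSE]))
  })
  list(folds = folds, y = y, meta = ft[, setdiff(names(ft), fc), drop = FALSE],
       blocks = blocks)
}

# random forest on precomputed fold embeddings for a given label vector
cv_score <- function(cv, y, n_trees, seed) {
  pred <- rep(NA_character_, length(y))
  probs <- matrix(NA_real_, length(y), 3, dimnames = list(NULL, MIND_STATES))
  for (k in seq_along(cv$folds)) {
    f <- cv$folds[[k]]
    ytr <- factor(y[f$tr], levels = intersect(MIND_STATES, unique(y[f$tr])))
    if (nlevels(ytr) < 2) { ms_log("fold ", f$block, " skipped"); next }
    sf <- rep(min(table(ytr)) / length(ytr), nlevels(ytr))
    rf <- ranger::ranger(x = as.data.frame(f$Ztr), y = ytr,
                         num.trees = n_trees, probability = TRUE,
                         seed = child_seed(seed, k), num.threads = 1,
                         replace = TRUE, sample.fraction = sf)
    pr <- stats::predict(rf, data = as.data.frame(f$Zte),
                         num.threads = 1)$predictions
    probs[f$te, colnames(pr)] <- pr
    pred[f$te] <- colnames(pr)[max.col(pr, ties.method = "first")]
  }
  list(pred = pred, probs = probs,
       score = balanced_accuracy(y[!is.na(pred)], pred[!is.na(pred)]))
}

#' Block-grouped cross-validated mind-state classification
#'
#' Leave-one-block-out cross-validation (blocks are the experimental
#' blocks, so temporally adjacent trials never straddle the train/test
#' split). Each fold fits the full pipeline -- impute, standardize,
#' kernel-PCA reduction, 300-tree random forest with class-balanced
#' weights -- on the training blocks only. The score is the balanced
#' accuracy over pooled held-out trials.
#'
#' @param features `feature_table` (only its labeled rows are used).
#' @param n_trees forest size, default 300.
#' @param target_var cumulative variance target of the reduction.
#' @param method reduction method, `"pca"` (default) or `"kpca"`.
#' @param max_components component cap for the reduction, default 25.
#' @param seed integer seed.
#' @param cv optional precomputed fold embeddings from an earlier fit
#'   (internal reuse; the label-free pipeline stages do not change).
#' @return object of class `stateclf_fit`: `balanced_accuracy`,
#'   `predictions` (per labeled trial: true, predicted, probabilities),
#'   `blocks`.
#' @export
fit_crossval <- function(features, n_trees = 300, target_var = 0.95,
                         method = "pca", max_components = 25, seed = 1,
                         cv = NULL) {
  cv <- cv %||% prepare_cv(features, target_var, method, max_components)
  res <- cv_score(cv, cv$y, n_trees, seed)
  structure(list(
    balanced_accuracy = res$score,
    predictions = data.frame(trial_id = cv$meta$trial_id,
                             block = cv$meta$block, true = cv$y,
                             predicted = res$pred, stringsAsFactors = FALSE),
    probabilities = res$probs, blocks = cv$blocks, seed = seed,
    n_trees = n_trees, target_var = target_var, method = method, cv = cv),
    class = "stateclf_fit")
}

#' Permutation chance level for the mind-state classifier
#'
#' Shuffles state labels across labeled trials (within the subject,
#' preserving class counts) and re-runs the full block-grouped
#' cross-validation for each permutation.
#'
#' @param features `feature_table`.
#' @param n_perm permutations, default 500 (below 100 warns).
#' @param seed integer seed.
#' @param n_trees,target_var,method,max_components as in [fit_crossval()].
#' @param fit optional `stateclf_fit` for the same features/settings; its
#'   fold embeddings are reused (they are label-free) so only the forests
#'   are refitted per permutation.
#' @return list with `observed` (balanced accuracy), `null` (length
#'   `n_perm`), `p` (add-one empirical p-value).
#' @export
permutation_chance <- function(features, n_perm = 500, seed = 1,
                               n_trees = 300, target_var = 0.95,
                               method = "pca", max_components = 25,
                               fit = NULL) {
  if (n_perm < 100) warnf("n_perm = %d < 100: unstable null tails", n_perm)
  fit <- fit %||% fit_crossval(features, n_trees, target_var, method,
                               max_components, seed)
  cv <- fit$cv
  null <- vapply(seq_len(n_perm), function(i) {
    yp <- with_seed(child_seed(seed, 100 + i), sample(cv$y))
    cv_score(cv, yp, n_trees, child_seed(seed, 10000 + i))$score
  }, 1.0)
  list(observed = fit$balanced_accuracy, null = null,
       p = (1 + sum(null >= fit$balanced_accuracy)) / (n_perm + 1))
}

#' Fit the final pipeline on all labeled rows
#' @param features `feature_table`.
#' @param ... passed to the pipeline (n_trees, target_var, method).
#' @param seed integer seed.
#' @return `state_pipeline` usable with [predict_unlabeled()].
#' @export
fit_full <- function(features, seed = 1, ...) {
  fc <- attr(features, "feature_cols")
  lab <- features$state_label %in% MIND_STATES
  fit_pipeline(as.matrix(features[lab, fc, drop = FALSE]),
               features$state_label[lab], seed = seed, ...)
}

#' Predict mind states for unlabeled trials
#'
#' Every unlabeled row receives the argmax-probability state; ties break
#' toward ON (then MW).
#'
#' @param pipeline `state_pipeline` from [fit_full()].
#' @param features `feature_table` (its unlabeled rows are predicted).
#' @return data.frame with `trial_id`, `onset_sample` (if present),
#'   `predicted` and per-state probabilities.
#' @export
predict_unlabeled <- function(pipeline, features) {
  fc <- attr(features, "feature_cols")
  unl <- !(features$state_label %in% MIND_STATES)
  ft <- features[unl, , drop = FALSE]
  if (nrow(ft) == 0) stopf("no unlabeled rows")
  pr <- predict_pipeline(pipeline, as.matrix(ft[, fc, drop = FALSE]))
  ord <- intersect(MIND_STATES, colnames(pr))   # ON first: tie -> ON
  pr <- pr[, ord, drop = FALSE]
  out <- data.frame(trial_id = ft$trial_id, stringsAsFactors = FALSE)
  if ("onset_sample" %in% names(ft)) out$onset_sample <- ft$onset_sample
  out$predicted <- ord[max.col(pr, ties.method = "first")]
  cbind(out, as.data.frame(pr))
}

#' Run the full trial-by-trial state-prediction pipeline on one session
#'
#' Convenience driver for one synthetic subject: stimulus epoching and
#' 5-second labeling, feature assembly, block-grouped cross-validation,
#' optional permutation chance level, prediction of unlabeled trials and
#' behavioral validation. To keep the false-alarm comparison of the
#' validation stable, all unlabeled No-Go trials are predicted together
#' with a random sample of unlabeled Go trials.
#'
#' @param recording `mind_recording` with probes.
#' @param seed integer seed for every stochastic step.
#' @param n_perm permutations for the chance level (0 skips it).
#' @param n_unlabeled_go number of unlabeled Go trials to predict.
#' @param min_labeled_per_state subjects with fewer labeled trials than
#'   this in any state are excluded (returns `NULL`), mirroring the
#'   only-subjects-with-all-three-states rule.
#' @param ... passed to [fit_crossval()] / [fit_full()].
#' @return `NULL` if excluded, else a list with `fit` (`stateclf_fit`),
#'   `chance` (from [permutation_chance()], or NULL), `predictions`,
#'   `validation` (from [validate_predictions()]) and `labeled_counts`.
#' @export
run_state_classification <- function(recording, seed = 1, n_perm = 100,
                                     n_unlabeled_go = 300,
                                     min_labeled_per_state = 8, ...) {
  stim <- label_trials(baseline_correct(epoch_stimuli(recording)),
                       recording$probes)
  counts <- table(factor(stim$metadata$state_label, levels = MIND_STATES))
  if (any(counts < min_labeled_per_state)) {
    ms_log("subject excluded: labeled counts ",
           paste(counts, collapse = "/"))
    return(NULL)
  }
  md <- stim$metadata
  lab_idx <- which(md$state_label != "unlabeled")
  unl_nogo <- which(md$state_label == "unlabeled" & md$go_nogo == "nogo")
  unl_go <- which(md$state_label == "unlabeled" & md$go_nogo == "go")
  unl_go <- with_seed(child_seed(seed, 9),
                      sample(unl_go, min(n_unlabeled_go, length(unl_go))))
  sub <- subset_epochs(stim, sort(c(lab_idx, unl_nogo, unl_go)))
  ftab <- compute_features(sub, recording$channels)
  fit <- fit_crossval(ftab, seed = child_seed(seed, 1), ...)
  chance <- if (n_perm > 0)
    permutation_chance(ftab, n_perm = n_perm, seed = child_seed(seed, 2),
                       fit = fit, ...)
  else NULL
  pipe <- fit_full(ftab, seed = child_seed(seed, 3), ...)
  preds <- predict_unlabeled(pipe, ftab)
  bt <- behavior_table(recording$events, recording$fs,
                       labels = md[, c("onset_sample", "state_label")])
  val <- validate_predictions(preds, bt)
  list(fit = fit, chance = chance, predictions = preds, validation = val,
       labeled_counts = counts, features = ftab)
}

#' Behavioral validation of predicted mind states
#'
#' Re-runs the behavior summaries and contrasts using predicted state
#' labels on unlabeled trials, and reports whether the predicted-state
#' behavior reproduces the planted/labeled ordering (most misses and
#' slowest RTs in MB, most false alarms in MW).
#'
#' @param predictions data.frame from [predict_unlabeled()] with
#'   `onset_sample`.
#' @param behavior `behavior_table` for the same session.
#' @return list with `summary` (per predicted state), `ordering` (named
#'   logical checks), `table` (behavior table relabeled by predictions).
#' @export
validate_predictions <- function(predictions, behavior) {
  stopifnot("onset_sample" %in% names(predictions))
  tab <- behavior
  m <- match(tab$onset_sample, predictions$onset_sample)
  tab$state_label[!is.na(m)] <- predictions$predicted[m[!is.na(m)]]
  tab <- tab[!is.na(m), , drop = FALSE]     # predicted trials only
  tab <- tab[tab$state_label %in% MIND_STATES, , drop = FALSE]
  if (nrow(tab) == 0) stopf("no trials with predicted states")
  sm <- summarize_behavior(tab)
  g <- function(st, col) {
    v <- sm[[col]][sm$state == st]
    if (length(v)) mean(v, na.rm = TRUE) else NA_real_
  }
  ordering <- c(
    mb_most_misses = isTRUE(g("MB", "miss_rate") > g("MW", "miss_rate") &&
                            g("MB", "miss_rate") > g("ON", "miss_rate")),
    mb_slowest_rt = isTRUE(g("MB", "rt_median") > g("MW", "rt_median") &&
                           g("MB", "rt_median") > g("ON", "rt_median")),
    mw_most_fa = isTRUE(g("MW", "fa_rate") > g("ON", "fa_rate")))
  list(summary = sm, ordering = ordering, table = tab)
}
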