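# Node-wise state contrasts and Benjamini-Hochberg FDR control.

#' Benjamini-Hochberg step-up FDR
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (`NA` allowed,
#'   passed through).
#' @param q FDR level for the mask, default 0.05.
#' @return list with `q_values` (monotone-adjusted) and `mask`
#'   (`q_values < q`); empty input yields empty output.
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.9))$q_values   # 0.03 0.03 0.90
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (length(p_values) == 0)
    return(list(q_values = numeric(0), mask = logical(0)))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  qv <- rep(NA_real_, length(p_values))
  ok <- which(!is.na(p_values))
  m <- length(ok)
  if (m > 0) {
    p <- p_values[ok]
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))      # step-up monotonization
    adj <- pmin(1, adj)
    qv[ok[o]] <- adj
  }
  list(q_values = qv, mask = !is.na(qv) & qv < q)
}

#' Node-wise state contrast with FDR mask
#'
#' The statistical engine behind per-electrode (or per-connection)
#' topographic contrast maps. With multiple subjects: subject-level state
#' means per node, then a paired test across subjects (paired t-test for 15
#' or more subjects, Wilcoxon signed-rank below). With a single subject:
#' Welch t-test over trials. P-values are BH-corrected across nodes within
#' the contrast.
#'
#' @param values trials x nodes numeric matrix of marker or connectivity
#'   values (flagged `NA` entries allowed).
#' @param states per-trial state labels.
#' @param pair two states; effect sign is `pair[1] - pair[2]`.
#' @param subjects optional per-trial subject ids.
#' @param q FDR level, default 0.05.
#' @param node_names optional node labels.
#' @return data.frame (class `group_contrast_map`) with `node`, `effect`,
#'   `p`, `q_values`, `mask`; nodes with no usable values are listed with
#'   `NA` and excluded from correction.
#' @export
node_state_contrast <- function(values, states, pair, subjects = NULL,
                                q = 0.05, node_names = NULL) {
  stopifnot(is.matrix(values), length(states) == nrow(values))
  if (!all(pair %in% states))
    stopf("state(s) %s absent", paste(setdiff(pair, states), collapse = ", "))
  subjects <- subjects %||% rep("s1", nrow(values))
  n_nodes <- ncol(values)
  node_names <- node_names %||% colnames(values) %||% paste0("node", seq_len(n_nodes))
  eff <- p <- rep(NA_real_, n_nodes)
  subs <- unique(subjects)
  for (j in seq_len(n_nodes)) {
    if (length(subs) >= 2) {
      d <- vapply(subs, function(s) {
        a <- values[states == pair[1] & subjects == s, j]
        b <- values[states == pair[2] & subjects == s, j]
        mean(a, na.rm = TRUE) - mean(b, na.rm = TRUE)
      }, 1.0)
      d <- d[is.finite(d)]
      if (length(d) < 2) next
      eff[j] <- mean(d)
      p[j] <- if (length(d) >= 15)
        stats::t.test(d)$p.value
      else tryCatch(stats::wilcox.test(d, exact = FALSE)$p.value,
                    error = function(e) NA_real_)
    } else {
      a <- values[states == pair[1], j]; a <- a[is.finite(a)]
      b <- values[states == pair[2], j]; b <- b[is.finite(b)]
      if (length(a) < 2 || length(b) < 2) next
      eff[j] <- mean(a) - mean(b)
      p[j] <- stats::t.test(a, b)$p.value
    }
  }
  fdr <- fdr_bh(p, q = q)
  out <- data.frame(node = node_names, effect = eff, p = p,
                    q_values = fdr$q_values, mask = fdr$mask,
                    stringsAsFactors = FALSE)
  class(out) <- c("group_contrast_map", "data.frame")
  attr(out, "pair") <- pair
  out
}

#' Extract a trials x nodes matrix for one marker from a marker matrix
#' @param markers `marker_matrix`.
#' @param marker marker name (e.g. `"psd_beta"`, `"sampen"`).
#' @return trials x channels matrix with channel names.
#' @export
marker_values <- function(markers, marker) {
  i <- match(marker, markers$marker_names)
  if (is.na(i)) stopf("unknown marker %s", marker)
  v <- markers$values[, , i, drop = FALSE]
  dim(v) <- dim(markers$values)[1:2]
  colnames(v) <- markers$channels
  v
}
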