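# Behavioral metrics (misses, false alarms, reaction times) per mind state.

#' Build a behavior table from an event stream
#'
#' Re-derives trial outcomes from raw stimulus and response events: a
#' response belongs to the nearest preceding stimulus within the grace
#' window (the maximum SOA, 1250 ms, by default) and is consumed once, the
#' ownership rule required by a null-ISI design. State labels come from a
#' labeled stimulus table (e.g. [label_trials()] metadata) joined by
#' onset sample; unlabeled trials keep `"unlabeled"`.
#'
#' @param events event data.frame with `onset_sample`, `kind`, `go_nogo`,
#'   `block` (e.g. `recording$events`).
#' @param fs sampling rate, Hz.
#' @param labels optional data.frame with `onset_sample` and `state_label`.
#' @param subject subject id stored with every trial, default `"s1"`.
#' @param grace_ms response-ownership window, ms.
#' @return data.frame (class `behavior_table`): one row per stimulus with
#'   `subject`, `block`, `go_nogo`, `responded`, `rt_ms`, `state_label`.
#' @export
behavior_table <- function(events, fs, labels = NULL, subject = "s1",
                           grace_ms = 1250) {
  stim <- events[events$kind == "stimulus", , drop = FALSE]
  resp <- events[events$kind == "response", , drop = FALSE]
  if (nrow(stim) == 0) stopf("no stimulus events")
  stim <- stim[order(stim$onset_sample), , drop = FALSE]
  resp_s <- sort(resp$onset_sample)
  grace <- grace_ms / 1000 * fs
  responded <- logical(nrow(stim))
  rt <- rep(NA_real_, nrow(stim))
  used <- logical(length(resp_s))
  for (i in seq_len(nrow(stim))) {
    dt <- resp_s - stim$onset_sample[i]
    j <- which(!used & dt > 0 & dt <= grace)
    if (length(j)) {
      j <- j[1]
      used[j] <- TRUE
      responded[i] <- TRUE
      rt[i] <- dt[j] / fs * 1000
    }
  }
  out <- data.frame(subject = subject, block = stim$block,
                    go_nogo = stim$go_nogo,
                    onset_sample = stim$onset_sample,
                    responded = responded, rt_ms = rt,
                    state_label = "unlabeled", stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    m <- match(out$onset_sample, labels$onset_sample)
    out$state_label[!is.na(m)] <- labels$state_label[m[!is.na(m)]]
  }
  class(out) <- c("behavior_table", "data.frame")
  out
}

#' Summarize behavior per subject and state
#'
#' Miss rate = unanswered Go trials / Go trials; FA rate = answered No-Go
#' trials / No-Go trials; RT statistics over responded Go trials only.
#' Cells with zero Go (or No-Go) trials yield `NA` and are flagged.
#'
#' @param table `behavior_table` (or any data.frame with the same columns).
#' @param by_state include the state split (default TRUE).
#' @return data.frame (class `behavior_summary`): one row per subject x
#'   state with `n_go`, `n_nogo`, `miss_rate`, `fa_rate`, `rt_median`,
#'   `rt_mean`.
#' @export
summarize_behavior <- function(table, by_state = TRUE) {
  if (nrow(table) == 0) stopf("empty behavior table")
  grp <- if (by_state) interaction(table$subject, table$state_label,
                                   drop = TRUE, sep = "\r")
         else factor(table$subject)
  rows <- lapply(levels(grp), function(g) {
    t <- table[grp == g, , drop = FALSE]
    go <- t$go_nogo == "go"; nogo <- !go
    rts <- t$rt_ms[go & t$responded]
    parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
    data.frame(
      subject = parts[1],
      state = if (by_state) parts[2] else "all",
      n_go = sum(go), n_nogo = sum(nogo),
      miss_rate = if (sum(go)) mean(!t$responded[go]) else NA_real_,
      fa_rate = if (sum(nogo)) mean(t$responded[nogo]) else NA_real_,
      rt_median = if (length(rts)) stats::median(rts) else NA_real_,
      rt_mean = if (length(rts)) mean(rts) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("behavior_summary", "data.frame")
  out
}

#' Pairwise behavioral contrasts between states
#'
#' For each measure (miss rate, FA rate, median RT) and state pair, a
#' paired across-subject test on subject-level values (paired t-test for 15
#' or more subjects, Wilcoxon signed-rank below); with a single subject, a
#' within-subject trial bootstrap. P-values are BH-corrected across the
#' measure x pair family.
#'
#' @param table `behavior_table` with state labels.
#' @param pairs list of state pairs, default all three.
#' @param n_boot bootstrap replicates for single-subject mode.
#' @param seed seed for the bootstrap.
#' @param q FDR level.
#' @return data.frame with `measure`, `state_a`, `state_b`, `effect`
#'   (a - b), `p`, `q_values`, `mask`.
#' @export
behavior_state_contrast <- function(table,
                                    pairs = list(c("MB", "ON"), c("MB", "MW"),
                                                 c("MW", "ON")),
                                    n_boot = 1000, seed = 1, q = 0.05) {
  states_present <- unique(table$state_label)
  if (length(intersect(MIND_STATES, states_present)) < 2)
    stopf("need at least two labeled states")
  subs <- unique(table$subject)
  measures <- c("miss_rate", "fa_rate", "rt_median")
  res <- list()
  for (pp in pairs) {
    if (!all(pp %in% states_present)) next
    for (ms in measures) {
      if (length(subs) >= 2) {
        sm <- summarize_behavior(table)
        d <- vapply(subs, function(s) {
          a <- sm[[ms]][sm$subject == s & sm$state == pp[1]]
          b <- sm[[ms]][sm$subject == s & sm$state == pp[2]]
          if (!length(a) || !length(b)) NA_real_ else a - b
        }, 1.0)
        d <- d[is.finite(d)]
        if (length(d) < 2) next
        pv <- if (length(d) >= 15) stats::t.test(d)$p.value
              else tryCatch(stats::wilcox.test(d, exact = FALSE)$p.value,
                            error = function(e) NA_real_)
        res[[length(res) + 1L]] <- data.frame(
          measure = ms, state_a = pp[1], state_b = pp[2],
          effect = mean(d), p = pv, stringsAsFactors = FALSE)
      } else {
        ta <- table[table$state_label == pp[1], , drop = FALSE]
        tb <- table[table$state_label == pp[2], , drop = FALSE]
        stat <- function(t) {
          s <- summarize_behavior(t, by_state = FALSE)
          s[[ms]][1]
        }
        obs <- stat(ta) - stat(tb)
        if (!is.finite(obs)) next
        boots <- with_seed(child_seed(seed, match(ms, measures)), {
          vapply(seq_len(n_boot), function(i) {
            sa <- ta[sample(nrow(ta), replace = TRUE), , drop = FALSE]
            sb <- tb[sample(nrow(tb), replace = TRUE), , drop = FALSE]
            stat(sa) - stat(sb)
          }, 1.0)
        })
        boots <- boots[is.finite(boots)]
        pv <- 2 * min(mean(c(boots, 0) <= 0), mean(c(boots, 0) >= 0))
        res[[length(res) + 1L]] <- data.frame(
          measure = ms, state_a = pp[1], state_b = pp[2],
          effect = obs, p = min(1, pv), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res)
  fdr <- fdr_bh(out$p, q = q)
  out$q_values <- fdr$q_values
  out$mask <- fdr$mask
  out
}
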