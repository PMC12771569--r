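#' Scalp channel layout used by the synthetic generator
#'
#' A desk-scale stand-in for a high-density montage: `n_channels` electrodes
#' arranged in four anterior-to-posterior rows (frontal, central, parietal,
#' occipital). Rows are the carrier of the planted front-back gradients, so
#' every analysis that talks about "frontal" or "posterior" channels resolves
#' it through this layout rather than through name conventions.
#'
#' @param n_channels total channel count; must be divisible by 4 (default 32).
#' @return data.frame with columns `name`, `row` (factor frontal/central/
#'   parietal/occipital), `x` (left-right in \[-1, 1\]) and `y`
#'   (posterior-anterior in \[-1, 1\]).
#' @examples
#' head(channel_layout())
#' @export
channel_layout <- function(n_channels = 32) {
  if (n_channels %% 4 != 0 || n_channels <= 0)
    stopf("n_channels must be a positive multiple of 4, got %d", n_channels)
  per_row <- n_channels / 4
  rows <- c("frontal", "central", "parietal", "occipital")
  prefix <- c(frontal = "F", central = "C", parietal = "P", occipital = "O")
  out <- do.call(rbind, lapply(seq_along(rows), function(i) {
    data.frame(
      name = paste0(prefix[rows[i]], seq_len(per_row)),
      row = rows[i],
      x = seq(-1, 1, length.out = per_row),
      y = rev(seq(-1, 1, length.out = 4))[i],
      stringsAsFactors = FALSE
    )
  }))
  out$row <- factor(out$row, levels = rows)
  rownames(out) <- NULL
  out
}

#' Channel indices belonging to a layout row
#' @param layout data.frame from [channel_layout()].
#' @param row one of `"frontal"`, `"central"`, `"parietal"`, `"occipital"`.
#' @return integer channel indices.
#' @export
row_channels <- function(layout, row) {
  row <- match.arg(row, levels(layout$row))
  which(layout$row == row)
}

#' Channel pairs carrying planted long-range coupling
#'
#' Three fronto-parietal pairs (left, midline-ish, right) receive the
#' state-dependent linear and nonlinear coupling injected by
#' [generate_session()]. Connectivity analyses can look here for the ground
#' truth of where coupling lives.
#'
#' @param layout data.frame from [channel_layout()].
#' @return two-column integer matrix of channel index pairs.
#' @export
planted_pairs <- function(layout) {
  fr <- row_channels(layout, "frontal")
  pa <- row_channels(layout, "parietal")
  k <- length(fr)
  picks <- unique(pmax(1, round(c(0.15, 0.5, 0.85) * k)))
  cbind(frontal = fr[picks], parietal = pa[picks])
}
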