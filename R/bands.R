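#' Frequency band definitions
#'
#' The canonical five-band partition used throughout: delta 1-4, theta 4-8,
#' alpha 8-12, beta 12-30, gamma 30-45 Hz. Bands tile 1-45 Hz without
#' overlap; normalized band power is computed over their union.
#'
#' @param names optional subset of band names to return.
#' @return data.frame with columns `name`, `f_lo`, `f_hi` (Hz).
#' @examples
#' default_bands()
#' default_bands(c("delta", "theta", "alpha"))
#' @export
default_bands <- function(names = NULL) {
  b <- data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    f_lo = c(1, 4, 8, 12, 30),
    f_hi = c(4, 8, 12, 30, 45),
    stringsAsFactors = FALSE
  )
  if (!is.null(names)) {
    miss <- setdiff(names, b$name)
    if (length(miss)) stopf("unknown band(s): %s", paste(miss, collapse = ", "))
    b <- b[match(names, b$name), , drop = FALSE]
    rownames(b) <- NULL
  }
  b
}

validate_bands <- function(bands, fs = NULL) {
  stopifnot(is.data.frame(bands), all(c("name", "f_lo", "f_hi") %in% names(bands)))
  if (any(bands$f_lo <= 0) || any(bands$f_hi <= bands$f_lo))
    stopf("bands must satisfy 0 < f_lo < f_hi")
  if (!is.null(fs) && any(bands$f_hi > fs / 2))
    stopf("band upper edge above Nyquist (%g Hz)", fs / 2)
  invisible(bands)
}

#' Symbolization lag for a band
#'
#' After band-pass filtering, the 3-sample symbolic kernel should span about
#' one cycle of the band's upper edge, so the lag is
#' `tau = max(1, round(fs / (3 * f_hi)))` samples (at 250 Hz: delta 21,
#' theta 10, alpha 7).
#'
#' @param band one-row data.frame with `f_hi`, or a band name.
#' @param fs sampling rate in Hz.
#' @return integer lag in samples.
#' @export
tau_for_band <- function(band, fs) {
  if (is.character(band)) band <- default_bands(band)
  max(1L, as.integer(round(fs / (3 * band$f_hi[1]))))
}
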