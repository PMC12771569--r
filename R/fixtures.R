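# On-disk session format: BrainVision triplet for the EEG (text header +
# marker file, 16-bit multiplexed binary data at 0.01 uV resolution) and
# tab-separated tables for events and probes. The TSV tables are the
# authoritative event record; the .vmrk file carries stimulus/probe markers
# for interoperability with standard EEG readers.

BV_RESOLUTION <- 0.01  # uV per bit; +/-327.67 uV range, quantization 0.005 uV

#' Write a synthetic session to disk
#'
#' Writes `<stem>.vhdr`, `<stem>.eeg`, `<stem>.vmrk` (BrainVision, INT_16
#' multiplexed, 0.01 uV resolution), `<stem>_events.tsv` (columns
#' onset_sample, kind, category, go_nogo, rt_ms, block),
#' `<stem>_probes.tsv` (onset_sample, answer, vigilance, block), and, when
#' `include_truth`, `<stem>_truth.tsv` (run-length encoded latent states).
#'
#' @param recording `mind_recording` from [generate_session()].
#' @param path output directory (created if missing).
#' @param stem file-name stem, default `"session"`.
#' @param include_truth also write the generator's latent-state timecourse.
#' @return invisibly, the named vector of written file paths.
#' @export
write_fixture <- function(recording, path, stem = "session",
                          include_truth = TRUE) {
  stopifnot(inherits(recording, "mind_recording"))
  if (is.null(recording$data))
    stopf("recording has no EEG data (generated with synth_eeg = FALSE)")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  f <- function(ext) file.path(path, paste0(stem, ext))

  n_ch <- nrow(recording$data)
  ints <- as.integer(round(pmin(32767, pmax(-32768,
    recording$data / BV_RESOLUTION))))
  con <- file(f(".eeg"), "wb")
  writeBin(ints, con, size = 2L, endian = "little")  # multiplexed: ch fastest
  close(con)

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", stem, ".eeg"),
    paste0("MarkerFile=", stem, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_ch),
    paste0("SamplingInterval=", format(1e6 / recording$fs)),
    "[Binary Infos]",
    "BinaryFormat=INT_16",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%g,\u00b5V", seq_len(n_ch), recording$channels$name,
            BV_RESOLUTION))
  writeLines(hdr, f(".vhdr"), useBytes = TRUE)

  stim <- recording$events[recording$events$kind == "stimulus", , drop = FALSE]
  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", stem, ".eeg"),
    "[Marker Infos]",
    sprintf("Mk1=New Segment,,1,1,%d", n_ch),
    if (nrow(stim)) sprintf("Mk%d=Stimulus,S%s,%d,1,0",
                            seq_len(nrow(stim)) + 1L,
                            ifelse(stim$go_nogo == "nogo", "2", "1"),
                            stim$onset_sample),
    if (nrow(recording$probes)) sprintf("Mk%d=Comment,Probe/%s,%d,1,0",
                            seq_len(nrow(recording$probes)) + nrow(stim) + 1L,
                            recording$probes$answer,
                            recording$probes$onset_sample))
  writeLines(mrk, f(".vmrk"), useBytes = TRUE)

  ev <- recording$events[, c("onset_sample", "kind", "category", "go_nogo",
                             "rt_ms", "block")]
  write.table(ev, f("_events.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  pb <- recording$probes[, c("onset_sample", "answer", "vigilance", "block")]
  write.table(pb, f("_probes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  files <- c(eeg = f(".eeg"), vhdr = f(".vhdr"), vmrk = f(".vmrk"),
             events = f("_events.tsv"), probes = f("_probes.tsv"))
  if (include_truth) {
    r <- rle(as.character(recording$truth_states))
    write.table(data.frame(length = r$lengths, state = r$values),
                f("_truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, truth = f("_truth.tsv"))
  }
  invisible(files)
}

#' Read a session written by [write_fixture()]
#'
#' @param path directory holding the files.
#' @param stem file-name stem.
#' @return `mind_recording` (config slot absent; truth states present only
#'   if the truth table was written).
#' @export
read_fixture <- function(path, stem = "session") {
  f <- function(ext) file.path(path, paste0(stem, ext))
  if (!file.exists(f(".vhdr"))) stopf("no header file at %s", f(".vhdr"))
  hdr <- readLines(f(".vhdr"), encoding = "UTF-8")
  get_val <- function(key) {
    ln <- grep(paste0("^", key, "="), hdr, value = TRUE)[1]
    sub(paste0("^", key, "="), "", ln)
  }
  if (!identical(get_val("BinaryFormat"), "INT_16") ||
      !identical(get_val("DataOrientation"), "MULTIPLEXED"))
    stopf("unsupported BrainVision variant")
  n_ch <- as.integer(get_val("NumberOfChannels"))
  fs <- 1e6 / as.numeric(get_val("SamplingInterval"))
  ch_lines <- grep("^Ch[0-9]+=", hdr, value = TRUE)
  ch_names <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                     `[`, "", 1L)
  res <- as.numeric(vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                           `[`, "", 3L))

  sz <- file.info(f(".eeg"))$size
  con <- file(f(".eeg"), "rb")
  ints <- readBin(con, "integer", n = sz / 2, size = 2L, signed = TRUE,
                  endian = "little")
  close(con)
  data <- matrix(as.numeric(ints), nrow = n_ch) * res
  rownames(data) <- ch_names

  events <- read.table(f("_events.tsv"), sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE)
  probes <- read.table(f("_probes.tsv"), sep = "\t", header = TRUE,
                       stringsAsFactors = FALSE,
                       colClasses = c(answer = "character"))
  events$onset_s <- (events$onset_sample - 1) / fs
  probes$onset_s <- (probes$onset_sample - 1) / fs

  layout <- channel_layout(n_ch)
  layout$name <- ch_names
  truth <- NULL
  if (file.exists(f("_truth.tsv"))) {
    r <- read.table(f("_truth.tsv"), sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
    truth <- factor(inverse.rle(list(lengths = r$length, values = r$state)),
                    levels = MIND_STATES)
  }
  structure(list(data = data, fs = fs, channels = layout, events = events,
                 probes = probes, truth_states = truth,
                 n_samples = ncol(data), config = NULL),
            class = "mind_recording")
}
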