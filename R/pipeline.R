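# End-to-end pipeline: synth -> epoch -> markers/connectivity -> behavior
# -> decoding -> trial-by-trial state prediction, with a reproducibility
# manifest. One top-level seed fans out to per-stage child seeds through
# child_seed(), so any stage can be re-run in isolation.

#' Assemble a pipeline configuration
#'
#' @param seed top-level seed; every stochastic stage derives its own seed
#'   from it.
#' @param out_dir output directory.
#' @param session named list of [session_config()] overrides.
#' @param decode_stride timepoint stride for temporal decoding.
#' @param n_perm permutations for decoding/classifier nulls.
#' @param run_decoding,run_classifier stage switches.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("mindstate_run_"),
                            session = list(), decode_stride = 5,
                            n_perm = 100, run_decoding = TRUE,
                            run_classifier = TRUE) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 session = session, decode_stride = decode_stride,
                 n_perm = n_perm, run_decoding = run_decoding,
                 run_classifier = run_classifier),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any subset of the [pipeline_config()] fields.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline on one synthetic session
#'
#' Stages: generate session, write fixture, pre-probe and stimulus
#' epoching with the 5-s labeling rule, marker matrix, alpha-band
#' connectivity on the planted pairs, behavior summary and contrasts,
#' optional temporal decoding of stimulus category, optional trial-by-
#' trial state classification with prediction of unlabeled trials and
#' behavioral validation. Artifacts are written under `out_dir` together
#' with a manifest (config hash, seed, package version, per-file
#' checksums).
#'
#' @param config `pipeline_config` (or a YAML path).
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  cfg_file <- file.path(out, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))

  ses_args <- config$session
  ses_args$seed <- child_seed(config$seed, 10)
  scfg <- do.call(session_config, ses_args)

  ms_log("stage synth (seed ", scfg$seed, ")")
  rec <- generate_session(scfg)
  write_fixture(rec, out, stem = "session")

  ms_log("stage epoch")
  pre <- epoch_preprobe(rec)
  stim <- baseline_correct(epoch_stimuli(rec))
  stim <- label_trials(stim, rec$probes)
  saveRDS(pre, file.path(out, "epochs_preprobe.rds"))
  saveRDS(stim, file.path(out, "epochs_stimulus.rds"))

  ms_log("stage markers")
  mk <- compute_marker_matrix(pre)
  write.table(marker_long(mk), file.path(out, "markers_preprobe.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ms_log("stage connectivity")
  pairs <- planted_pairs(rec$channels)
  states_present <- intersect(MIND_STATES, unique(pre$metadata$state_label))
  conn <- if (length(states_present) >= 2)
    plv_wsmi_dissociation_check(pre, band = "alpha", pairs = pairs,
                                state_pairs = utils::combn(states_present, 2,
                                                           simplify = FALSE))
  else NULL
  if (!is.null(conn))
    write.table(conn, file.path(out, "connectivity_contrasts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  ms_log("stage behavior")
  bt <- behavior_table(rec$events, rec$fs,
                       labels = stim$metadata[, c("onset_sample", "state_label")])
  bsum <- summarize_behavior(bt[bt$state_label %in% MIND_STATES, ])
  write.table(bsum, file.path(out, "behavior_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  decoding <- NULL
  if (isTRUE(config$run_decoding)) {
    ms_log("stage decode")
    bal <- balance_subsample(stim, by = "stimulus_category",
                             seed = child_seed(config$seed, 20))
    curve <- temporal_decode(bal, stride = config$decode_stride,
                             seed = child_seed(config$seed, 21))
    decoding <- decode_significance(curve, bal, n_perm = config$n_perm,
                                    seed = child_seed(config$seed, 22))
    write.table(data.frame(time = decoding$times, auc = decoding$auc,
                           p = decoding$p, q = decoding$q_values,
                           significant = decoding$significant),
                file.path(out, "decoding_curve.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  classifier <- NULL
  if (isTRUE(config$run_classifier) &&
      length(intersect(MIND_STATES, unique(stim$metadata$state_label))) == 3) {
    ms_log("stage predict")
    ftab <- compute_features(stim, rec$channels)
    fit <- fit_crossval(ftab, seed = child_seed(config$seed, 30))
    pipe <- fit_full(ftab, seed = child_seed(config$seed, 31))
    preds <- predict_unlabeled(pipe, ftab)
    val <- validate_predictions(preds, bt)
    write.table(preds, file.path(out, "predictions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    classifier <- list(fit = fit, predictions = preds, validation = val)
  }

  files <- setdiff(list.files(out, full.names = TRUE), cfg_file)
  manifest <- list(package_version = as.character(utils::packageVersion("mindstate")),
                   seed = config$seed, config_hash = cfg_hash,
                   checksums = as.list(tools::md5sum(files)))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  ms_log("pipeline complete: ", out)
  invisible(list(recording = rec, preprobe = pre, stimulus = stim,
                 markers = mk, connectivity = conn, behavior = bsum,
                 decoding = decoding, classifier = classifier,
                 manifest = manifest, out_dir = out))
}
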