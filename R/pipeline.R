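#' Configuration for an end-to-end run
#'
#' Bundles the generator, filter, entropy and classifier settings of one
#' reproducible run. Serializable to JSON; re-running an identical
#' configuration reproduces identical outputs.
#'
#' @param synth a \code{\link{synth_config}}.
#' @param filters a \code{\link{filter_spec}}, or NULL to skip filtering
#'   (the generator's output is already band-limited; filtering mainly
#'   matters for recorded data).
#' @param entropy an \code{\link{entropy_params}}.
#' @param features feature subset, default all four.
#' @param classifiers classifier names, default all ten.
#' @param epoch_len_s epoch length in seconds.
#' @param normalize \code{"pooled"} (per-subject min-max over all
#'   epochs, the conventional choice), \code{"fold"} (re-fit per
#'   training fold) or \code{"none"}.
#' @param seed master seed for classifier fitting.
#' @return object of class \code{run_config}.
#' @export
run_config <- function(synth = synth_config(),
                       filters = NULL,
                       entropy = entropy_params(),
                       features = c("SE", "FE", "AE", "PE"),
                       classifiers = CLASSIFIER_NAMES,
                       epoch_len_s = 1,
                       normalize = c("pooled", "fold", "none"),
                       seed = 1L) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(synth, "synth_config"),
            is.null(filters) || inherits(filters, "filter_spec"),
            inherits(entropy, "entropy_params"),
            all(features %in% c("SE", "FE", "AE", "PE")),
            all(classifiers %in% CLASSIFIER_NAMES))
  structure(list(synth = synth, filters = filters, entropy = entropy,
                 features = features, classifiers = classifiers,
                 epoch_len_s = epoch_len_s, normalize = normalize,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Extract features for a whole dataset
#'
#' Applies (optional) filtering, epoching and entropy extraction to each
#' recording and returns one long feature table. Normal and fatigue
#' epochs of the same subject and channel are pooled.
#'
#' @param recordings list of \code{eeg_recording}s (e.g. from
#'   \code{\link{generate_dataset}}).
#' @param cfg a \code{\link{run_config}}.
#' @return long-format data.frame: subject, channel, epoch, label,
#'   feature, value.
#' @export
dataset_features <- function(recordings, cfg = run_config()) {
  tabs <- lapply(recordings, function(rec) {
    if (!is.null(cfg$filters)) rec <- apply_filters(rec, cfg$filters)
    sets <- epoch_recording(rec, cfg$epoch_len_s)
    do.call(rbind, lapply(sets, extract_features,
                          features = cfg$features, p = cfg$entropy))
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline
#'
#' simulate -> (filter) -> epoch -> entropy features -> normalize ->
#' LOO grid -> summary tables, written as TSV artifacts plus a JSON
#' manifest recording every setting in effect, so any stage can be
#' rerun or audited independently.
#'
#' @param cfg a \code{\link{run_config}}.
#' @param outdir output directory (created if missing); NULL writes
#'   nothing to disk.
#' @param verbose print per-cell progress.
#' @return invisibly, a list with \code{features}, \code{results},
#'   \code{table} (\code{\link{feature_classifier_table}}), \code{best}
#'   (\code{\link{best_combination_per_subject}}).
#' @export
run_pipeline <- function(cfg = run_config(), outdir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  recs <- generate_dataset(cfg$synth)
  feats <- dataset_features(recs, cfg)
  if (cfg$normalize == "pooled") feats <- normalize_features(feats)
  results <- evaluate_grid(feats, cfg$classifiers, seed = cfg$seed,
                           fold_normalize = cfg$normalize == "fold",
                           verbose = verbose)
  tab <- feature_classifier_table(results)
  best <- best_combination_per_subject(results)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(d, f) write.table(d, file.path(outdir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
    wr(feats, "features.tsv")
    wr(results, "results.tsv")
    wr(best, "best_combinations.tsv")
    acc <- data.frame(classifier = rownames(tab$acc_mean),
                      round(tab$acc_mean, 1), check.names = FALSE)
    wr(acc, "mean_accuracy.tsv")
    manifest <- list(
      package_version = as.character(utils::packageVersion("entrofatigue")),
      seed = cfg$seed, normalize = cfg$normalize,
      features = cfg$features, classifiers = cfg$classifiers,
      epoch_len_s = cfg$epoch_len_s,
      synth = unclass(cfg$synth),
      filters = if (is.null(cfg$filters)) NULL else unclass(cfg$filters),
      entropy = unclass(cfg$entropy))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
  }
  invisible(list(features = feats, results = results, table = tab,
                 best = best))
}
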