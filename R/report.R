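#' Feature x classifier mean-accuracy table
#'
#' Each cell is the mean over all (subject, channel) cells of the LOO
#' accuracy for that feature and classifier, with the sample (n-1) SD
#' alongside, plus row/column marginals; an AUC twin is returned as
#' well. Missing grid cells are reported as \code{NA}, never silently
#' dropped.
#'
#' @param results grid data.frame from \code{\link{evaluate_grid}}.
#' @return object of class \code{ef_table}: list with \code{acc_mean},
#'   \code{acc_sd}, \code{auc_mean}, \code{auc_sd} (classifier x feature
#'   matrices, in percent for accuracy), \code{n_cells}, and marginals.
#' @export
feature_classifier_table <- function(results) {
  stopifnot(all(c("feature", "classifier", "acc", "auc") %in% names(results)))
  feats <- sort(unique(results$feature))
  clfs <- sort(unique(results$classifier))
  agg <- function(col, f) {
    m <- matrix(NA_real_, length(clfs), length(feats),
                dimnames = list(clfs, feats))
    for (ci in clfs) for (fi in feats) {
      v <- results[[col]][results$classifier == ci & results$feature == fi]
      if (length(v) > 0) m[ci, fi] <- f(v)
    }
    m
  }
  sd1 <- function(v) if (length(v) > 1) sd(v) else 0
  out <- list(acc_mean = 100 * agg("acc", mean), acc_sd = 100 * agg("acc", sd1),
              auc_mean = agg("auc", mean), auc_sd = agg("auc", sd1),
              n_cells = agg("acc", length),
              feature_means = 100 * vapply(feats, function(fi)
                mean(results$acc[results$feature == fi]), 0),
              classifier_means = 100 * vapply(clfs, function(ci)
                mean(results$acc[results$classifier == ci]), 0))
  class(out) <- "ef_table"
  out
}

#' @export
print.ef_table <- function(x, ...) {
  cat("Mean accuracy (%) +/- SD over (subject, channel) cells\n")
  m <- matrix(sprintf("%.1f ± %.1f", x$acc_mean, x$acc_sd),
              nrow(x$acc_mean), dimnames = dimnames(x$acc_mean))
  print(m, quote = FALSE)
  cat("\nMean AUC +/- SD\n")
  m2 <- matrix(sprintf("%.3f ± %.3f", x$auc_mean, x$auc_sd),
               nrow(x$auc_mean), dimnames = dimnames(x$auc_mean))
  print(m2, quote = FALSE)
  invisible(x)
}

#' Best channel/feature/classifier combination per subject
#'
#' Argmax of LOO accuracy over all cells of each subject; ties broken by
#' higher AUC, then lexicographically by (channel, feature, classifier).
#' Subjects whose best accuracy is below 0.6 are flagged as showing no
#' usable signal (the null-data regime).
#'
#' @param results grid data.frame from \code{\link{evaluate_grid}}.
#' @return data.frame: subject, channel, feature, classifier, acc, auc,
#'   no_signal.
#' @export
best_combination_per_subject <- function(results) {
  subjects <- unique(results$subject)
  rows <- lapply(subjects, function(s) {
    r <- results[results$subject == s, ]
    r <- r[order(-r$acc, -r$auc, r$channel, r$feature, r$classifier), ]
    data.frame(subject = s, channel = r$channel[1], feature = r$feature[1],
               classifier = r$classifier[1], acc = r$acc[1], auc = r$auc[1],
               no_signal = r$acc[1] < 0.6, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank channels for a fixed feature and classifier
#'
#' Channels sorted by mean LOO accuracy over subjects, SD and AUC
#' columns alongside; the SD columns make between-seed rank instability
#' visible when channels are exchangeable.
#'
#' @param results grid data.frame from \code{\link{evaluate_grid}}.
#' @param feature feature name (e.g. \code{"FE"}).
#' @param classifier classifier name (e.g. \code{"RF"}).
#' @return data.frame of class \code{ef_ranking}: channel, mean_acc,
#'   sd_acc, mean_auc, sd_auc, n_cells, sorted by mean_acc descending
#'   (ties: higher mean_auc, then label order).
#' @export
rank_channels <- function(results, feature, classifier) {
  r <- results[results$feature == feature & results$classifier == classifier, ]
  if (nrow(r) == 0)
    stop(sprintf("no results for feature %s + classifier %s", feature,
                 classifier))
  chs <- unique(r$channel)
  sd1 <- function(v) if (length(v) > 1) sd(v) else 0
  tab <- do.call(rbind, lapply(chs, function(ch) {
    v <- r[r$channel == ch, ]
    data.frame(channel = ch, mean_acc = mean(v$acc), sd_acc = sd1(v$acc),
               mean_auc = mean(v$auc), sd_auc = sd1(v$auc),
               n_cells = nrow(v), stringsAsFactors = FALSE)
  }))
  tab <- tab[order(-tab$mean_acc, -tab$mean_auc, tab$channel), ]
  rownames(tab) <- NULL
  class(tab) <- c("ef_ranking", "data.frame")
  attr(tab, "feature") <- feature
  attr(tab, "classifier") <- classifier
  tab
}

#' @export
print.ef_ranking <- function(x, ...) {
  cat(sprintf("Channel ranking for %s + %s (mean accuracy %% over subjects)\n",
              attr(x, "feature"), attr(x, "classifier")))
  y <- data.frame(channel = x$channel,
                  acc = sprintf("%.1f ± %.1f", 100 * x$mean_acc,
                                100 * x$sd_acc),
                  auc = sprintf("%.3f ± %.3f", x$mean_auc, x$sd_auc))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Bar plot of a channel ranking
#'
#' @param x an \code{ef_ranking}.
#' @param ... passed to \code{barplot}.
#' @method plot ef_ranking
#' @export
plot.ef_ranking <- function(x, ...) {
  op <- par(mar = c(6, 4, 2, 1)); on.exit(par(op))
  bp <- barplot(100 * x$mean_acc, names.arg = x$channel, las = 2,
                ylab = "mean LOO accuracy (%)",
                main = sprintf("%s + %s", attr(x, "feature"),
                               attr(x, "classifier")), ...)
  arrows(bp, 100 * (x$mean_acc - x$sd_acc), bp,
         100 * (x$mean_acc + x$sd_acc), angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' @importFrom graphics arrows barplot par
NULL
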