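#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Positive class is the fatigue state: Sn = TP/(TP+FN),
#' Sp = TN/(TN+FP), Acc = (TP+TN)/total. A denominator of zero (no
#' positive or no negative instances) yields \code{NA} for the affected
#' rate rather than a misleading number.
#'
#' @param counts named list or vector with \code{tp}, \code{fp},
#'   \code{tn}, \code{fn}.
#' @return list with \code{acc}, \code{sn}, \code{sp}.
#' @export
compute_metrics <- function(counts) {
  counts <- as.list(counts)
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(!is.null(tp), !is.null(fp), !is.null(tn), !is.null(fn),
            tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  total <- tp + fp + tn + fn
  if (total == 0) stop("all confusion counts are zero")
  list(acc = (tp + tn) / total,
       sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Area under the ROC curve
#'
#' Threshold-sweep ROC area with the midrank tie convention, computed as
#' the normalized Mann-Whitney U statistic: the probability that a
#' random fatigue epoch scores above a random normal epoch, ties counted
#' one half.
#'
#' @param scores numeric per-instance scores, higher = more fatigue-like.
#' @param labels factor or 0/1 vector; 1/\code{"fatigue"} is positive.
#' @return AUC in [0, 1].
#' @export
compute_auc <- function(scores, labels) {
  pos <- labels == "fatigue" | labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present for AUC")
  r <- rank(scores)                       # midranks handle ties
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-epoch-out evaluation of one feature/classifier cell
#'
#' Every epoch of a single subject's pooled normal + fatigue epochs is
#' predicted by a model trained on all remaining epochs; confusion
#' counts accumulate over folds and the AUC is computed from the
#' held-out scores. Stochastic learners are re-seeded identically in
#' every fold, so the result is deterministic given the specification.
#'
#' @param values numeric feature vector (or n x p matrix), one row per
#'   epoch.
#' @param labels per-epoch labels (0/1 or \code{"normal"}/
#'   \code{"fatigue"}).
#' @param spec a \code{\link{classifier_spec}} or classifier name.
#' @param fold_normalize if TRUE, min-max normalization to [-1, 1] is
#'   re-fit on each training fold and the held-out value is clipped,
#'   avoiding the (label-free) range leakage of pooled normalization.
#' @return object of class \code{ef_eval}: counts, \code{acc},
#'   \code{sn}, \code{sp}, \code{auc}, n folds.
#' @export
loo_evaluate <- function(values, labels, spec, fold_normalize = FALSE) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  X <- .as_matrix(values)
  y <- factor(ifelse(labels == "fatigue" | labels == 1, "fatigue", "normal"),
              levels = c("normal", "fatigue"))
  n <- nrow(X)
  if (n != length(y)) stop("values and labels lengths differ")
  if (min(table(y)) < 2) stop("need at least 2 epochs per class")
  clf <- build_classifier(spec)
  pred <- character(n)
  score <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    Xte <- X[i, , drop = FALSE]
    if (fold_normalize) {
      for (j in seq_len(ncol(X))) {
        rng <- range(Xtr[, j])
        if (rng[1] < rng[2]) {
          Xtr[, j] <- 2 * (Xtr[, j] - rng[1]) / (rng[2] - rng[1]) - 1
          Xte[, j] <- min(max(2 * (Xte[, j] - rng[1]) / (rng[2] - rng[1]) - 1,
                              -1), 1)
        } else {
          Xtr[, j] <- 0; Xte[, j] <- 0
        }
      }
    }
    m <- clf$fit(Xtr, ytr)
    pred[i] <- as.character(clf$predict(m, Xte))
    score[i] <- clf$score(m, Xte)
  }
  tp <- sum(pred == "fatigue" & y == "fatigue")
  fp <- sum(pred == "fatigue" & y == "normal")
  tn <- sum(pred == "normal" & y == "normal")
  fn <- sum(pred == "normal" & y == "fatigue")
  met <- compute_metrics(list(tp = tp, fp = fp, tn = tn, fn = fn))
  structure(list(counts = list(tp = tp, fp = fp, tn = tn, fn = fn),
                 acc = met$acc, sn = met$sn, sp = met$sp,
                 auc = compute_auc(score, y), n = n,
                 classifier = spec$name),
            class = "ef_eval")
}

#' @export
print.ef_eval <- function(x, ...) {
  cat(sprintf("<ef_eval> %s, %d LOO folds: acc=%.3f sn=%.3f sp=%.3f auc=%.3f\n",
              x$classifier, x$n, x$acc, x$sn, x$sp, x$auc))
  invisible(x)
}

#' Evaluate the full (subject, channel, feature, classifier) grid
#'
#' Runs \code{\link{loo_evaluate}} for every combination present in the
#' feature table crossed with the requested classifiers.
#'
#' @param features long-format feature data.frame (see
#'   \code{\link{extract_features}}); typically normalized first.
#' @param classifiers character vector of classifier names or list of
#'   \code{\link{classifier_spec}}s.
#' @param seed seed handed to each classifier spec built from a name.
#' @param fold_normalize passed to \code{\link{loo_evaluate}}.
#' @param verbose print progress per cell.
#' @return data.frame, one row per cell: subject, channel, feature,
#'   classifier, tp, fp, tn, fn, acc, sn, sp, auc.
#' @export
evaluate_grid <- function(features, classifiers = CLASSIFIER_NAMES,
                          seed = 1L, fold_normalize = FALSE,
                          verbose = FALSE) {
  specs <- lapply(classifiers, function(cl)
    if (is.character(cl)) classifier_spec(cl, seed = seed) else cl)
  cells <- unique(features[, c("subject", "channel", "feature")])
  rows <- vector("list", nrow(cells) * length(specs))
  k <- 1L
  for (i in seq_len(nrow(cells))) {
    sel <- features$subject == cells$subject[i] &
      features$channel == cells$channel[i] &
      features$feature == cells$feature[i]
    v <- features$value[sel]; lab <- features$label[sel]
    ok <- !is.na(v)
    for (sp in specs) {
      ev <- loo_evaluate(v[ok], lab[ok], sp, fold_normalize = fold_normalize)
      rows[[k]] <- data.frame(subject = cells$subject[i],
                              channel = cells$channel[i],
                              feature = cells$feature[i],
                              classifier = sp$name,
                              tp = ev$counts$tp, fp = ev$counts$fp,
                              tn = ev$counts$tn, fn = ev$counts$fn,
                              acc = ev$acc, sn = ev$sn, sp = ev$sp,
                              auc = ev$auc, stringsAsFactors = FALSE)
      if (verbose)
        message(sprintf("subject %s %s %s %s: acc=%.3f auc=%.3f",
                        cells$subject[i], cells$channel[i],
                        cells$feature[i], sp$name, ev$acc, ev$auc))
      k <- k + 1L
    }
  }
  do.call(rbind, rows)
}
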