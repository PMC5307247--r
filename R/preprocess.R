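#' Filter specification for EEG preprocessing
#'
#' Mirrors conventional clinical preprocessing: a power-line notch plus a
#' broad band-pass. The contract is the frequency response (>= 20 dB
#' attenuation at the notch frequency, <= 1 dB passband ripple at 10 Hz),
#' not a specific kernel; filters are applied forward-backward
#' (zero-phase) so epoch alignment is preserved.
#'
#' @param notch_freq power-line frequency to reject, Hz (default 50).
#' @param notch_q notch quality factor (default 30; bandwidth = f/Q).
#' @param bp_low,bp_high band-pass edges in Hz (defaults 0.15 and 45).
#' @param bp_order Butterworth order for the low-pass section; the
#'   high-pass section uses order 2 for numerical stability at the very
#'   low cut-off.
#' @return object of class \code{filter_spec}.
#' @export
filter_spec <- function(notch_freq = 50, notch_q = 30,
                        bp_low = 0.15, bp_high = 45, bp_order = 4) {
  stopifnot(bp_low > 0, bp_low < bp_high, notch_freq > 0, notch_q > 0,
            bp_order >= 1)
  structure(list(notch_freq = notch_freq, notch_q = notch_q,
                 bp_low = bp_low, bp_high = bp_high, bp_order = bp_order),
            class = "filter_spec")
}

# RBJ biquad notch coefficients (b, a) for frequency f0 at rate fs.
.notch_coefs <- function(f0, q, fs) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Apply notch and band-pass filters to a recording
#'
#' @param rec an \code{eeg_recording}.
#' @param spec a \code{\link{filter_spec}}.
#' @return filtered \code{eeg_recording} of identical shape.
#' @export
apply_filters <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "filter_spec"))
  nyq <- rec$fs / 2
  if (spec$bp_high >= nyq) stop("band-pass upper edge at or above Nyquist")
  if (spec$notch_freq >= nyq) stop("notch frequency at or above Nyquist")
  nt <- .notch_coefs(spec$notch_freq, spec$notch_q, rec$fs)
  hp <- signal::butter(2, spec$bp_low / nyq, type = "high")
  lp <- signal::butter(spec$bp_order, spec$bp_high / nyq, type = "low")
  out <- rec
  for (ci in seq_len(nrow(rec$data))) {
    # demean first: the offset is rejected exactly and the huge DC step
    # cannot excite edge transients in the forward-backward passes
    x <- rec$data[ci, ] - mean(rec$data[ci, ])
    x <- signal::filtfilt(nt$b, nt$a, x)
    x <- signal::filtfilt(hp, x)
    x <- signal::filtfilt(lp, x)
    out$data[ci, ] <- x
  }
  out
}

#' Segment a recording into fixed-length epochs
#'
#' Epochs are contiguous, non-overlapping, half-open sample windows in
#' temporal order; trailing samples that do not fill an epoch are
#' discarded. Every epoch inherits the recording's state label.
#'
#' @param rec an \code{eeg_recording}.
#' @param epoch_len_s epoch length in seconds (default 1).
#' @return named list (one per channel) of \code{epoch_set} objects:
#'   \code{epochs} (n_epochs x epoch_samples matrix), \code{labels}
#'   (0 = normal, 1 = fatigue), \code{subject_id}, \code{channel},
#'   \code{fs}.
#' @export
epoch_recording <- function(rec, epoch_len_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  L <- round(epoch_len_s * rec$fs)
  n <- ncol(rec$data)
  if (n < L) stop("recording shorter than one epoch")
  n_ep <- n %/% L
  lab <- if (identical(rec$state, "fatigue")) 1L else 0L
  out <- lapply(seq_along(rec$channels), function(ci) {
    m <- matrix(rec$data[ci, seq_len(n_ep * L)], nrow = n_ep, ncol = L,
                byrow = TRUE)
    structure(list(subject_id = rec$subject_id, channel = rec$channels[ci],
                   epochs = m, labels = rep(lab, n_ep), fs = rec$fs),
              class = "epoch_set")
  })
  names(out) <- rec$channels
  out
}

#' Combine epoch sets of the same subject and channel
#'
#' Stacks (typically) the normal-state and fatigue-state epochs of one
#' channel into a single labeled set for classification.
#'
#' @param ... \code{epoch_set} objects with matching channel and fs.
#' @return one \code{epoch_set}.
#' @export
bind_epoch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "epoch_set"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, TRUE, "epoch_set")))
  ch <- unique(vapply(sets, `[[`, "", "channel"))
  fs <- unique(vapply(sets, `[[`, 0, "fs"))
  if (length(ch) != 1 || length(fs) != 1)
    stop("epoch sets differ in channel or sampling rate")
  structure(list(subject_id = sets[[1]]$subject_id, channel = ch,
                 epochs = do.call(rbind, lapply(sets, `[[`, "epochs")),
                 labels = unlist(lapply(sets, `[[`, "labels")), fs = fs),
            class = "epoch_set")
}

#' Min-max normalize feature values to [-1, 1] per subject
#'
#' Affine map of each (subject, channel, feature) column onto [-1, 1]:
#' the column minimum maps to -1 and the maximum to +1, computed over the
#' subject's pooled normal + fatigue epochs. Pooling before
#' cross-validation leaks the (label-free) test range into training; a
#' fold-local alternative is available in \code{\link{loo_evaluate}}.
#' A constant column has no range and is set to 0 with a warning.
#'
#' @param features long-format feature data.frame from
#'   \code{\link{extract_features}} (columns subject, channel, epoch,
#'   label, feature, value).
#' @return the same data.frame with \code{value} rescaled.
#' @export
normalize_features <- function(features) {
  stopifnot(all(c("subject", "channel", "feature", "value") %in% names(features)))
  key <- interaction(features$subject, features$channel, features$feature,
                     drop = TRUE)
  n_const <- 0L
  for (g in levels(key)) {
    i <- which(key == g)
    v <- features$value[i]
    rng <- range(v)
    if (rng[1] == rng[2]) {
      features$value[i] <- 0
      n_const <- n_const + 1L
    } else {
      features$value[i] <- 2 * (v - rng[1]) / (rng[2] - rng[1]) - 1
    }
  }
  if (n_const > 0)
    warning(sprintf("%d constant feature column(s) set to 0", n_const))
  features
}
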