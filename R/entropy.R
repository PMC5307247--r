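#' Parameters for the entropy features
#'
#' \code{m} and \code{r_factor} follow the common EEG convention:
#' embedding dimension 2 and tolerance r = 0.2 x SD of the analyzed
#' series (here the 1-s epoch, so r adapts per epoch). \code{fuzzy_n} is
#' the exponent of the fuzzy membership function exp(-(d/r)^n). Spectral
#' entropy is computed on a Hann-windowed, mean-removed periodogram; by
#' default all bins above DC up to Nyquist are retained
#' (\code{pe_band = NULL}), matching the definition of the Shannon
#' entropy of the normalized power spectrum; a band restriction such as
#' \code{c(0.5, 45)} may be supplied.
#'
#' @param m embedding dimension (default 2).
#' @param r_factor tolerance multiplier on the series SD (default 0.2).
#' @param fuzzy_n fuzzy membership exponent (default 2).
#' @param pe_band NULL for the full spectrum, or \code{c(low, high)} Hz.
#' @param pe_normalize divide by log(number of bins) so PE is in [0, 1].
#' @param pe_window \code{"hann"} (default; contains leakage from
#'   off-bin components) or \code{"rectangular"} (exact for on-bin
#'   frequencies).
#' @return object of class \code{entropy_params}.
#' @export
entropy_params <- function(m = 2L, r_factor = 0.2, fuzzy_n = 2,
                           pe_band = NULL, pe_normalize = TRUE,
                           pe_window = c("hann", "rectangular")) {
  stopifnot(m >= 1, r_factor > 0, fuzzy_n >= 1)
  pe_window <- match.arg(pe_window)
  if (!is.null(pe_band))
    stopifnot(length(pe_band) == 2, pe_band[1] >= 0, pe_band[1] < pe_band[2])
  structure(list(m = as.integer(m), r_factor = r_factor, fuzzy_n = fuzzy_n,
                 pe_band = pe_band, pe_normalize = pe_normalize,
                 pe_window = pe_window),
            class = "entropy_params")
}

.check_series <- function(x, p) {
  if (length(x) < p$m + 2) stop("series too short for embedding dimension m")
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("degenerate input: zero standard deviation (tolerance r would be 0)")
  p$r_factor * s
}

#' Approximate entropy
#'
#' Pincus' regularity statistic: the log-likelihood that runs of length
#' \code{m} that match within tolerance r (Chebyshev distance,
#' self-matches included) still match at length \code{m + 1}. Lower
#' values indicate a more regular series.
#'
#' @param x numeric series (one epoch).
#' @param p an \code{\link{entropy_params}}.
#' @return scalar ApEn.
#' @export
approximate_entropy <- function(x, p = entropy_params()) {
  r <- .check_series(x, p)
  apen_cpp(as.numeric(x), p$m, r)
}

#' Sample entropy
#'
#' Richman & Moorman's bias-reduced variant of approximate entropy:
#' -log(A/B) where B counts template pairs (self-matches excluded)
#' matching at length m and A those still matching at length m + 1, both
#' over the first N - m start points. Returns \code{Inf} with a warning
#' when no matching pair exists at either length.
#'
#' @inheritParams approximate_entropy
#' @return scalar SampEn (possibly \code{Inf}).
#' @export
sample_entropy <- function(x, p = entropy_params()) {
  r <- .check_series(x, p)
  v <- sampen_cpp(as.numeric(x), p$m, r)
  if (!is.finite(v))
    warning("no template match at length m or m+1; returning Inf sentinel")
  v
}

#' Fuzzy entropy
#'
#' Chen et al.'s soft variant of sample entropy: templates are
#' baseline-removed (their own mean subtracted) and the hard tolerance is
#' replaced by the membership exp(-(d/r)^n), so the statistic is finite
#' and smooth for any non-constant series.
#'
#' @inheritParams approximate_entropy
#' @return scalar FuzzyEn.
#' @export
fuzzy_entropy <- function(x, p = entropy_params()) {
  r <- .check_series(x, p)
  fuzzyen_cpp(as.numeric(x), p$m, r, p$fuzzy_n)
}

#' Spectral entropy
#'
#' Shannon entropy of the normalized power spectrum of one epoch:
#' mean-removed, Hann-windowed periodogram, bin powers normalized to a
#' probability vector, H = -sum p log p, optionally divided by log(K)
#' (K = retained bins) so the value lies in [0, 1]. Low for narrow-band,
#' high for broadband signals.
#'
#' @param x numeric series (one epoch).
#' @param fs sampling rate in Hz.
#' @param p an \code{\link{entropy_params}}.
#' @return scalar spectral entropy.
#' @export
spectral_entropy <- function(x, fs, p = entropy_params()) {
  n <- length(x)
  if (n < 64) stop("epoch too short for a spectral estimate")
  if (all(x == 0)) stop("degenerate input: all-zero signal")
  x <- x - mean(x)
  w <- if (identical(p$pe_window, "rectangular")) rep(1, n)
       else 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
  P <- Mod(fft(x * w)[2:(n %/% 2 + 1)])^2
  f <- (seq_len(n %/% 2)) * fs / n
  if (!is.null(p$pe_band)) {
    keep <- f >= p$pe_band[1] & f <= p$pe_band[2]
    if (sum(keep) < 2) stop("pe_band contains fewer than 2 frequency bins")
    P <- P[keep]
  }
  K <- length(P)
  tot <- sum(P)
  if (tot == 0) stop("degenerate input: no in-band power")
  q <- P / tot
  q <- q[q > 0]
  H <- -sum(q * log(q))
  if (p$pe_normalize) H / log(K) else H
}

#' Extract entropy features from an epoch set
#'
#' One value per (epoch, feature). The tolerance r is recomputed from
#' each epoch's own SD. Infinite sample-entropy sentinels (no template
#' match) are imputed with the largest finite value of the column and
#' the count is reported via a message. Epochs whose series is
#' degenerate (zero SD) abort unless they are fewer than 0.1\% of the
#' set, in which case their values are recorded as NA.
#'
#' @param es an \code{epoch_set}.
#' @param features subset of \code{c("SE", "FE", "AE", "PE")}.
#' @param p an \code{\link{entropy_params}}.
#' @return long-format data.frame: subject, channel, epoch, label,
#'   feature, value.
#' @export
extract_features <- function(es, features = c("SE", "FE", "AE", "PE"),
                             p = entropy_params()) {
  stopifnot(inherits(es, "epoch_set"))
  features <- match.arg(features, several.ok = TRUE)
  n_ep <- nrow(es$epochs)
  out <- vector("list", length(features))
  for (fi in seq_along(features)) {
    f <- features[fi]
    vals <- numeric(n_ep)
    n_bad <- 0L
    for (i in seq_len(n_ep)) {
      x <- es$epochs[i, ]
      v <- tryCatch(switch(f,
                           SE = suppressWarnings(sample_entropy(x, p)),
                           AE = approximate_entropy(x, p),
                           FE = fuzzy_entropy(x, p),
                           PE = spectral_entropy(x, es$fs, p)),
                    error = function(e) NA_real_)
      if (is.na(v)) n_bad <- n_bad + 1L
      vals[i] <- v
    }
    if (n_bad > 0) {
      if (n_bad / n_ep > 0.001)
        stop(sprintf("%d/%d epochs degenerate for feature %s", n_bad, n_ep, f))
      message(sprintf("%d degenerate epoch(s) recorded as NA for %s", n_bad, f))
    }
    n_inf <- sum(is.infinite(vals))
    if (n_inf > 0) {
      vals[is.infinite(vals)] <- max(vals[is.finite(vals)])
      message(sprintf("%d infinite %s value(s) imputed with column max", n_inf, f))
    }
    out[[fi]] <- data.frame(subject = es$subject_id, channel = es$channel,
                            epoch = seq_len(n_ep), label = es$labels,
                            feature = f, value = vals,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
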