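#' Configuration for the synthetic two-state EEG generator
#'
#' Defines the dimensions and the physiology-inspired signal model of the
#' simulated study: per channel, a sum of four band-limited oscillators
#' (delta 0.5-4, theta 4-8, alpha 8-13, beta 13-30 Hz) on top of 1/f
#' background noise. The fatigue state differs from the normal state only
#' through the regularity contrast \code{delta}: a fraction
#' \eqn{\rho = \delta/(1+\delta)} of the broadband noise power is moved
#' into a narrow-band alpha-range sinusoid, which lowers all four
#' entropies (the fatigued EEG is more regular and more narrow-band).
#' With \code{delta = 0} the two states are drawn from identical
#' distributions.
#'
#' @param n_subjects number of simulated subjects (default 12).
#' @param channels character vector of 10-20 montage labels.
#' @param fs sampling rate in Hz (default 1000).
#' @param epochs_per_state number of 1-s epochs per state (default 300).
#' @param epoch_len_s epoch length in seconds (default 1).
#' @param band_powers_normal,band_powers_fatigue named numeric vectors
#'   (delta, theta, alpha, beta) of relative oscillator amplitudes. Equal
#'   by default so the state contrast is carried by \code{delta} alone.
#' @param noise_sd standard deviation of the 1/f background noise.
#' @param noise_exponent spectral slope of the background noise.
#' @param delta regularity contrast (effect size, >= 0). 0 = no
#'   state difference.
#' @param subject_sd log-scale SD of per-subject band-amplitude offsets,
#'   shared across channels and states, so the best channel/combination
#'   varies between subjects.
#' @param boost_channel optional channel label that receives
#'   \code{boost_delta} instead of \code{delta} (planted-signal studies).
#' @param boost_delta regularity contrast for \code{boost_channel}.
#' @param seed integer master seed; every (subject, state, channel)
#'   stream is derived from it deterministically.
#' @return an object of class \code{synth_config}.
#' @export
synth_config <- function(n_subjects = 12,
                         channels = c("FP1", "FP2", "F3", "F4", "C3", "C4",
                                      "P3", "P4", "O1", "O2", "F7", "F8",
                                      "T3", "T4", "T5", "T6", "FZ", "CZ",
                                      "PZ", "OZ", "FC3", "FC4", "CP3", "CP4",
                                      "FT7", "FT8", "TP7", "TP8", "PO3", "PO4"),
                         fs = 1000,
                         epochs_per_state = 300,
                         epoch_len_s = 1,
                         band_powers_normal = c(delta = 1.0, theta = 0.7,
                                                alpha = 0.9, beta = 0.5),
                         band_powers_fatigue = band_powers_normal,
                         noise_sd = 1.0,
                         noise_exponent = 1.0,
                         delta = 1.0,
                         subject_sd = 0.15,
                         boost_channel = NULL,
                         boost_delta = NULL,
                         seed = 1L) {
  bands <- c("delta", "theta", "alpha", "beta")
  stopifnot(n_subjects >= 1, length(channels) >= 1, fs > 0,
            epochs_per_state >= 2, epoch_len_s > 0,
            all(bands %in% names(band_powers_normal)),
            all(bands %in% names(band_powers_fatigue)),
            all(band_powers_normal >= 0), all(band_powers_fatigue >= 0),
            noise_sd >= 0, delta >= 0)
  if (fs <= 2 * 30) stop("fs too low for the 13-30 Hz beta band (aliasing)")
  if (!is.null(boost_channel) && !boost_channel %in% channels)
    stop("boost_channel not among channel labels")
  structure(list(n_subjects = as.integer(n_subjects), channels = channels,
                 fs = fs, epochs_per_state = as.integer(epochs_per_state),
                 epoch_len_s = epoch_len_s,
                 band_powers_normal = band_powers_normal[bands],
                 band_powers_fatigue = band_powers_fatigue[bands],
                 noise_sd = noise_sd, noise_exponent = noise_exponent,
                 delta = delta, subject_sd = subject_sd,
                 boost_channel = boost_channel,
                 boost_delta = boost_delta, seed = as.integer(seed)),
            class = "synth_config")
}

# conventional EEG band edges in Hz
.band_edges <- list(delta = c(0.5, 4), theta = c(4, 8),
                    alpha = c(8, 13), beta = c(13, 30))

# 1/f^a Gaussian noise of length n via spectral shaping, unit SD.
.pink_noise <- function(n, exponent) {
  w <- rnorm(n)
  if (exponent == 0) return(w)
  W <- fft(w)
  k <- c(1, seq_len(n - 1))                     # avoid DC blow-up
  f <- pmin(k, n - k) / n                       # two-sided frequency index
  shape <- f^(-exponent / 2)
  shape[1] <- 0
  x <- Re(fft(W * shape, inverse = TRUE)) / n
  x / sd(x)
}

#' Generate one synthetic recording (one subject, one state)
#'
#' Each channel is an independent stream deterministically derived from
#' \code{(cfg$seed, subject_id, state, channel)}; per-subject band
#' offsets depend only on \code{(cfg$seed, subject_id)} so they are
#' shared between the two states.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @param subject_id integer subject index (1-based).
#' @param state \code{"normal"} or \code{"fatigue"}.
#' @return an \code{eeg_recording}: list with \code{subject_id},
#'   \code{state}, \code{channels}, \code{data} (channels x samples
#'   matrix) and \code{fs}.
#' @export
generate_recording <- function(cfg, subject_id, state) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!state %in% c("normal", "fatigue"))
    stop("state must be 'normal' or 'fatigue'")
  n <- round(cfg$epochs_per_state * cfg$epoch_len_s * cfg$fs)
  t <- (seq_len(n) - 1) / cfg$fs
  state_idx <- if (state == "fatigue") 2L else 1L
  bp <- if (state == "fatigue") cfg$band_powers_fatigue else cfg$band_powers_normal

  # per-subject multiplicative band offsets, identical across states
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(cfg$seed, subject_id, 777L))
  subj_off <- rlnorm(4, 0, cfg$subject_sd)
  names(subj_off) <- names(.band_edges)

  data <- matrix(0, nrow = length(cfg$channels), ncol = n,
                 dimnames = list(cfg$channels, NULL))
  for (ci in seq_along(cfg$channels)) {
    ch <- cfg$channels[ci]
    # oscillator frequencies/phases are a property of the subject's
    # channel, shared by both states, so that delta = 0 leaves nothing
    # for a classifier to learn
    set.seed(derive_seed(cfg$seed, subject_id, ci, 555L))
    x <- numeric(n)
    for (b in names(.band_edges)) {
      e <- .band_edges[[b]]
      f0 <- runif(1, e[1], e[2])
      ph <- runif(1, 0, 2 * pi)
      x <- x + bp[[b]] * subj_off[[b]] * sin(2 * pi * f0 * t + ph)
    }
    set.seed(derive_seed(cfg$seed, subject_id, state_idx, ci))
    d <- cfg$delta
    if (!is.null(cfg$boost_channel) && ch == cfg$boost_channel)
      d <- cfg$boost_delta %||% cfg$delta
    rho <- if (state == "fatigue") d / (1 + d) else 0
    # background noise is drawn independently per epoch (unit SD each):
    # a recording-level noise realization would couple all of a state's
    # epochs through its random low-frequency power and make the two
    # states distinguishable even at delta = 0
    L <- round(cfg$epoch_len_s * cfg$fs)
    noise <- cfg$noise_sd * as.numeric(vapply(
      seq_len(n %/% L), function(e) .pink_noise(L, cfg$noise_exponent),
      numeric(L)))
    x <- x + sqrt(1 - rho) * noise
    if (rho > 0) {
      f_nb <- runif(1, 8, 13)                   # narrow-band alpha component
      ph_nb <- runif(1, 0, 2 * pi)
      x <- x + sqrt(2 * rho) * cfg$noise_sd * sin(2 * pi * f_nb * t + ph_nb)
    }
    data[ci, ] <- x
  }
  structure(list(subject_id = subject_id, state = state,
                 channels = cfg$channels, data = data, fs = cfg$fs),
            class = "eeg_recording")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a full two-state dataset
#'
#' @param cfg a \code{\link{synth_config}}.
#' @return list of \code{n_subjects * 2} recordings (normal then fatigue
#'   per subject).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  recs <- vector("list", cfg$n_subjects * 2L)
  k <- 1L
  for (s in seq_len(cfg$n_subjects)) {
    for (st in c("normal", "fatigue")) {
      recs[[k]] <- generate_recording(cfg, s, st)
      k <- k + 1L
    }
  }
  recs
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s, state %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$state, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' Write a recording to disk
#'
#' \code{tsv}: a '#key=value' header block (subject, state, fs) followed
#' by a tab-separated table, one column per channel, one row per sample.
#' \code{edf}: European Data Format, 16-bit, physical range +/-200 uV,
#' one 1-s data record per second.
#'
#' @param rec an \code{eeg_recording}.
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"edf"}.
#' @export
write_recording <- function(rec, path, format = c("tsv", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "eeg_recording"))
  if (format == "edf") return(write_edf(rec, path))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#subject_id=%s", rec$subject_id),
               sprintf("#state=%s", rec$state),
               sprintf("#fs=%.10g", rec$fs)), con)
  writeLines(paste(rec$channels, collapse = "\t"), con)
  m <- t(rec$data)
  write.table(format(m, digits = 9, trim = TRUE, scientific = TRUE),
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a recording written by \code{\link{write_recording}}
#'
#' Format is inferred from the file: EDF files start with the 8-byte
#' version field "0       "; anything else is parsed as the TSV dialect.
#'
#' @param path file path.
#' @return an \code{eeg_recording}.
#' @export
read_recording <- function(path) {
  magic <- readBin(path, "raw", n = 8)
  if (length(magic) == 8 && rawToChar(magic) == "0       ")
    return(read_edf(path))
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#", "", h), "=", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  if (is.null(meta$fs)) stop("malformed header: missing fs")
  body <- lines[!grepl("^#", lines)]
  channels <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  vals <- suppressWarnings(
    as.numeric(unlist(strsplit(body[-1], "\t", fixed = TRUE))))
  if (anyNA(vals)) stop("non-numeric cell in recording table")
  m <- matrix(vals, ncol = length(channels), byrow = TRUE)
  if (ncol(m) != length(channels)) stop("channel-count mismatch")
  structure(list(subject_id = meta$subject_id %||% NA,
                 state = meta$state %||% NA,
                 channels = channels, data = t(m),
                 fs = as.numeric(meta$fs)),
            class = "eeg_recording")
}
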