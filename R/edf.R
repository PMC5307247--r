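# Minimal EDF (European Data Format) I/O for continuous EEG blocks.
# 256-byte fixed header + 256 bytes per signal, int16 little-endian data
# records of 1 s each. Physical range fixed at +/-200 uV (16-bit digital
# range), the common clinical EEG dialect; values outside are clipped.

.edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)        # left-justified
  substr(s, 1, width)
}

write_edf <- function(rec, path, phys_range = c(-200, 200)) {
  ns <- length(rec$channels)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  fs <- as.integer(round(fs))
  n <- ncol(rec$data)
  n_rec <- n %/% fs
  if (n_rec < 1) stop("recording shorter than one 1-s EDF record")
  dig_min <- -32768L; dig_max <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_field("0", 8),
    .edf_field(sprintf("subject_%s", rec$subject_id), 80),
    .edf_field(sprintf("state_%s", rec$state), 80),
    .edf_field("01.01.00", 8), .edf_field("00.00.00", 8),
    .edf_field(256 + 256 * ns, 8),
    .edf_field("", 44),
    .edf_field(n_rec, 8),
    .edf_field("1", 8),                                 # record duration (s)
    .edf_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  per_sig <- function(vals, width)
    writeChar(paste0(vapply(vals, .edf_field, "", width = width),
                     collapse = ""), con, eos = NULL)
  per_sig(rec$channels, 16)                             # label
  per_sig(rep("", ns), 80)                              # transducer
  per_sig(rep("uV", ns), 8)                             # physical dimension
  per_sig(rep(phys_range[1], ns), 8)
  per_sig(rep(phys_range[2], ns), 8)
  per_sig(rep(dig_min, ns), 8)
  per_sig(rep(dig_max, ns), 8)
  per_sig(rep("", ns), 80)                              # prefiltering
  per_sig(rep(fs, ns), 8)                               # samples per record
  per_sig(rep("", ns), 32)                              # reserved
  scale <- (dig_max - dig_min) / (phys_range[2] - phys_range[1])
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ci in seq_len(ns)) {
      phys <- pmin(pmax(rec$data[ci, idx], phys_range[1]), phys_range[2])
      dig <- as.integer(round((phys - phys_range[1]) * scale + dig_min))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("not an EDF file")
  patient <- rd(80); recording <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16); rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8)); phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8)); dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))                             # samples per record
  rdv(32)
  if (length(unique(spr)) != 1) stop("heterogeneous sampling rates unsupported")
  fs <- spr[1] / dur
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1], dimnames = list(labels, NULL))
  for (r in seq_len(n_rec)) {
    for (ci in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ci], size = 2,
                     signed = TRUE, endian = "little")
      phys <- phys_min[ci] + (dig - dig_min[ci]) *
        (phys_max[ci] - phys_min[ci]) / (dig_max[ci] - dig_min[ci])
      data[ci, ((r - 1) * spr[ci] + 1):(r * spr[ci])] <- phys
    }
  }
  structure(list(subject_id = sub("^subject_", "", patient),
                 state = sub("^state_", "", recording),
                 channels = labels, data = data, fs = fs),
            class = "eeg_recording")
}
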