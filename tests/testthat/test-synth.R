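test_that("generated recordings have the configured dimensions and are deterministic", {
  cfg <- synth_config(n_subjects = 1, channels = c("CP4", "O1"),
                      epochs_per_state = 5, epoch_len_s = 1, fs = 250,
                      seed = 4)
  rec <- generate_recording(cfg, 1, "normal")
  expect_equal(dim(rec$data), c(2, 5 * 250))
  expect_true(all(is.finite(rec$data)))
  rec2 <- generate_recording(cfg, 1, "normal")
  expect_identical(rec$data, rec2$data)
  # a different channel order position yields a different stream
  expect_false(identical(rec$data[1, ], rec$data[2, ]))
  expect_error(generate_recording(cfg, 1, "drowsy"), "state")
})

test_that("generate_dataset yields two recordings per subject with pooled epoch totals", {
  cfg <- synth_config(n_subjects = 3, channels = "CP4",
                      epochs_per_state = 4, fs = 200, seed = 2)
  recs <- generate_dataset(cfg)
  expect_length(recs, 6)
  states <- vapply(recs, `[[`, "", "state")
  expect_equal(sum(states == "normal"), 3)
  n_epochs <- sum(vapply(recs, function(r) ncol(r$data) %/% (r$fs * 1), 0))
  expect_equal(n_epochs, 3 * 2 * 4)
  recs2 <- generate_dataset(cfg)
  expect_identical(recs, recs2)
})

test_that("configuration invariants are enforced", {
  expect_error(synth_config(fs = 50), "aliasing")
  expect_error(synth_config(epochs_per_state = 1))
  expect_error(synth_config(boost_channel = "XX"), "boost_channel")
  expect_error(synth_config(delta = -1))
})

test_that("normal-state band-power densities follow the configured amplitude order", {
  # at low background noise the per-Hz power density of each band must
  # order as the configured oscillator amplitudes: delta > alpha > theta > beta
  cfg <- synth_config(n_subjects = 1, channels = "CP4",
                      epochs_per_state = 120, noise_sd = 0.2,
                      subject_sd = 0, seed = 6)
  rec <- generate_recording(cfg, 1, "normal")
  es <- epoch_recording(rec)[["CP4"]]
  P <- colMeans(t(apply(es$epochs, 1, function(x) Mod(fft(x)[2:501])^2)))
  f <- 1:500
  dens <- vapply(list(delta = c(0.5, 4), theta = c(4, 8),
                      alpha = c(8, 13), beta = c(13, 30)),
                 function(e) sum(P[f >= e[1] & f <= e[2]]) / diff(e), 0)
  expect_equal(order(dens, decreasing = TRUE), c(1, 3, 2, 4))
})

test_that("delta = 0 leaves no mean entropy difference between states", {
  ft <- synth_features(epochs_per_state = 100, delta = 0, seed = 12,
                       features = "SE", normalize = FALSE)
  p <- t.test(ft$value[ft$label == 0], ft$value[ft$label == 1])$p.value
  expect_gt(p, 0.01)
})

test_that("fatigue lowers fuzzy entropy on every channel at delta = 2", {
  for (seed in 1:3) {
    ft <- synth_features(channels = c("CP4", "O1", "FZ"),
                         epochs_per_state = 30, delta = 2, seed = seed,
                         features = "FE", normalize = FALSE)
    for (ch in unique(ft$channel)) {
      v <- ft[ft$channel == ch, ]
      expect_lt(mean(v$value[v$label == 1]), mean(v$value[v$label == 0]))
    }
  }
})

test_that("the normal-fatigue sample-entropy gap is non-decreasing in delta", {
  gap <- vapply(c(0, 0.5, 1, 2), function(d) {
    ft <- synth_features(epochs_per_state = 60, delta = d, seed = 31,
                         features = "SE", normalize = FALSE)
    mean(ft$value[ft$label == 0]) - mean(ft$value[ft$label == 1])
  }, 0)
  expect_true(all(diff(gap) > -0.02))      # monotone up to Monte-Carlo noise
  expect_gt(gap[4], gap[1])
})

test_that("tsv round-trip preserves the signal and metadata", {
  cfg <- synth_config(n_subjects = 1, channels = c("CP4", "O1"),
                      epochs_per_state = 2, fs = 100, seed = 8)
  rec <- generate_recording(cfg, 1, "fatigue")
  f <- tempfile(fileext = ".tsv")
  write_recording(rec, f, "tsv")
  back <- read_recording(f)
  expect_equal(back$channels, rec$channels)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$state, "fatigue")
  expect_lt(max(abs(back$data - rec$data)), 1e-6 * sd(rec$data))
  unlink(f)
})

test_that("reading a corrupted table fails loudly", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("#subject_id=1", "#state=normal", "#fs=100",
               "CP4\tO1", "0.1\t0.2", "oops\t0.3"), f)
  expect_error(read_recording(f), "non-numeric")
  unlink(f)
})

test_that("EDF round-trip of a +/-100 uV sinusoid is faithful to quantization", {
  cfg <- synth_config(n_subjects = 1, channels = "CP4", epochs_per_state = 2,
                      fs = 100, seed = 8)
  rec <- generate_recording(cfg, 1, "normal")
  rec$data[1, ] <- 100 * sin(2 * pi * 5 * (0:(ncol(rec$data) - 1)) / 100)
  f <- tempfile(fileext = ".edf")
  write_recording(rec, f, "edf")
  back <- read_recording(f)
  expect_equal(back$channels, "CP4")
  expect_equal(back$fs, 100)
  expect_gt(cor(back$data[1, ], rec$data[1, ]), 0.999)
  # 16-bit quantization of the +/-200 uV range: step ~ 6.1e-3 uV
  expect_lt(max(abs(back$data - rec$data)), 0.01)
  unlink(f)
})
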