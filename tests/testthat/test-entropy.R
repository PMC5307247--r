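test_that("optimized entropies equal the naive double-loop oracles", {
  set.seed(101)
  p <- entropy_params()
  gens <- list(function(n) rnorm(n),
               function(n) runif(n, -1, 1),
               function(n) arima.sim(list(ar = 0.8), n),
               function(n) sin(2 * pi * 7 * seq_len(n) / n) + 0.3 * rnorm(n))
  for (k in 1:12) {
    n <- sample(c(100, 200), 1, prob = c(0.8, 0.2))
    x <- as.numeric(gens[[1 + (k %% 4)]](n))
    r <- p$r_factor * sd(x)
    expect_equal(approximate_entropy(x, p), naive_apen(x, 2, r),
                 tolerance = 1e-12)
    expect_equal(suppressWarnings(sample_entropy(x, p)),
                 naive_sampen(x, 2, r), tolerance = 1e-12)
    expect_equal(fuzzy_entropy(x, p), naive_fuzzyen(x, 2, r, 2),
                 tolerance = 1e-12)
  }
})

test_that("degenerate and short series are rejected", {
  expect_error(sample_entropy(rep(5, 100)), "degenerate")
  expect_error(approximate_entropy(rep(5, 100)), "degenerate")
  expect_error(fuzzy_entropy(rep(5, 100)), "degenerate")
  expect_error(sample_entropy(c(1, 2, 3)), "short")
  expect_error(spectral_entropy(rep(0, 1000), 1000), "degenerate")
  expect_error(spectral_entropy(rnorm(32), 1000), "short")
})

test_that("perfectly regular alternating series has zero sample entropy", {
  x <- rep(c(1, 2), 50)
  expect_equal(sample_entropy(x), 0)
})

test_that("fuzzy entropy stays finite where sample entropy hits the Inf sentinel", {
  # alternating small/large levels where every template pair is at least
  # 99 apart while r = 0.2*SD is about 30: no match at any length
  x <- c(1, 100, 2, 200, 3, 300, 4, 400)
  expect_warning(v <- sample_entropy(x), "Inf sentinel")
  expect_true(is.infinite(v))
  expect_true(is.finite(fuzzy_entropy(x)))
})

test_that("regularity entropies are invariant to affine scaling a*x + b", {
  set.seed(11)
  x <- rnorm(150)
  y <- 3.7 * x + 42
  expect_equal(approximate_entropy(x), approximate_entropy(y),
               tolerance = 1e-10)
  expect_equal(sample_entropy(x), sample_entropy(y), tolerance = 1e-10)
  expect_equal(fuzzy_entropy(x), fuzzy_entropy(y), tolerance = 1e-10)
})

test_that("long i.i.d. Gaussian series reach the analytic matching-probability limit", {
  # P(extra coordinate matches) = 2*Phi(r/sqrt(2)) - 1 for N(0,1) pairs
  ref <- -log(2 * pnorm(0.2 / sqrt(2)) - 1)
  set.seed(202)
  se <- mean(replicate(6, sample_entropy(rnorm(5000))))
  ae <- mean(replicate(6, approximate_entropy(rnorm(5000))))
  expect_lt(abs(se - ref), 0.1)
  expect_lt(abs(ae - ref), 0.1)
})

test_that("sample entropy orders sinusoid < sinusoid+noise < noise at matched SD", {
  t <- (0:999) / 1000
  for (seed in 1:5) {
    set.seed(seed)
    s <- sin(2 * pi * 10 * t)
    mix <- s + rnorm(1000, sd = 0.5)
    nz <- rnorm(1000)
    v <- vapply(list(s, mix, nz),
                function(x) sample_entropy(x / sd(x)), 0)
    expect_true(v[1] < v[2] && v[2] < v[3])
  }
})

test_that("spectral entropy hits its narrow-band and broadband limits", {
  t <- (0:999) / 1000
  expect_lte(spectral_entropy(sin(2 * pi * 10 * t), 1000), 0.2)
  set.seed(5)
  pe <- replicate(10, spectral_entropy(rnorm(1000), 1000))
  expect_true(all(pe >= 0.9 & pe <= 1))
  # two equal-power exact-bin sinusoids, leakage-free (rectangular
  # window, on-bin frequencies): unnormalized H = log 2
  p <- entropy_params(pe_normalize = FALSE, pe_window = "rectangular")
  x <- sin(2 * pi * 10 * t) + cos(2 * pi * 20 * t)
  expect_equal(spectral_entropy(x, 1000, p), log(2), tolerance = 0.05 * log(2))
})

test_that("band-restricted spectral entropy rejects empty bands and stays in [0,1]", {
  t <- (0:999) / 1000
  p <- entropy_params(pe_band = c(0.5, 45))
  v <- spectral_entropy(sin(2 * pi * 10 * t) + rnorm(1000, sd = 0.1), 1000, p)
  expect_true(v >= 0 && v <= 1)
  expect_error(spectral_entropy(rnorm(1000), 1000,
                                entropy_params(pe_band = c(10, 10.5))),
               "fewer than 2")
})

test_that("extract_features returns one finite value per epoch and feature", {
  ft <- synth_features(epochs_per_state = 10, delta = 1, seed = 9,
                       features = c("SE", "FE", "AE", "PE"),
                       normalize = FALSE)
  expect_equal(nrow(ft), 4 * 20)
  expect_true(all(is.finite(ft$value)))
  expect_setequal(unique(ft$feature), c("SE", "FE", "AE", "PE"))
  expect_equal(sum(ft$label == 1), 4 * 10)
})
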