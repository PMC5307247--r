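test_that("confusion-count metrics follow the Sn/Sp/Acc formulas", {
  m <- compute_metrics(list(tp = 40, fn = 10, tn = 45, fp = 5))
  expect_equal(m$sn, 0.80)
  expect_equal(m$sp, 0.90)
  expect_equal(m$acc, 0.85)
  perfect <- compute_metrics(list(tp = 7, tn = 9, fp = 0, fn = 0))
  expect_equal(perfect$acc, 1)
  # degenerate denominators yield NA, not a wrong number
  expect_true(is.na(compute_metrics(list(tp = 0, fn = 0, tn = 5, fp = 5))$sn))
  expect_true(is.na(compute_metrics(list(tp = 5, fn = 5, tn = 0, fp = 0))$sp))
  expect_error(compute_metrics(list(tp = 0, fn = 0, tn = 0, fp = 0)), "zero")
})

test_that("AUC equals the Mann-Whitney pair-counting oracle, ties at one half", {
  set.seed(55)
  for (k in 1:25) {
    n <- sample(10:40, 1)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- if (k %% 3 == 0) sample(1:5, n, replace = TRUE) else rnorm(n)
    expect_equal(compute_auc(scores, labels), naive_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_equal(compute_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_error(compute_auc(rnorm(5), rep(1, 5)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(66)
  s <- rnorm(50); lab <- sample(c(0, 1), 50, replace = TRUE)
  a <- compute_auc(s, lab)
  expect_equal(compute_auc(exp(s), lab), a)
  expect_equal(compute_auc(2 * s + 7, lab), a)
})

test_that("random scores give chance-level AUC", {
  set.seed(77)
  aucs <- replicate(40, compute_auc(rnorm(200), rep(c(0, 1), 100)))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("LOO on a separable feature is perfect for any classifier", {
  v <- c(rnorm(10, 0, 0.05), rnorm(10, 5, 0.05))
  lab <- rep(c(0, 1), each = 10)
  for (nm in c("KNN", "DT", "GNB")) {
    ev <- loo_evaluate(v, lab, nm)
    expect_equal(ev$acc, 1, info = nm)
    expect_equal(ev$auc, 1, info = nm)
    expect_equal(ev$sn, 1, info = nm)
    expect_equal(ev$sp, 1, info = nm)
  }
})

test_that("LOO folds are hand-traceable on a 4-epoch KNN(k=1) example", {
  ev <- loo_evaluate(c(0, 0.1, 1, 1.1), c(0, 0, 1, 1),
                     classifier_spec("KNN", k = 1))
  # each held-out epoch's nearest neighbour shares its label
  expect_equal(ev$acc, 1)
  expect_equal(ev$counts, list(tp = 2, fp = 0, tn = 2, fn = 0))
})

test_that("confusion counts accumulated over folds are sufficient for accuracy", {
  set.seed(9)
  v <- rnorm(40); lab <- rep(c(0, 1), 20)
  ev <- loo_evaluate(v, lab, "GNB")
  m <- compute_metrics(ev$counts)
  expect_equal(ev$acc, m$acc)
  expect_equal(ev$n, 40)
  expect_equal(with(ev$counts, tp + fp + tn + fn), 40)
})

test_that("the held-out epoch never contributes to training", {
  # alternating labels on an evenly spaced 1-D feature with KNN k=1:
  # every point's nearest *other* point carries the opposite label, so
  # correct fold hygiene forces accuracy 0; had the held-out epoch
  # leaked into training it would be its own nearest neighbour and
  # accuracy would be 1.
  v <- seq(0, 1, length.out = 12)
  lab <- rep(c(0, 1), 6)
  ev <- loo_evaluate(v, lab, classifier_spec("KNN", k = 1))
  expect_equal(ev$acc, 0)
})

test_that("labels shuffled on null features stay in the chance band", {
  ft <- synth_features(epochs_per_state = 100, delta = 0, seed = 23,
                       features = "SE")
  set.seed(23)
  lab <- sample(ft$label)
  ev <- loo_evaluate(ft$value, lab, classifier_spec("KNN", seed = 23))
  expect_gte(ev$acc, 0.4)
  expect_lte(ev$acc, 0.6)
})

test_that("fold-local normalization changes no separable verdict and clips to [-1,1]", {
  v <- c(rnorm(10, 0, 0.05), rnorm(10, 5, 0.05))
  lab <- rep(c(0, 1), each = 10)
  ev <- loo_evaluate(v, lab, "KNN", fold_normalize = TRUE)
  expect_equal(ev$acc, 1)
})

test_that("evaluate_grid returns one row per cell with coherent metrics", {
  ft <- synth_features(channels = c("CP4", "O1"), epochs_per_state = 15,
                       delta = 2, seed = 3, features = c("FE", "PE"))
  res <- evaluate_grid(ft, c("KNN", "DT"), seed = 3)
  expect_equal(nrow(res), 2 * 2 * 2)
  expect_true(all(res$tp + res$fp + res$tn + res$fn == 30))
  expect_true(all(res$acc >= 0 & res$acc <= 1))
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  expect_equal(res$acc, (res$tp + res$tn) / 30)
})
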