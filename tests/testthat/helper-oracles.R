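# Naive O(N^2) double-loop reference implementations of the template
# entropies, kept deliberately independent of the compiled kernels.

naive_apen <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    s <- 0
    for (i in seq_len(nt)) {
      cnt <- 0
      for (j in seq_len(nt)) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r)
          cnt <- cnt + 1
      }
      s <- s + log(cnt / nt)
    }
    s / nt
  }
  phi(m) - phi(m + 1)
}

naive_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) for (j in (i + 1):nt) {
    d <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
    if (d <= r) {
      B <- B + 1
      if (max(d, abs(x[i + m] - x[j + m])) <= r) A <- A + 1
    }
  }
  if (A == 0 || B == 0) return(Inf)
  -log(A / B)
}

naive_fuzzyen <- function(x, m, r, nf) {
  n <- length(x)
  nt <- n - m
  phi <- function(mm) {
    tpl <- lapply(seq_len(nt), function(i) {
      v <- x[i:(i + mm - 1)]; v - mean(v)
    })
    s <- 0
    for (i in 1:(nt - 1)) for (j in (i + 1):nt)
      s <- s + exp(-(max(abs(tpl[[i]] - tpl[[j]])) / r)^nf)
    s / (nt * (nt - 1) / 2)
  }
  log(phi(m)) - log(phi(m + 1))
}

# Mann-Whitney AUC by explicit pair counting, ties counted one half.
naive_auc <- function(scores, labels) {
  pos <- scores[labels == 1 | labels == "fatigue"]
  neg <- scores[labels == 0 | labels == "normal"]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Small two-state feature table straight from the generator.
synth_features <- function(n_subjects = 1, channels = "CP4",
                           epochs_per_state = 50, delta = 2, seed = 1,
                           features = "FE", normalize = TRUE, ...) {
  cfg <- synth_config(n_subjects = n_subjects, channels = channels,
                      epochs_per_state = epochs_per_state, delta = delta,
                      seed = seed, ...)
  ft <- dataset_features(generate_dataset(cfg),
                         run_config(synth = cfg, features = features,
                                    normalize = "none"))
  if (normalize) ft <- normalize_features(ft)
  ft
}
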