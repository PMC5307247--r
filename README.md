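# entrofatigue

Single-channel EEG analysis of driver fatigue: which electrode, which
entropy feature and which classifier best separate 1-second epochs of a
normal driving state from a fatigued one?

Fatigued EEG is more regular and more narrow-band than alert EEG, so
signal-complexity measures discriminate the two states. `entrofatigue`
implements the complete comparison harness:

* **Four entropy features per epoch** — sample entropy
  SE = −ln(A/B) (conditional probability that templates matching at
  length *m* still match at length *m*+1, self-matches excluded),
  approximate entropy AE = Φ^m(r) − Φ^{m+1}(r) (self-matches included),
  fuzzy entropy FE (baseline-removed templates, soft membership
  e^{−(d/r)^n}), and spectral entropy PE = −Σ p_k ln p_k / ln K of the
  normalized power spectrum. Template entropies use the Chebyshev
  distance with m = 2 and r = 0.2·SD of the epoch; the compiled kernels
  are cross-checked against naive double-loop oracles to 1e−12.
* **Preprocessing** — 50 Hz notch + 0.15–45 Hz band-pass, zero-phase;
  segmentation into contiguous 1-s epochs; per-subject min–max scaling
  of features to [−1, 1].
* **Ten classifiers** under one contract (fit / predict / score):
  KNN (k = 5), linear SVM, RBF SVM (γ = 2, C = 1), Gaussian process,
  decision tree (depth ≤ 10), random forest (10 trees, depth ≤ 10),
  MLP (100 hidden units), AdaBoost (50 stumps), Gaussian naive Bayes,
  QDA.
* **Leave-one-epoch-out evaluation** per (subject, channel, feature,
  classifier) cell: accuracy, sensitivity, specificity (fatigue =
  positive class) and the Mann–Whitney AUC from held-out scores.
* **Ranking** — feature × classifier mean ± SD tables, per-subject best
  combination (ties: AUC, then lexicographic), channel rankings.
* **A synthetic two-state EEG generator** (band oscillators over 1/f
  noise; fatigue moves a fraction δ/(1+δ) of the noise power into a
  narrow alpha-band component, lowering all four entropies) so the
  whole pipeline is testable without recordings, plus TSV/EDF I/O.

## Worked example

```r
library(entrofatigue)

cfg <- run_config(
  synth = synth_config(n_subjects = 2, channels = c("CP4", "O1"),
                       epochs_per_state = 30, delta = 1.5, seed = 42),
  features = c("SE", "FE", "PE"),
  classifiers = c("KNN", "RF", "LS"),
  seed = 42)
run <- run_pipeline(cfg)
print(run$table)
```

```
Mean accuracy (%) +/- SD over (subject, channel) cells
    FE         PE         SE        
KNN 94.2 ± 4.0 87.5 ± 6.9 93.8 ± 4.6
LS  95.4 ± 2.8 89.2 ± 5.2 94.6 ± 3.7
RF  92.1 ± 3.7 80.8 ± 9.7 90.8 ± 5.7
```

Each cell is the mean LOO accuracy over the 2 subjects × 2 channels at
that feature/classifier pair, ± the sample SD across those four cells.
At this effect size (δ = 1.5, i.e. 60 % of the broadband noise power
turned into a narrow-band regular component in the fatigue state) the
regularity entropies separate the states well, while the spectral
entropy — a cruder summary of the same shift — trails by several
points.

```r
print(best_combination_per_subject(run$results))
```

```
  subject channel feature classifier       acc       auc no_signal
1       1     CP4      FE         LS 0.9833333 1.0000000     FALSE
2       2     CP4      FE         LS 0.9666667 0.9944444     FALSE
```

```r
print(rank_channels(run$results, "FE", "RF"))
```

```
Channel ranking for FE + RF (mean accuracy % over subjects)
 channel        acc           auc
     CP4 95.0 ± 2.4 0.981 ± 0.003
      O1 89.2 ± 1.2 0.951 ± 0.015
```

`no_signal` would flag a subject whose best accuracy stays under 0.6 —
the chance regime; with δ = 0 the generator produces state-identical
distributions and every classifier sits in the binomial band around
50 %.

A thin command-line front end over the same functions lives at
`inst/scripts/entrofatigue.R` (subcommands `simulate`, `features`,
`evaluate`, `report`, `run`).

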