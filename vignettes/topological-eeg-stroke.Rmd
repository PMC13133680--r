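---
title: "Higher-order topological features for EEG-based stroke severity classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Higher-order topological features for EEG-based stroke severity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Stroke severity in the acute phase is graded clinically with the NIHSS
score; patients with NIHSS ≤ 4 are conventionally called *mild* and
those with 5–15 *moderate*. `eegtopo` implements an EEG-based classifier
of this binary distinction that augments conventional signal and
network descriptors with *higher-order* topological structure of the
functional brain network — the cycles that pairwise connectivity
measures alone do not see.

The processing chain is:

1. **Band filtering and segmentation.** Each multichannel recording is
   filtered into one of five rhythms (delta 1–3, theta 4–7, alpha 8–12,
   beta 13–30, gamma 31–40 Hz) with a zero-phase forward–backward
   4th-order Butterworth band-pass, then cut into one non-overlapping
   window per trial.
2. **Functional connectivity.** Per segment, a channels × channels
   coupling matrix: Pearson correlation (PCC) or the phase-locking
   value, `PLV_ij = |mean_t exp(i(φ_i(t) − φ_j(t)))|`, with phases from
   the analytic (Hilbert) signal of each band-filtered channel.
3. **Topology.** The coupling matrix becomes a dissimilarity
   `d_ij = 1 − |a_ij|`, the input of a Vietoris–Rips filtration capped
   at edge length 1.0. Persistent homology yields a diagram of
   (birth, death) pairs per dimension (H0 components, H1 cycles);
   diagrams are vectorized as persistence landscapes, Betti curves and
   persistent entropy, summarized by eight graph-level descriptors
   (landscape amplitudes with 1 and 2 layers for H0/H1, Betti
   amplitudes for H0/H1, entropies for H0/H1; p = 1 norms over
   100-point grids).
4. **Node features.** Per channel: mean absolute value, standard
   deviation, skewness, excess kurtosis, band power (Welch), and — on
   the thresholded PLV graph — local clustering coefficient and
   normalized betweenness. The retained set (mean absolute value,
   standard deviation, band power, betweenness, and seven of the eight
   higher-order descriptors, dropping the H1 persistent entropy) gives
   the 29 × 11 per-segment feature matrix. Graph-level topological
   descriptors are broadcast to every node row.
5. **Classifier.** A lightweight dense graph convolutional network:
   one graph convolution `D̃^{-1/2}(A+I)D̃^{-1/2} X Θ` from F = 11
   features to width W = 14, batch normalization (ε = 1e−5), LeakyReLU
   (α = 0.01) and dropout, flatten to the 406-dimensional embedding,
   two fully connected layers (406 → 29 → 2), log-softmax. Training:
   Adam on cross-entropy, learning rate divided by 10 every 50 epochs,
   10-fold subject-wise cross-validation against a fixed held-out test
   list. Class imbalance is handled with SMOTE.
6. **Cycle-ratio analysis.** Per segment, the longest-persistence
   finite cycle class (H1/H2) is selected, the subgraph of all edges
   entering the filtration within its lifetime is built, and each
   node's *cycle ratio* — the sum over co-cyclic nodes j of
   `c_ij / c_jj`, where `c` counts shared minimum-length cycles — is
   averaged over segments and compared between severity groups
   (Mann–Whitney per channel, Benjamini–Hochberg across channels).

## What the synthetic cohort emulates

No public accession string exists for the reference dataset, so the
package ships a generator that reproduces its *structure*: 50 subjects
(33 mild, 17 moderate), 20 trials of 8 s each, 29 channels in a 10-20
montage, five analysis bands. NIHSS scores are drawn uniformly from
{1..4} (mild) and {5..11} (moderate), matching the reference group
means approximately and guaranteeing the U = 0 separation that defines
the labeling.

The class signal is planted **only** as band-limited phase-coupling
topology. Each class carries a set of coupled channel *rings* in the
gamma band: ring channel i receives `s_i + s_{i+1 (mod L)}`, where the
`s_k` are independent narrowband sinusoids (random frequency within the
band and phase per trial). Adjacent ring channels thus share exactly
one component — measured PLV ≈ 0.4 versus ≈ 0.09 background — while
non-adjacent channels share none, so the PLV graph contains a genuine
ring and the distance matrix a persistent H1 class. (A single
oscillation shared by all ring channels with phase lags was considered
and rejected: it makes *every* ring pair phase-locked, a clique whose
cycle the filtration fills immediately, leaving no persistent H1.)
Mild subjects carry one 4-channel frontal ring; moderate subjects that
ring plus a 5-channel centro-parietal ring. The coupling strength κ
scales the oscillation amplitude (1.5 κ × noise SD per component);
κ = 0 removes the effect entirely, making the classes exchangeable —
the null cohort used as a negative control.

What the generator does **not** emulate: 1/f background spectra,
artifacts (ocular, myogenic), volume conduction, inter-subject montage
variability, or any physiologically realistic source geometry. Passing
tests on this cohort therefore demonstrate that the pipeline detects
planted phase-coupling topology above noise — not that it attains any
particular accuracy on clinical EEG.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `fs` | 250 Hz | sampling rate; not stated by the reference protocol, any value > 80 Hz works |
| band edges | table above | fixed by the five-rhythm convention |
| window | 8 s (2–8 configurable) | one window per trial; sub-8-s windows anchor to the trial phases |
| trial phases | instruction [0,2) s, MI [2,6) s, break [6,8) s | an assumption: the layout reproduces the documented phase coverage of every window length (2–4 s start at the MI cue, 5–6 s reach back into instruction, 7–8 s into the break) but the exact boundaries are not printed anywhere; configurable via `trial_phases()` |
| montage | 29 labels | the 24 electrodes named by the sensitivity ladder plus Cz, CPz, FT7, FT8, TP7 (assumption; configurable) |
| PLV threshold τ | 0.3 | default adjacency sparsity; 0.5/0.8/full are ablation settings |
| filtration cap | 1.0 | the range of `1 − |a|` distances |
| landscape/Betti grids | n = 100, p = 1 | vectorization resolution and norm |
| denoising | min lifetime 0, drop H2 | the "significant feature" rule of the reference analysis is unstated, so the lifetime threshold is exposed rather than guessed; H2 is always dropped for features |
| dropout, initial lr | 0.3, 1e−3 | band/metric-dependent in the reference protocol but never printed; plain config entries here |
| SMOTE | k = 5, seed 42 | convex interpolation within the minority class |
| CV | 10 folds, 150 epochs, seed 42 | subject-wise, fixed test list |

## Numerical and design choices

- **Log base.** Persistent entropy uses the natural log (configurable);
  "log" in the defining formula is read as `ln`, the usual convention
  in the persistent-entropy literature.
- **Infinite classes.** The essential H0 class (and anything else alive
  at the cap) is truncated to death = 1.0 and flagged `capped`; capped
  classes participate in vectorizations but are ineligible for the
  cycle analysis.
- **Vectorization grid.** Per-diagram, spanning [min birth, max death]
  of the requested dimension; a degenerate zero-width span returns zero
  amplitudes. One consequence worth knowing: because every H0 class is
  born at 0 and the capped class dies at 1.0, the first H0 landscape
  layer is always the same tent, so `LandAmp_H0_N1` is constant across
  segments (its z-scoring warns about zero variance and leaves the
  column centered). It is retained for fidelity to the published
  feature list.
- **Cycle-class selection.** The "longest persistence" rule is applied
  to dimensions ≥ 1 only. Finite H0 classes exist for every metric (the
  merge tree), so admitting them would make the advertised degenerate
  case — no finite class on an all-equal distance matrix — unreachable,
  and a *cycle* analysis seeded by a component class would be
  incoherent. Ties resolve by earliest birth, then lowest dimension.
- **Cycle-ratio formula.** `r_i = Σ_{j : c_ij > 0} c_ij / c_jj` with
  `r_i = 0` when i lies on no minimal cycle; `c_ij` counts cycles in
  the union of all per-node minimum-length cycle sets that contain both
  i and j. The implementation is validated against exhaustive
  enumeration of all simple cycles on small graphs, giving 3 on a
  triangle and n on an n-cycle.
- **Graph for node features.** Local network features always use the
  τ = 0.3 PLV adjacency — the same graph the classifier propagates
  over — even in PCC experiments, so each sample has a single graph
  definition; the connectivity *metric* choice governs the distance
  matrix feeding the topological features.
- **SMOTE placement and leakage.** Two modes are supported. The
  *global* mode (default of `experiment_config`) oversamples once
  before splitting, which is what the reference protocol's fixed test
  list (containing synthetic subject ids above 50) implies; it is
  measurably leaky, because synthetic training samples interpolate
  test-subject segments. The *fold* mode oversamples inside each
  training partition only and evaluates on real subjects; it is the
  mode used for the package's own null-control experiment, where it
  keeps a κ = 0 cohort at chance accuracy while the planted cohort is
  classified essentially perfectly.
- **Broadcasting.** The 29 × 11 shape forces node-wise placement of the
  seven graph-level topological features; replicating them across rows
  is the minimal consistent reading. Whether the reference analysis
  instead computed per-node subgraph topology is unknowable from the
  printed feature names.
- **Homology depth for features.** The eight descriptors use only
  H0/H1 (H2 is discarded by the denoising rule before any descriptor is
  formed), so the feature path computes homology up to H1; the result
  is provably identical to computing H2 and dropping it, at about a
  tenth of the cost. The cycles module keeps the full depth, where H2
  classes are eligible.
- **Determinism.** Every stochastic step (cohort noise, SMOTE draws,
  weight initialization, shuffling, dropout) flows from explicit seeds;
  two runs with one seed are bit-identical. Mann–Whitney p-values use
  the tie-corrected normal approximation without continuity correction.

## Problem sizes used by the test suite

The package's own experiments run at the reference scale — 50 subjects
× 20 trials × 29 channels — for the end-to-end classification checks,
with 50 training epochs and 10 folds; unit tests use small cohorts
(2–8 subjects, 2–4 trials) and ≤ 8-point inputs where independent
brute-force oracles (dense boundary-matrix reduction for persistence,
exhaustive simple-cycle enumeration for cycle ratios, pair counting for
the rank test) are affordable. The cycle-ratio group comparison in the
acceptance script uses 3 segments per subject.

## Known limitations

- Synthetic data only; no claim of clinical accuracy transfers from it.
- The EDF writer stores signals and header metadata; trial onsets and
  NIHSS travel in the JSON sidecar rather than EDF+ annotations.
- The exact band-dependent dropout rates and learning rates of the
  reference protocol are unpublished; defaults here are sensible, not
  reconstructed.
- Betweenness/clustering are computed on the binary thresholded graph;
  weighted variants are out of scope.
- The shortest-cycle search is exact and fast on the sparse lifetime
  subgraphs this pipeline produces, but worst-case exponential on dense
  graphs with large girth.
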