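# eegtopo

Stroke severity classification from EEG functional brain networks,
fusing **higher-order topological features** (persistent homology of
connectivity distance matrices) with conventional signal and network
descriptors, classified by a lightweight **dense graph convolutional
network**.

## Who this is for

Researchers studying EEG biomarkers of stroke severity (mild, NIHSS ≤ 4,
versus moderate, 5 ≤ NIHSS ≤ 15) or, more generally, anyone who wants a
self-contained R implementation of persistence-based brain-network
features: Vietoris–Rips filtration of `d_ij = 1 − |a_ij|` distance
matrices, persistence landscapes, Betti curves, persistent entropy, and
cycle-ratio node importance — together with a graph classifier that
consumes them.

## The method in brief

Per 8-s segment of band-filtered EEG (delta/theta/alpha/beta/gamma), a
channels × channels coupling matrix is computed (Pearson correlation or
phase-locking value, `PLV_ij = |⟨e^{i(φ_i−φ_j)}⟩_t|`). Its distance
transform feeds a Vietoris–Rips filtration (cap 1.0); the persistence
diagram is vectorized as

- landscape amplitudes `‖λ‖₁ = Σ_k Σ_j λ_k(t_j)` for 1 and 2 layers
  (H0 and H1),
- Betti-curve amplitudes `Σ_j β(t_j)` (H0 and H1),
- persistent entropies `H = −Σ p_i ln p_i`, `p_i = (d_i−b_i)/Σ(d_i−b_i)`.

These graph-level descriptors, broadcast to nodes, join mean absolute
value, standard deviation, band power and betweenness centrality in a
29 × 11 feature matrix. A single dense graph convolution
(`D̃^{−1/2}(A+I)D̃^{−1/2} X Θ`, F = 11 → W = 14) over the τ = 0.3
thresholded PLV graph, batch norm, LeakyReLU/dropout, and two dense
layers (406 → 29 → 2, log-softmax) classify each segment; training uses
Adam, step learning-rate decay, SMOTE rebalancing and subject-wise
10-fold cross-validation with a fixed test list. A cycle-ratio module
identifies channels prominently involved in the most persistent cycle
structures.

Because the reference clinical dataset is not redistributable, the
package ships a synthetic cohort generator (50 subjects: 33 mild / 17
moderate, 20 × 8-s trials, 29 channels) that plants class-dependent
gamma-band phase-coupling *rings* — the discriminative signal is purely
topological. See the methods vignette
(`vignettes/topological-eeg-stroke.Rmd`) for every modeling decision.

## Worked example

```r
library(eegtopo)

spec <- cohort_spec(n_mild = 6, n_moderate = 4, n_trials = 6, seed = 42)
cohort <- generate_cohort(spec)
cohort[[1]]
#> <eeg_recording> subject 1: 29 ch x 12000 samples @ 250 Hz, 6 trials, mild (NIHSS 1)

seg <- segment(bandpass(cohort[[1]], "gamma"), 8)[[1]]
d   <- distance_matrix(plv_matrix(seg))
diag <- vr_persistence(d, max_dim = 1, max_edge = 1)
head(diag[diag$dimension == 1, ], 3)
#>    dimension     birth     death capped
#> 30         1 0.6524685 0.8665676  FALSE
#> 31         1 0.8102800 0.8661640  FALSE
#> 32         1 0.8140701 0.8741793  FALSE

round(higher_order_vector(d), 3)
#>        LandAmp_H0_N1        LandAmp_H0_N2        LandAmp_H1_N1
#>               24.747               42.167                4.900
#>        LandAmp_H1_N2          BettiAmp_H0          BettiAmp_H1
#>                5.381             2247.000              373.000
#> PersistenceEntropy_0 PersistenceEntropy_1
#>                3.361                2.963

samples <- cohort_samples(cohort, band = "gamma", metric = "plv")
cv <- cross_validate(samples, model_config(),
                     train_config(epochs = 40, folds = 5, seed = 42,
                                  test_ids = c("2", "8")),
                     smote = "fold")
round(cv$mean, 3)
#>  accuracy        f1    recall precision       auc
#>     0.983     0.982     0.967     1.000     1.000
```

The H1 rows are gamma-band cycles in the phase-locking network (birth =
distance at which the cycle closes, death = distance at which it fills
in); the planted frontal ring is what makes `BettiAmp_H1` and the H1
landscape amplitudes class-informative, and the cross-validated metrics
show the classifier recovering that planted signal from a held-out test
subject pair.

A thin command-line wrapper (`inst/cli/eegtopo`) exposes `synth`,
`grid` and `cycles` verbs over the same functions.

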