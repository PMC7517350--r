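---
title: "Decoding alpha-oscillation brain networks by connection-cluster classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding alpha-oscillation brain networks by connection-cluster classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sensor-space EEG connectivity is contaminated by volume conduction: one
cortical source is seen by many electrodes, so correlation-based
connectivity matrices contain artificial and spurious ("ghost") links.
Rather than trying to suppress that mixing, the framework implemented here
mines the contaminated matrices directly.  Its unit of analysis is the
**connection cluster** — a node together with every edge incident to it.
Because signal mixing is essentially constant over a recording session,
*changes* in how connection clusters group together over time reflect
genuine reorganisation of the underlying activity, even when individual
links cannot be trusted.  The motivating application is prolonged-task
vigilance: as fatigue accumulates during an hour of monotonous driving,
strong alpha-band (8–13 Hz) coupling drifts from frontal to
parieto-occipital sites, and an auditory countermeasure (listening to the
radio) is expected to hold the most active clusters frontally.

## Pipeline

`run_pipeline()` chains five stages, each exposed as ordinary functions:

1. **Band extraction** (`extract_alpha`).  Each channel is decomposed with a
   9-level orthonormal Daubechies DWT; the detail level whose dyadic band
   $[f_s/2^{L+1},\, f_s/2^L]$ contains 10 Hz is kept and the channel is
   reconstructed from those coefficients alone.  At the standard 500 Hz
   sampling rate this is level 5, spanning 7.8125–15.625 Hz.
2. **Segmentation** (`segment_recording`).  The recording is cut into
   contiguous equal stages (10 min in a full-length session); a trailing
   remainder is discarded.
3. **Connectivity** (`build_connectivity`).  Every channel pair is scored by
   the absolute normalised zero-lag cross-correlation
   $$\gamma_{ij} = \frac{\left|\sum_t s_i(t)\, s_j(t)\right|}
     {\sqrt{\sum_t s_i(t)^2 \sum_t s_j(t)^2}} \in [0, 1],$$
   computed literally without mean-centering (band-limited signals are near
   zero-mean, so this tracks the Pearson correlation magnitude closely; a
   centered variant is available).  The diagonal is zeroed.  The sum of
   squared entries is the **global connectivity energy**, an overall
   coupling summary.
4. **Connection-cluster classification** (`agglomerate`, `cut_dendrogram`,
   `assign_classes`).  Node $i$ becomes the vector of its $M = N - 1$
   connection strengths.  Agglomerative clustering under Euclidean distance
   merges the closest clusters until one remains; cutting the dendrogram at
   $Z = 4$ leaves four groups, and each group is ranked by the merge step at
   which it is first absorbed: the group that stays distinct longest is
   Class 4, the most "different"/active one.  Class trajectories across
   stages (`class_trajectory`) are the framework's main read-out.
5. **Entropy and statistics** (`differential_entropy`, `regional_de`,
   `rank_sum_test`, `group_summary`).  Differential entropy
   $-\int p(x) \log p(x)\,dx$ of the alpha-band signal quantifies regional
   information content; regional means over the frontal
   (Fp1, Fp2, F7, F3, Fz, F4, F8) and parieto-occipital
   (T5, P3, Pz, P4, T6, O1, O2) channel groups are compared between cohorts
   with the Wilcoxon rank-sum test at $\alpha = 0.05$.

A Louvain community-detection comparator (`louvain_communities`) is
included because modularity-based partitions are the standard alternative
view of the same matrices; on mixing-contaminated networks its communities
are typically static across stages, which is exactly the contrast the
cluster-classification method is designed to overcome.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `levels` | 9 | DWT depth; must reach the dyadic band containing 10 Hz |
| `wavelet` | `"db8"` | analysis basis (see below) |
| `denoise` | `"none"` | universal soft thresholding, optional |
| `segment_seconds` | 600 full-length, 60 in the synthetic presets | stage duration |
| `Z` | 4 | number of merge-order classes |
| `linkage` | `"single"` | inter-cluster distance (complete/average available) |
| `de_estimator` | `"gaussian"` | closed form $\tfrac12\ln(2\pi e \hat\sigma^2)$; histogram (Freedman–Diaconis) as a non-Gaussianity check |
| `de_base` | $e$ | entropies in nats |

**Wavelet basis.**  The method is defined on dyadic wavelet bands, not on an
ideal band-pass filter, so the basis determines how much of a pure in-band
tone actually lands in the selected level.  Measured on a 10 Hz tone at
500 Hz, the level-5 coefficient energy fraction is 0.68 (db2), 0.84 (db4)
and 0.95 (db8).  db8 is therefore the default: it is the shortest standard
Daubechies filter whose dyadic split keeps >90 % of mid-alpha energy in the
alpha level, and it remains a routine choice for EEG decomposition.  The
softer bases stay available for sensitivity analyses.

**Boundary handling.**  The DWT is periodised (circular), with internal
zero-padding to a multiple of $2^{\text{levels}}$.  This keeps the
transform strictly orthonormal: reconstruction from the full pyramid is
exact to machine precision and total coefficient energy equals signal
energy, which makes the alpha energy ratio (level energy over total
energy) a true fraction of signal energy.  Redundant boundary-extension
schemes would break that identity.  The cost is a possible edge artefact
within one filter support of the signal ends, negligible at the segment
lengths used here.

**Linkage.**  The merge rule is stated as an arg-min over cluster-pair
distances reduced to a distance between two node vectors, which single
linkage expresses most literally; it is the default, with complete and
average selectable.  The printed distance formula omits the square root of
the Euclidean norm; the package uses the true Euclidean distance — a
monotone transform that leaves merge order, cuts and classes unchanged
under single or complete linkage.

## Determinism and tie rules

* **Merge ties**: among equal-distance cluster pairs, the lexicographically
  smallest (id, id) pair merges first (leaf ids 1..N in canonical montage
  order, merged ids N+1..2N−1).
* **Class ties**: the first merge above the cut always absorbs two cut
  clusters at the same step; the one containing the lower canonical node
  index takes the lower class.
* **Louvain order**: the local-move sweep follows the canonical node order
  shuffled by the user's seed; the algorithm is order-dependent by nature,
  and fixing the shuffle makes runs reproducible while leaving that
  sensitivity visible.

One subtlety of the $M = N-1$ node-vector encoding deserves a note: because
each vector omits the self-entry, the Euclidean distance between nodes $i$
and $j$ pairs some components that refer to different partner nodes, and
the pairing depends on the canonical node order.  Distances — and in edge
cases the cut partition — are therefore not exactly invariant under
reordering the montage.  This is inherent to the encoding, dominated in
practice by the aligned components; the package fixes the canonical order
(Fp1 … O2) so results are fully reproducible.

## Rank-sum test

$U$ is computed from summed midranks.  For $n_1 + n_2 \le 16$ the two-sided
p-value is exact: every $\binom{n_1+n_2}{n_1}$ assignment of the pooled
midranks is enumerated and the smaller tail doubled (capped at 1).  The
large-sample mode uses a continuity-corrected normal approximation whose
mean, variance, skewness and kurtosis are the *exact* permutation-null
moments of the midrank sum (computed from population power sums, so tie
corrections are exact by construction), sharpened with the Edgeworth
skewness/kurtosis terms.  On tie-free samples at $n_1 = n_2 = 8$ this stays
within about $5\times10^{-4}$ of the exact p, versus about 0.011 for the
plain corrected normal.  The reported `z_stat` remains the familiar
continuity-corrected normal deviate.  With heavy ties at very small $n$ the
approximation degrades; `auto` mode sidesteps this by using enumeration
whenever it is feasible.

## The synthetic cohorts

The study's recordings are not publicly deposited, so the package carries a
generator (`scenario_config`, `simulate_recording`) whose presets define
the two study arms: 14 subjects each, 19 channels, 500 Hz, six stages.

Each scalp region (frontal, parieto-occipital, auditory T3/T4) is driven by
a sinusoidal alpha source with per-subject frequency jitter
(10 ± 0.4 Hz), slow sinusoidal amplitude modulation, and a per-stage
amplitude from the preset's gain schedule.  Two phase-offset sub-sources
per region (zero-lag correlation ≈ 0.95 frontal, 0.7 parieto-occipital)
grade the within-region coherence; small fixed frequency offsets keep
different regions near-orthogonal over a stage.  Independent white noise
(SD 10 µV) is added per channel, and all channels are mixed by a fixed
Gaussian distance-decay leakage matrix over the 2-D 10–20 layout —
time-invariant by construction, which is the mixing assumption the whole
method rests on.

The preset gain schedules are the scenario definition: the control arm's
frontal amplitude falls (30 → 0.5 µV) while the parieto-occipital amplitude
rises (2 → 30 µV), so the ground-truth "most active" region drifts
posteriorly; the radio arm keeps the frontal amplitude high in every stage,
boosts the auditory channels in stage 1 (35 µV), and doubles the overall
amplitude scale, so its regional differential entropy sits about
$\ln 2$ nats above the control arm while correlations are unaffected.  The
late-stage control frontal gains are set low enough that the fading region
melts into the noise background instead of persisting as a middling
cluster — mirroring the intended phenomenology that high classes *vanish*
frontally under fatigue.

The leakage spread (0.15 distance units) is deliberately weak.  At
realistic volume-conduction strength, neighbouring electrodes share enough
mixed noise that the class topography becomes geometry-driven; keeping the
kernel narrow makes the source topography the dominant structure, which is
what the end-to-end recovery tests are meant to probe.  Consequences: the
generator demonstrates the method's behaviour under mild mixing, and says
nothing about performance under severe mixing, non-sinusoidal alpha,
artifacts (blinks, EMG), or non-stationary leakage — none of which it
emulates.  Passing tests on these cohorts show ground-truth recovery under
the generator's assumptions, not clinical validity.

Test and acceptance runs use 60-second stages (the full-length 600 s is a
config away); at 19 channels this keeps a 28-subject end-to-end run to a
couple of minutes while leaving every stage long enough (30 000 samples)
for stable correlation and entropy estimates.

## Degenerate inputs and numerical choices

* Zero-energy signals: `zero_lag_correlation` refuses them (undefined);
  `alpha_ratio` reports 0 with a warning to keep batch pipelines total.
* Gaussian DE requires nonzero variance; the histogram estimator requires
  at least two distinct values.
* An all-zero connectivity matrix yields a single Louvain community with
  $Q = 0$.
* Singleton cells in `group_summary` report SD 0 with a warning.
* EDF storage quantises to 16 bits over the per-channel range; tables are
  full-precision text.  Non-integer sampling rates cannot be stored as EDF
  (one-second records).
* Recordings whose rate puts no dyadic level on 10 Hz (below 20 Hz
  sampling) are rejected rather than approximated.

## Known limitations

* The cross-correlation estimator is deliberately mixing-prone; no leakage
  correction, phase-based or coherence estimator is provided — the point of
  the method is to work despite mixing, and the comparison is part of its
  rationale.
* No multiple-testing correction is applied to the rank-sum tables (the
  reference analysis applies none); a Bonferroni pass is a one-liner on the
  output table if wanted.
* The DE log base and amplitude scale conventions make absolute entropy
  values comparable only within a fixed pipeline configuration.
* Merge-order classes are only defined relative to a cut; with $Z$ near $N$
  the ranking degenerates to the merge order itself.
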