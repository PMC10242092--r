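---
title: "Shape-based classification of respiratory airflow cycles"
author: "respclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-based classification of respiratory airflow cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respclust)
```

## The problem

Plethysmography of small rodents produces a nasal airflow trace (mL/s,
positive during inspiration) sampled at a few hundred hertz. Classical
descriptors — inspiratory/expiratory time, inhaled/exhaled volume,
frequency — summarize each respiratory cycle by a handful of numbers and
discard the *shape* of the flow, which carries information about motor
control of inspiration, post-inspiratory pauses, and other physiologically
meaningful behaviors. `respclust` classifies cycles directly by shape,
without supervision:

1. **Segmentation.** The lung volume is reconstructed by integrating the
   airflow and removing the linear trend that integration of any offset
   produces. Volume minima mark inspiration starts, the maximum between two
   consecutive minima marks the expiration start. Inspirations and
   expirations are analyzed independently from here on.
2. **Reference learning.** The variable-length inspiration (and,
   separately, expiration) sequences are z-normalized and clustered by
   K-means under the dynamic time warping (DTW) measure, with K-means++
   seeding and cluster centroids computed by batch stochastic DTW
   barycenter averaging (BS-DBA). The resulting centroids are the
   *reference shapes*.
3. **Symbolization.** Every cycle of a recording is assigned the nearest
   reference by 1-NN DTW; each cycle becomes a two-character symbol (an
   inspiration letter plus an expiration digit). A per-reference distance
   threshold — a quantile of the within-cluster training distances — gates
   atypical cycles out as outliers instead of forcing a label.

Downstream, symbolized recordings are summarized as referent-cycle (RC)
time-distribution maps, marginal polar profiles and bar-code timelines, and
groups of subjects are compared cell-by-cell with Mann-Whitney U tests
under Benjamini-Hochberg false discovery rate control.

## The model components

### Volume reconstruction and boundary detection

For airflow samples $s_1,\dots,s_n$ at rate $f_s$, the volume is
$v_t = \tfrac1{f_s}\sum_{u\le t} s_u - (\hat a t + \hat b)$ with
$\hat a,\hat b$ the ordinary least-squares line through the cumulative sum,
so that $\sum_t v_t = 0$ and $\sum_t t\,v_t = 0$ exactly. The $1/f_s$
factor keeps $v$ in mL, which is what the prominence parameter (in mL)
applies to.

Inspiration starts are prominence-filtered local minima of $v$: the
prominence of a minimum is evaluated within a sliding window (default 2 s)
as the smaller of the two "bases" reached before a lower sample appears on
either side; minima with prominence below 0.03 mL are noise and are
dropped. Because $v_t$ includes the flow at $t$, the volume extremum falls
on the *last* sample of the preceding phase; boundaries are therefore
placed one sample after the extremum, which makes boundary recovery on
noise-free synthetic data exact for interior cycles. Plateau extrema keep
their earliest sample, making segmentation deterministic. Cycles whose
inspiration or expiration falls outside [0.05 s, 2 s] are discarded whole
— merging them with neighbors would fabricate shapes — and their spans are
remembered so that symbolization can emit them as unclassified time.

### DTW with a Sakoe-Chiba corridor

The DTW measure between sequences $x \in \mathbb R^m$, $y \in \mathbb R^n$
is the minimum over monotone alignment paths of the summed squared gaps,
with no path-length normalization. Alignments are restricted to a
Sakoe-Chiba corridor specified by a *temporal* radius (default 0.01 s).
Numerical conventions, fixed for cross-platform determinism:

* radius in samples is `max(1, round-half-up(radius * fs))` — at 250 Hz,
  0.01 s gives 3 samples (2.5 rounds up);
* for unequal lengths the corridor follows the corner-to-corner resampled
  diagonal and is widened by the minimal amount that keeps it connected
  under the three admissible steps, so the end cells are always reachable;
* tie-breaks during path backtracking prefer the diagonal step.

### BS-DBA averaging

The centroid of a cluster is a fixed-length sequence minimizing the sum of
DTW costs to the members. `bsDba()` performs mini-batch stochastic
subgradient descent on that objective: each epoch shuffles the members
(seeded), and for each batch every barycenter sample is pulled toward the
member samples its alignment path matches it to, with step size
$\eta_t = \eta_0/(1+t)$ over batch updates and $\eta_0 = 1/(2\,\text{batch
size})$. Standalone averaging initializes at the medoid; inside K-means
the update is warm-started from the current centroid, which is cheaper and
empirically equivalent after a few iterations. The objective is evaluated
once per epoch and the best iterate seen — including the initialization —
is returned, so the reported objective trace is non-increasing by
construction. A singleton set returns its (resampled) member unchanged.
The reference length is 0.2 s (50 samples at 250 Hz) rather than the mean
member duration; the mean-duration rule remains available by passing
`lSamples = NULL`.

### Clustering conventions

* z-normalization uses the population (1/n) standard deviation; constant
  sequences carry no shape, are excluded from training, and symbolize as
  outliers.
* K-means++ seeding weights candidates by the DTW measure to the nearest
  chosen center (the measure is already a squared-error quantity).
* The iteration budget is fixed (default 10) with no convergence test; a
  final assignment pass fixes the reported memberships, within-cluster
  distances, and the inertia bookkeeping used to assert that reassignment
  never increases the total inertia.
* Empty clusters are reseeded with the sequence farthest from its
  centroid.
* Clusters are ordered by increasing mean *member* duration (seconds of
  the source phase sequences, not barycenter support) and labelled
  `A, B, ...` (inspiration) or `0, 1, ...` (expiration), so later labels
  always mean longer phases.

### Outlier gating and statistics

Per-reference thresholds are empirical quantiles (linear interpolation
between order statistics, the R type-7 estimator) of the within-cluster
training distances at level `alpha` (default 0.95). Sequences are
z-normalized at symbolization time exactly as at training time. A cycle is
an outlier when either of its phases is; RC maps count only fully
classified cycles, with outlier time reported separately.

RC distributions are *time* distributions — each cell holds the percent of
classified time, not the cycle count — and group comparisons test these
per-subject percentages, keeping the tested quantity identical to the
displayed one. The Mann-Whitney U test uses the exact null distribution
when both groups have fewer than 8 subjects and no ties occur, and the
tie-corrected normal approximation with continuity correction otherwise;
cells constant across all subjects of both groups get $p = 1$ rather than
being dropped, preserving the map shape. Benjamini-Hochberg correction is
applied across all $K_1 K_2$ cells. For pre/post designs a paired Wilcoxon
signed-rank variant is available (`paired = TRUE`) but the unpaired test
is the default.

## The synthetic generator

Real recordings of this kind are not redistributable, so validation rests
on `generateRecording()`/`generateCohort()`, which emulate the features the
method depends on: quasi-periodic ~0.3 s cycles built from archetypes —
sinusoidal, biphasic (air entering in two phases) and delayed (pause
before inflow) inspirations; sinusoidal and post-inspiratory-pause
expirations of graded pause length — with per-cycle uniform duration
warping, additive white noise at a configurable SNR, and an optional slow
(0.05 Hz) sinusoidal baseline drift. Default amplitude is 1.5 mL/s peak
inspiratory flow with 0.15 s phases, i.e. a tidal volume of ~0.14 mL,
typical murine values. Every cycle is rendered with exactly balanced
inspired and expired volume, so the noise-free volume trace returns to
baseline at each boundary and ground-truth boundaries are well defined.

Two deliberate realism choices matter for interpretation:

* Pauses carry a small residual flow (6% of peak) rather than exactly zero
  flow. With a perfectly flat pause the volume is constant there and the
  position of its extremum under noise is arbitrary, which would make the
  "true" boundary ill-defined; a residual flow pins it, as in real animals
  where flow never vanishes exactly.
* Baseline drift interacts with pauses: drift flow comparable to the
  residual pause flow can move boundary extrema into a pause and clip it.
  This is a property of the volume-based segmentation itself, not of the
  generator; the parameter-recovery simulations therefore use noise and
  warping but no drift, while drift is exercised where only the detrending
  and counting behavior is asserted.

What passing these tests does **not** show: performance on real data with
sniffing, movement artifacts, apneas, sensor drift beyond a slow sinusoid,
or class structure that is not a clean mixture of a few archetypes. The
generator validates the machinery, not the biology.

## Validation scales and expected behavior

The shipped tests and `scripts/acceptance.R` run, on one CPU in a few
minutes: the 32-recording x 1,800-cycle training-set bookkeeping (57,600
cycles); DTW equivalence with an independent brute-force dynamic program
on 200 random variable-length pairs, on all pairs of alphabet sequences up
to length 4, and on 500 random alphabet pairs of lengths 5-8 (the full
exhaustive set to length 8 would be ~5x10^7 pairs and adds nothing);
detrending moments below 1e-6 relative; exact noise-free boundary recovery
(≤ 1 sample) and cycle counts off by at most one at 20 dB SNR; BS-DBA
fixed-point, objective-improvement and template-recovery checks over 20
seeded runs; K-means recovery of three inspiration archetypes with median
adjusted Rand index ≥ 0.9 over 10 seeds (n = 100 per class, ±20% warp,
20 dB SNR); outlier-gating counts at `alpha` 1.0 and 0.95; Mann-Whitney
size (≤ 7% any-rejection over 1,000 null replicates of 8 vs 8 subjects)
and power (a 30-point single-cell shift detected with off-cell rejections
at the FDR level); and an end-to-end fit + symbolize accuracy ≥ 90%
(median over 5 cohorts).

Symbol accuracy is computed among *classified* cycles, with the outlier
fraction reported alongside. This is the operationally meaningful
definition: the gate is designed to abstain on atypical cycles, and at
`alpha = 0.95` per phase roughly 5% of training-distribution phases —
hence up to ~10% of cycles — are expected abstentions by construction, not
mistakes.

## Known limitations

* The number of references per phase is user-chosen (default 5); no
  automatic selection heuristic is included.
* K-means with a fixed iteration budget converges to a local optimum that
  depends on the seed; fits are bit-reproducible given (data order, seed,
  configuration), and permuting the input only changes results through the
  seeded shuffle.
* Slow baseline drift is removed only in its linear component; strong
  nonlinear drift can shift boundaries near long pauses (see above).
* The recording container reads and writes a plain CSV dialect
  (`#`-prefixed key=value headers plus `time,flow` columns); proprietary
  acquisition formats must be converted upstream.
* Distances are unitless after z-normalization; thresholds learned on one
  experiment do not transfer to another without refitting.

## A minimal session

```{r example, eval = FALSE}
arch <- defaultArchetypes()
mix <- c(sine = 0.3, biphasic = 0.2, delayed = 0.15,
         pause_short = 0.2, pause_long = 0.15)
cohort <- generateCohort(4, "WT", list(WT = mix), arch,
                         cyclesPerRecording = 150, snrDb = 20,
                         warpPct = 0.2, seed = 1)
train <- subsampleTraining(cohort, 100)
mi <- fitThresholds(fitKmeans(train$inspiration, K = 3, seed = 1))
me <- fitThresholds(fitKmeans(train$expiration, K = 3, seed = 2))
sym <- symbolize(cohort[[1]]$recording, mi, me)
rcDistribution(sym)
barcode(sym)
```
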