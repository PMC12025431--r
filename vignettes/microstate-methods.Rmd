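---
title: "Microstate methods: models, conventions, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate methods: models, conventions, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstatr)
```

This vignette documents the mathematical model behind each stage of the
package, the numerical conventions that make results reproducible, and
the known limitations — particularly of the synthetic generator and the
duration estimates.

## The microstate model

A multichannel EEG sample is a voltage map $x_t \in \mathbb{R}^C$ over
$C$ channels. The microstate model asserts that, after removing each
map's spatial mean, the observed maps are noisy scaled copies of a small
number $K$ of template topographies $T_1, \dots, T_K$ (zero-mean, unit
norm), with the active template switching every 60–120 ms:

$$x_t = a_t \, T_{L(t)} + \varepsilon_t,$$

where $L(t)$ is the label sequence, $a_t$ a signed amplitude, and
$\varepsilon_t$ sensor noise. Two conventions follow from the physics:

* **Polarity invariance.** Oscillatory generators flip the sign of the
  map within a microstate, so $T$ and $-T$ denote the same state. All
  fitting criteria use squared or absolute correlations.
* **Average reference.** Spatial means carry no topographic information;
  every map is spatially centered before comparison.

## Global field power and peak selection

The GFP at sample $t$ is the spatial (population) standard deviation of
$x_t$. Topography is most reliable at GFP maxima, so clustering operates
on GFP-peak maps only. `select_gfp_peaks()` applies, in order:

1. strict local maxima (the first sample of a flat plateau counts);
2. outlier exclusion — peaks beyond `outlier_sd` standard deviations of
   the GFP distribution (two-sided by default) are dropped, because very
   large GFP values typically mark artifacts;
3. a minimum spacing (10 ms by default), enforced greedily from the
   highest peak downward.

Outliers are removed *before* spacing is enforced, so an excluded
artifact peak cannot shadow a valid neighbor.

## Modified k-means

`modified_kmeans()` alternates:

* **Assignment:** each centered map joins the template maximizing the
  squared inner product $(T_k^\top x_t)^2$ — for unit templates this is
  the polarity-invariant analogue of nearest-centroid assignment, and is
  equivalent to maximizing $|r|$, the absolute spatial correlation.
* **Update:** each template becomes the dominant eigenvector of the
  scatter matrix $\sum_{t \in k} x_t x_t^\top$ of its assigned maps,
  which maximizes the summed squared projections regardless of the
  maps' signs. The result is re-centered and normalized.

Fit quality is the global explained variance

$$\mathrm{GEV} = \frac{\sum_t (\mathrm{GFP}_t \, r_t)^2}
                      {\sum_t \mathrm{GFP}_t^2},$$

and the number of classes can be chosen by the cross-validation
criterion $\hat\sigma^2 \left( \frac{C-1}{C-1-K} \right)^2$ (lower is
better), where $\hat\sigma^2$ is the mean residual variance per degree
of freedom. The criterion is undefined when $C \le K + 1$.

### Numerical conventions

* **Template sign.** After every update, a template's largest-magnitude
  component is made positive. Combined with squared-projection
  assignment, this makes clustering *bitwise* invariant under sign flips
  of any subset of input maps — not merely invariant up to sign.
* **Ties.** Assignment ties go to the lowest class index. In `select_k()`,
  criterion values tied within a small data-scaled tolerance
  ($10^{-8} \times$ mean map variance) resolve to the smallest $K$: on
  noise-free data the criterion is numerically zero for every $K$ at or
  above the generative one, and the tolerance keeps the parsimonious
  model rather than letting $10^{-30}$-scale floating-point noise decide.
* **Empty clusters** are re-seeded with the observation worst fit by the
  current templates.
* **Restarts and seeds.** Each restart initializes from $K$ distinct
  observed maps; the restart with the highest GEV wins. All randomness
  flows through a single integer seed; derived seeds (per restart block,
  per candidate $K$, per pipeline stage) are fixed offsets of it.
* **Degenerate input.** Clustering refuses inputs in which all
  observations share a single topography (up to sign and scale); there
  is nothing to cluster.

## Back-fitting and temporal smoothing

`backfit()` labels every continuous sample by the template with the
highest $|r|$. Spatially constant samples have no defined correlation
and inherit the previous sample's label.

Raw back-fitted sequences fragment heavily wherever the instantaneous
amplitude is low, so segments shorter than a threshold (30 ms by
convention) are merged by `smooth_segments()`. The implementation
deviates deliberately from the naive rule of reassigning each frame of a
short segment independently to whichever neighbor template it resembles
more: independent per-frame choices can interleave the two neighbor
classes, creating new one-sample runs, and give no guarantee of
termination or of the postcondition that no short interior segment
remains. Instead, each offending segment (shortest first; segments
touching the record boundary are exempt) is split at the point $s$
minimizing the total global map dissimilarity

$$\sum_{t \le s} \mathrm{GMD}(x_t, T_\text{left}) +
  \sum_{t > s} \mathrm{GMD}(x_t, T_\text{right}),$$

with the left part joining the left neighbor's class and the right part
the right neighbor's. Each frame still goes to the neighbor its map
resembles more, but monotonically, so runs only grow or merge, the
procedure terminates, and afterwards no interior segment is shorter than
the threshold. GMD between normalized maps is
$\sqrt{2\,(1 - |r|)}$.

## Microstate parameters

From a labeled sequence, per class: mean dwell **duration** (ms),
**coverage** (fraction of samples), and **occurrence** (runs per
second). These obey the identity
$\text{coverage} = \text{duration} \times \text{occurrence} / 1000$
exactly when boundary runs are included (the default). **Transition
probabilities** count adjacent run pairs and normalize each source row
over its outgoing transitions; the diagonal is structurally zero.
Pre/post comparisons use the change rate
$(\text{post} - \text{pre})/\text{pre}$.

## Statistics

The statistical layer wraps the classical tests of a pre/post
three-group design: paired and pooled two-sample $t$ with Cohen's $d$,
Pearson chi-squared without continuity correction, one-way ANOVA, a
split-plot mixed ANOVA (between factor: group; within factor: class;
participant as the error stratum, with optional Greenhouse–Geisser
correction), a rank-based Dunn post hoc $z$ with tie-corrected variance
and Bonferroni adjustment, ordinary least squares for change-rate
regressions, and a topographic permutation test (TANOVA): the observed
statistic is the GMD between the two groups' GFP-normalized mean maps,
the null distribution reassigns participants to groups preserving group
sizes, and $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_\text{perm})$,
so $p$ is never exactly zero.

For the mixed design, standard split-plot degrees of freedom are used:
a $3 \times 4$ group-by-class interaction has $F(6,\; 3(n-1)\cdot 3)$,
not $F(3, \cdot)$ as occasionally printed in applied reports.

## The synthetic generator

`synthetic_spec()` / `simulate_recording()` implement a semi-Markov
generative model chosen to match the empirical dwell regime:

* the label process draws each visit's dwell from a gamma distribution
  (shape 4 by default) with a class-specific mean in the 60–100 ms
  range, then jumps according to a zero-diagonal transition matrix — a
  per-sample Markov chain would give geometric dwells far shorter than
  observed;
* the voltage is the active class's template scaled by a 10 Hz
  alpha-like rectified-sine envelope, with an independent random
  polarity sign and envelope phase per segment (deliberately exercising
  polarity invariance downstream), plus i.i.d. Gaussian sensor noise;
* canonical templates A–D are smooth functions of the electrode
  coordinates with all pairwise $|r| < 0.6$, mimicking the partial
  correlation of real microstate maps. An orthogonalized variant exists
  for identifiability checks; note the canonical A, B, C maps are
  linearly dependent by construction, so orthogonalization substitutes
  higher-order polynomial directions where needed.

`generate_study()` extends this to a three-group pre/post design with
per-participant dwell jitter and a behavioral model in which the
three-back reaction-time change rate is a known linear function of the
true Class C coverage change rate — making the regression stage testable
against a known slope.

### Scope and limitations

* The generator produces *topographic switching* data, not biophysical
  EEG: no 1/f spectrum, no spatially correlated noise, no artifacts.
  It validates the segmentation and statistics machinery, not
  preprocessing robustness against real-world noise.
* With the default amplitude (10) and noise (SD 2 per channel) across 64
  channels, the per-channel signal is comparable to the noise, so GEV
  values on synthetic data are much lower than the 0.7-range values
  typical of cleaned resting-state EEG — while label recovery remains
  accurate, which is the property that matters for parameter estimation.
* **Duration bias.** Under gamma(shape 4) dwells with means of 70–85 ms,
  roughly 6–10% of true dwells are shorter than 30 ms. The 30 ms
  smoothing merges them, inflating estimated mean durations by about
  +10% — a floor that applies even to the smoothed *true* label
  sequence, independent of noise. Coverage, occurrence ratios, and
  transition probabilities are essentially unaffected. Comparisons of
  durations across conditions analyzed with the same threshold remain
  valid; absolute durations carry the bias of their threshold.

## Reproducibility

Every stochastic routine accepts an integer seed and restores the RNG
state afterwards (`withr::with_seed`), so calls do not perturb the
caller's random stream. The test suite exercises each stage against
independent oracles: direct-arithmetic re-referencing, FFT gain checks
for the filters, per-column standard deviations for GFP, exhaustive
small-instance searches for the clustering optimum, hand-computed
split-plot sums of squares for the mixed ANOVA, and the coverage
identity across thousands of random sequences.
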