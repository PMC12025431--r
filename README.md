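# microstatr

Resting-state EEG microstate analysis in R: preprocessing, global field
power (GFP) peak extraction, polarity-invariant modified k-means
clustering, template back-fitting with temporal smoothing, microstate
parameters, and the statistical layer used in pre/post stimulation
designs — plus a semi-Markov synthetic EEG generator with matched ground
truth so every stage can be validated without recorded data.

## Background

EEG microstates are brief (~60–120 ms) periods during which the scalp
voltage topography stays quasi-stable before switching abruptly to a
different configuration. Resting-state recordings are dominated by a
small number of template topographies (canonically labeled A–D), and the
temporal statistics of their alternation — mean duration, fraction of
time covered, occurrences per second, and segment-to-segment transition
probabilities — are sensitive markers of cognitive state and of
interventions such as transcranial alternating current stimulation.

The analysis chain implemented here follows the standard topographic
segmentation approach:

1. **Preprocess**: re-reference (e.g. to linked mastoids), zero-phase
   4th-order Butterworth band-pass (1–40 Hz), anti-aliased downsampling
   (e.g. 1000 → 500 Hz).
2. **GFP peaks**: the GFP is the spatial standard deviation of the map at
   each sample; local maxima mark high signal-to-noise topographies.
   Peaks closer together than a minimum interval (10 ms) and outlier
   peaks (beyond 2 SD) are discarded.
3. **Cluster**: modified k-means on the peak maps, where a map and its
   negation are equivalent (assignment by squared normalized inner
   product; template update by the dominant eigenvector of the assigned
   maps' scatter matrix). Fit quality is summarized by the global
   explained variance (GEV); the number of templates can be chosen with a
   penalized cross-validation criterion.
4. **Back-fit and smooth**: every continuous sample is assigned to the
   template with the highest absolute spatial correlation, and segments
   shorter than 30 ms are merged into their neighbors by global map
   dissimilarity.
5. **Parameters and statistics**: duration, coverage, occurrence
   (linked by `coverage = duration × occurrence`), transition
   probabilities, paired pre/post tests with Bonferroni correction,
   mixed-design ANOVA with Dunn's post hoc, topographic permutation
   tests (TANOVA), and regressions relating microstate change rates to
   behavioral change rates.

## Worked example

Simulate a two-minute, 64-channel recording whose ground truth is known,
then run the full single-recording chain:

```r
library(microstatr)

spec <- synthetic_spec(seed = 42)     # 64 ch, 500 Hz, 120 s, K = 4
synth <- simulate_recording(spec)
synth$recording
#> <eeg_recording> 64 channels x 60000 samples @ 500 Hz (120.0 s)
#>   reference: synthetic average-free
#>   channels: FP1 FPZ FP2 AF7 AF3 AF4 AF8 F7 ...

gfp <- compute_gfp(synth$recording)
peaks <- select_gfp_peaks(gfp, min_interval = 10, outlier_sd = 2)
peaks
#> <gfp_peaks> 8374 peaks @ 500 Hz

obs <- t(synth$recording$data[, peaks$indices])
colnames(obs) <- synth$recording$channels
fit <- modified_kmeans(obs, k = 4, n_restarts = 20, seed = 1)
fit$templates
#> <ms_templates> k = 4 classes (A, B, C, D), 64 channels, GEV = 0.200, CV = 5.184

tmpl <- align_labels(fit$templates, synth$templates)
lab <- smooth_segments(backfit(synth$recording, tmpl),
                       synth$recording, tmpl, min_duration = 30)
params <- compute_params(lab)
params
#> <ms_params> 4 classes over 120.0 s
#> # A tibble: 4 × 5
#>   class class_name duration coverage occurrence
#>   <int> <chr>         <dbl>    <dbl>      <dbl>
#> 1     1 A              77.5    0.226       2.91
#> 2     2 B              81.6    0.227       2.78
#> 3     3 C              92.6    0.276       2.98
#> 4     4 D              91.4    0.271       2.97

round(params$transition, 3)
#>       A     B     C     D
#> A 0.000 0.301 0.372 0.327
#> B 0.317 0.000 0.347 0.335
#> C 0.325 0.311 0.000 0.364
#> D 0.354 0.331 0.315 0.000

mean(lab$labels == synth$labels$labels)   # agreement with ground truth
#> [1] 0.9530667
```

Even at a realistic noise level (per-channel noise comparable to the
per-channel signal, hence the modest GEV), the recovered label sequence
agrees with the generating one for ~95% of samples, and the recovered
durations sit a little above the generating means (70, 73, 85, 85 ms) —
see the note on smoothing bias below.

`tidy()`, `glance()`, and `autoplot()` methods are provided for the
template, parameter, GFP, and label objects.

## Study-level pipeline

`generate_study()` builds a three-group (sham / sine / triangular
stimulation) pre/post design in which the participants' three-back
reaction-time change rate is linearly coupled to their Class C coverage
change rate. The regression stage recovers that coupling:

```r
st <- generate_study(n_per_group = 12,
                     pre_spec = synthetic_spec(n_channels = 8, length_s = 30),
                     coupling_slope = 1, behavior_noise_sd = 0.03,
                     render = FALSE, seed = 7)
st
#> <ms_study> 72 recordings, groups: sham, sine, triangular
```

Regressing the reaction-time change rates on the true Class C coverage
change rates gives

```r
#> # A tibble: 1 × 5
#>   slope intercept r_squared        p     n
#>   <dbl>     <dbl>     <dbl>    <dbl> <int>
#> 1  1.02   0.00142     0.952 4.91e-24    36
```

For recorded data, `run_study()` takes a manifest tibble (`participant`,
`group`, `stage`, and file paths or in-memory recordings), runs
preprocessing, subject- and condition-level clustering, TANOVA,
back-fitting, parameter extraction and all group statistics, and returns
a single report object; `run_fixtures()` writes a complete synthetic
study to disk in the text matrix format that `read_recording()` also
reads (EDF and BrainVision files are supported too).

Classical statistics are exposed directly as well, e.g. a group-balance
check on a 3×2 gender count table:

```r
chi_squared_test(matrix(c(23, 17, 24, 15, 11, 14), nrow = 3))
#> # A tibble: 1 × 4
#>   statistic    df     p method
#>       <dbl> <int> <dbl> <chr>
#> 1    0.0666     2 0.967 Pearson chi-squared
```

## A note on smoothed durations

The 30 ms minimum-duration smoothing used in step 4 is standard, but it
has a measurable consequence: any true dwell shorter than 30 ms is
merged into its neighbors, so mean durations estimated from smoothed
label sequences are biased upward. For gamma-distributed dwells with
shape 4 and means of 70–85 ms, roughly 6–10% of dwells fall below 30 ms
and the inflation is about +10% — even when the smoothing is applied to
the *true* label sequence. Coverage, occurrence ratios, transition
probabilities, and group *contrasts* of durations are essentially
unaffected; absolute duration values should be compared only between
analyses using the same smoothing threshold.

## Vignette

`vignettes/microstate-methods.Rmd` documents the generative model, the
numerical conventions (polarity handling, tie-breaking, seed
derivation), the smoothing algorithm and its deviation from naive
per-frame reassignment, and the scope and limitations of the synthetic
generator.
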