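---
title: "Quantitative phenotyping of murine CAVD: models and methods"
author: "valvequant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative phenotyping of murine CAVD: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valvequant)
```

# Scope

Calcific aortic valve disease (CAVD) in mouse models is phenotyped along
four quantitative axes: transvalvular hemodynamics by pulsed-wave
Doppler, leaflet composition and thickness from Masson's trichrome
sections, cellular phenotype from DAPI/marker immunofluorescence, and
transcript abundance by RT-qPCR. `valvequant` implements each
quantification, the statistical decision tree that compares the
endpoints across groups, and a synthetic-data generator with known
ground truth so that every stage can be verified by parameter recovery.
The animals themselves are out of scope: the generators stand in for
them, and all empirical statements in this vignette are the ones the
package's test suite and `scripts/acceptance.R` actually compute.

# Doppler hemodynamics

## Model

A velocity trace is the envelope $v(t)$ of the aortic jet in mm/s, with
ECG R-peak times gating the trace into cardiac cycles. Cycles are
half-open intervals $[R_i, R_{i+1})$ so the partition is disjoint and
exhaustive over the R-peak span. Per cycle the package reports:

* **Peak systolic velocity** — the maximum of the envelope within the
  cycle.
* **Mean pressure gradient** — the time average of the simplified
  Bernoulli conversion $\Delta P = 4 v^2$ (with $v$ in m/s, giving
  mmHg) over the ejection window. Averaging is restricted to ejection
  so diastolic zeros do not dilute the mean.

Cycle metrics aggregate by unweighted two-stage averaging (cycles to
image, images to mouse; three images per mouse is the study
convention), and a mouse is classified as hemodynamically severe when
its peak velocity strictly exceeds 1320 mm/s, the 95th-percentile peak
velocity of an established hyperlipidemic CAVD model. A value exactly
at the threshold is not severe.

## Ejection window

The window is located as the longest contiguous run of samples above
10% of the cycle maximum and then, by default, widened outward to the
surrounding zero-velocity baseline. The widening matters: for a smooth
ejection pulse, averaging $4v^2$ over only the supra-threshold core
overstates the mean gradient by roughly a quarter, because the
low-velocity shoulders of ejection are excluded. With the baseline
extension the full pulse is averaged and, for the synthetic $\sin^2$
waveform, the closed form below is recovered to sample resolution.
`detect_ejection_window(..., extend_to_baseline = FALSE)` exposes the
bare thresholded run.

## Peak estimation under noise

The raw per-cycle maximum of a noisy envelope is biased upward by the
expected extreme of the noise — at an envelope noise SD of 5% of the
true peak, the bias of the raw maximum is several percent and does not
average away across cycles. `peak_systolic_velocity()` therefore
applies a 5-sample centered moving average before taking the maximum.
At the default 2 kHz sampling this flattens a noise-free peak by under
0.3% while reducing the noise-driven bias to about 1.5%, which is what
makes unbiased-within-3% recovery achievable. `smooth_window = 1`
restores the raw maximum.

## Synthetic traces

`simulate_doppler()` builds each cycle as
$v(t) = V_\text{peak}\sin^2(\pi t / T_\text{ej})$ over the ejection
window ($T_\text{ej}$ a fixed fraction of the cycle, default 0.35) and
zero in diastole, plus Gaussian noise truncated at zero. The $\sin^2$
shape is chosen because its mean gradient has a closed form: since the
mean of $\sin^4$ over a full arch is $3/8$, the time average of
$4 v^2$ over ejection is exactly $1.5\,V_\text{peak}^2$ (in mmHg with
$V_\text{peak}$ in m/s). This gives every downstream computation an
analytic oracle. R-peaks are emitted at all cycle boundaries
($n+1$ peaks for $n$ cycles) so gating recovers exactly the built
cycles. The default heart rate is 465 bpm, the typical rate of a
lightly anesthetised mouse.

```{r doppler-example}
tr <- simulate_doppler(1200, n_cycles = 10)
img <- summarize_image(analyze_trace(tr))
img
c(closed_form = 1.5 * 1.2^2, recovered = img$mean_gradient)
```

# Trichrome morphometrics

## HSL classification

Pixels inside a user-supplied leaflet ROI polygon are classified by
membership in named HSL windows: collagen (blue) at H 150–250°, and
cytoplasm/myocardium (red) at H 250–25° wrapping through 0°, both with
S 0.1–1.0 and L 0.1–0.93. All bounds are inclusive; the red window's
wrap is interpreted as $[250°, 360°) \cup [0°, 25°]$ because red hues
straddle 0°. ROI pixels matching no window are background (in practice
near-white, L > 0.93, or desaturated, S < 0.1 — the definition is "not
any stain class", since only non-background pixels are named by the
measurement). Window validation rejects pairs of windows overlapping
with positive measure; the two trichrome windows share the single hue
H = 250° and a pixel exactly there takes the first window in list
order. Area fractions are ratios of class pixels to non-background
pixels within the ROI, so the non-background fractions sum to one. A
pixel belongs to the ROI when its center lies inside the polygon
(even-odd rule); the boundary convention is therefore pixel-center
containment.

## Leaflet thickness

Mean thickness is total leaflet area divided by the length along the
cusp. Cusp length is measured on the medial-axis skeleton
(Zhang–Suen thinning) as the longest geodesic path through the
8-connected skeleton graph; the path length is taken as the Euclidean
length of the resampled path (every 4th vertex) rather than the sum of
raster steps, which would inflate oblique segments by up to 8%
(octile-distance error), and is extended at each end by the local
medial radius (the distance-transform value at the path endpoint) so
the measurement runs tip to tip. For a round blob whose skeleton
erodes away entirely the length degenerates to the inscribed diameter.
A user-supplied cusp polyline overrides the skeleton measurement, and
output is in pixels unless a physical pixel size is supplied. On a
200 × 20 px rectangle this yields 20.1 px, and rotating the rectangle
changes the estimate by well under 5%.

## Synthetic sections

`simulate_trichrome()` paints leaflet pixels with HSL values drawn
uniformly inside each class window shrunk by a per-channel jitter
margin (default 8° hue, 0.15 saturation/lightness). The margin exists
so that 8-bit RGB quantisation cannot move a painted pixel across a
window boundary: at low chroma a one-step RGB rounding error can shift
hue by several degrees, so the margin keeps sampled colors away from
both the window bounds and the low-chroma corners. Class pixel counts
follow the requested fractions exactly (largest-remainder rounding),
making classification recovery testable as exact label equality. The
default leaflet is an elongated ellipse with the aspect of a valve
cusp.

# Immunofluorescence quantification

## Nucleus segmentation

Three stages, in the order the assay describes them:

1. **Foreground** — two-cluster fuzzy c-means (fuzziness $m = 2$) on
   the ROI intensity histogram, deterministically initialised at the
   25th/75th intensity percentiles (tolerance $10^{-5}$ of the
   intensity range, at most 300 iterations). Pixels with bright-cluster
   membership above 0.5 — equivalently nearer the bright center — form
   the DAPI foreground. A constant ROI is a degenerate-clustering
   error.
2. **Watershed** — markers are regional maxima of the Euclidean
   distance transform after h-maxima suppression (h = 2 px); the
   watershed of the inverted distance transform, confined to the
   foreground, separates most touching nuclei. Objects under the
   minimum area (25 px at 20×) are removed. Both parameters are
   config-exposed since they depend on magnification.
3. **Concave-point splitting** — remaining clumps are detected by
   contour concavity: a contour point is concave when the interior
   angle measured over a 7-point contour window exceeds 210°. An
   object with at least two concave points is cut along the shortest
   chord joining two of them (pairs from the same notch are skipped,
   and the chord must stay inside the object) provided both parts meet
   the minimum area; chord pixels are reassigned to the nearest part so
   no area is lost. At most two passes are applied — no deeper
   recursion — and a convex object is returned unchanged, which makes
   the operation idempotent on the shapes it targets.

## Marker quantification

The positivity threshold is the median marker intensity over the
leaflet ROI, and positive pixels are strictly above it. Because the
median commutes with strictly increasing intensity maps, the positive
mask is exactly invariant under monotone rescaling — asserted
pixel-exact in the tests. Two read-outs share this threshold:

* **Area fraction** (αSMA, also reused for phospho-ERK1/2): positive
  pixels over all leaflet pixels.
* **Nuclear positivity** (Runx2): per-nucleus coverage is the fraction
  of the nucleus's pixels above threshold; a nucleus is positive when
  coverage strictly exceeds 0.5, so exactly half is negative. Positive
  counts are normalised to the total nucleus count.

One caveat follows from the median's definition: on an image whose
leaflet intensities are continuous (no ties), the positive fraction is
0.5 by construction. The area-fraction read-out is informative
because real marker images are tie-rich (quantised background); the
synthetic generator reproduces this in its high-SNR limit
(`psf_sigma = 0, noise_sd = 0`), where a planted 40% diffuse fraction
is recovered to three decimals, while under blur the boundary
transition pixels add a positive bias of roughly 0.05–0.1.

## Synthetic fields

`simulate_fluorescence()` places disc nuclei inside the leaflet by
rejection sampling; a requested number of touching pairs is built as
overlapping disc pairs (center distance 1.6 radii) whose union has
exactly two concave junction points — the geometry the splitting
stages target. The DAPI channel is the blurred disc indicator plus
truncated Gaussian noise in a 16-bit range. The marker channel plants
an exact per-nucleus coverage by marking pixels from one side of each
nucleus along a random direction, plus a diffuse extranuclear
component (a thresholded correlated random field) covering an exact
fraction of the leaflet. The baseline is structured: extranuclear
tissue carries more nonspecific autofluorescence (1200) than the
DNA-dense nucleus interior (400), which is what lets the leaflet
median separate true stain from unmarked nuclear pixels, as in real
sections where cytoplasmic background exceeds the dark nuclear
interior. What the generator does not emulate: non-disc nuclear
shapes, clumps of three or more nuclei, intensity gradients across the
field, and optical artifacts — recovery results therefore demonstrate
the pipeline's correctness on its stated geometry, not its performance
on arbitrary tissue.

```{r if-example}
sim <- simulate_fluorescence(n_nuclei = 40, n_touching_pairs = 4,
                             marker_coverage = rep(c(0.8, 0.2), 20),
                             dim = c(320, 320), seed = 1)
lab <- segment_nuclei(sim$dapi, sim$roi)
mq <- runx2_positivity(lab, sim$marker,
                       marker_threshold(sim$marker, sim$roi))
c(true_n = nrow(sim$truth), detected = max(lab),
  true_pos = mean(sim$truth$positive), est_pos = mq$positive_fraction)
```

# qPCR

Technical replicates are averaged per sample and target, then each
target's Cq is normalised by the geometric mean of the two
housekeeping genes of the same sample:
$\Delta C_t = C_{t,\text{target}} - \sqrt{C_{t,Gapdh} \cdot C_{t,Actb}}$.
The geometric mean is taken of the Cq values themselves, a literal
reading of the normalisation statement. Relative expression is
reported as $2^{-\Delta\Delta C_t}$ against a reference group
(amplification efficiency assumed 2; no standard-curve correction is
applied because none is available), but group statistics are always
computed on the untransformed $\Delta C_t$ values — `stats_input()`
enforces this hand-off. Undetermined (missing) wells are dropped with
a warning rather than imputed.

# The statistics engine

Every endpoint passes through the same decision tree:

* Normality is assessed per group by the D'Agostino–Pearson omnibus
  test ($K^2 = Z_\text{skew}^2 + Z_\text{kurt}^2 \sim \chi^2_2$). The
  implementation was verified against an independent reference
  implementation to 10 significant digits. The approximation is
  undefined below $n = 8$.
* A comparison is parametric only when every participating group has
  $n \ge 7$ **and** demonstrably normal data. Since normality cannot
  be demonstrated below $n = 8$, groups of exactly 7 are also routed
  non-parametric — the conservative resolution of the small-sample
  rule.
* Two groups: Student's t (equal variances) or Mann–Whitney U. Three
  or more: one-way ANOVA with Tukey post-hoc, or Kruskal–Wallis with
  Dunn's rank-based z post-hoc under a Bonferroni adjustment over all
  pairs. Paired change scores (the four-to-six-month drug-study
  design) test against zero with a one-sample t or Wilcoxon
  signed-rank.
* All tests are two-sided at $\alpha = 0.05$; a multi-group comparison
  is flagged significant when any adjusted pairwise p falls below
  $\alpha$. A parametric branch hitting zero variance falls back to
  its non-parametric counterpart with a warning.

Branch selection is a pure function of group sizes and normality
outcomes. Under null simulations (2000 replicates, groups of 10), the
empirical family-wise type-I error of every branch lies within 0.02 of
the nominal 0.05; the rank-based branches run slightly conservative
(about 0.035–0.04) due to test discreteness and the Bonferroni rule,
which is the expected behaviour of those procedures. Summary outputs
follow the mean ± SEM convention.

# Study orchestration

`run_study()` drives a complete synthetic study from one config (YAML
or list): per group it simulates mice with between-mouse variation in
true peak velocity, three Doppler clips per mouse, and optionally one
trichrome section, one fluorescence field, and a Cq table; it then
aggregates group summaries, classifies severity at 1320 mm/s, and runs
the decision tree on every endpoint. One root seed deterministically
derives all per-module and per-mouse seeds, so identical seeds produce
identical reports; every artifact is written as CSV/JSON.

Problem sizes used in the shipped checks were chosen to keep each
recovery statistically meaningful at desk scale: 100 cycles per
noise-free trace, 20 replicate clips for noisy recovery, 100 nuclei
with 10 touching pairs per field, 2000 replicates for test
calibration, and 50–100 replicate studies for the end-to-end power and
null-rate checks (planted 300 mm/s effect, n = 8 per group,
between-mouse SD 150 mm/s — a standardised effect of 2, detected in
over 95% of runs, with null runs flagged at about 5%).

# Known limitations

* Doppler envelopes are consumed, not extracted: spectrogram-to-envelope
  processing and vendor file formats are out of scope.
* The sin² ejection waveform is a convenience with an analytic oracle,
  not a hemodynamic simulation; recovery results say nothing about
  waveform-shape misspecification.
* The concave-split stage handles two-lobed clumps; chains of three or
  more touching nuclei may remain under-segmented (two passes, no
  recursion).
* The median-threshold read-outs inherit the median's blindness to
  global intensity shifts but also its 50% ceiling on continuous
  images; comparisons between groups imaged under identical settings
  are the intended use, as in the study design the package follows.
* Thickness assumes an elongated, largely unbranched leaflet profile;
  heavily branched skeletons would make "length along cusp" ambiguous,
  which is why a manual cusp polyline override is accepted.
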