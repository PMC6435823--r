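---
title: "Methods: single active-zone channel quantification and optical quantal analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single active-zone channel quantification and optical quantal analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azquant)
```

# The biological measurement this package models

At the *Drosophila* larval neuromuscular junction a motorneuron forms
hundreds of individual release sites (active zones, AZs). Each AZ carries
a cluster of CaV2-type Ca²⁺ channels (Cacophony) embedded in a Bruchpilot
scaffold, visible as one diffraction-limited fluorescent punctum per
channel when the protein is endogenously tagged. Three experimental
modalities are analyzed:

1. **Fixed/projected two-channel images** of channel and scaffold puncta,
   from which per-AZ channel abundance is quantified.
2. **Stimulus-locked movies** of a postsynaptically targeted Ca²⁺
   indicator, in which each vesicle-release event appears as a transient
   fluorescent flash; assigning flashes to AZs over ~100 stimuli yields a
   single-AZ release probability (*Pr*).
3. **Paired before/after images** of the same AZs around an acute
   pharmacological challenge (a glutamate-receptor blocker that triggers
   presynaptic homeostatic potentiation within minutes), plus intracellular
   recordings for quantal analysis and ratiometric dye recordings for
   presynaptic Ca²⁺ transients.

No raw data from any specific experiment ship with the package; instead a
fully seeded generator reproduces each modality with known ground truth,
and every analysis is validated against that truth.

# Coordinates and containers

All user-facing coordinates are continuous, 0-based `(x, y)` pairs with
pixel centers at integer positions; a matrix element `[r, c]` is the pixel
at `(x = c - 1, y = r - 1)`. The central containers are S4 classes
(`AZMap`, `ImageFrame`, `AZMovie`, `PunctaTable`, `EventStream`,
`ReleaseTable`, `PairedIntensityTable`, `ScalingFit`, `TercileReport`,
`TransientRecording`, `EphysRecording`) with validity checks on their
invariants (e.g. unique punctum ids, `sum = mean x area`, Pr in [0, 1],
strictly increasing stimulus frames).

# Punctum detection

The detection chain mirrors the standard ImageJ workflow for AZ
quantification:

1. **Background subtraction** — constant offset or a morphological
   greyscale opening with a disc (the rolling-ball equivalent; default
   radius 25 px). Thresholds are always estimated on the *unclipped*
   subtracted image: clipping at zero halves the noise distribution and
   would collapse a MAD-based spread estimate.
2. **Light Gaussian filter** — sigma 0.75 px by default. A preset
   `live-tagrfp` replaces this with the live-imaging mask recipe
   (Gaussian sigma 2 followed by an unsharp mask, radius 3, weight 0.8).
3. **Maxima with a noise tolerance** — the segmentation primitive is a
   descending-intensity flood (implemented in C++): pixels are visited
   from brightest to dimmest, regions grow around peaks, and two regions
   merge where the dip between them is no deeper than the tolerance
   (flood-fill prominence, the semantics of ImageJ's Find Maxima). A
   surviving peak must additionally stand above the intensity threshold
   by more than the tolerance, because the threshold bounds every merge
   region from below; without this rule, degenerate noiseless images
   produce zero-prominence "maxima" on threshold-level plateaus. Plateau
   peaks report the lexicographically smallest `(y, x)` pixel; when
   regions meet, the pixel joins the neighbour with the highest peak
   (ties toward the smaller `(y, x)` root).
4. **Seeded segmentation** — every pixel at or above the threshold is
   assigned to exactly one maximum by the same flood with the maxima as
   fixed seeds; unseeded islands attach to the seed nearest their local
   peak. Label count always equals maxima count.
5. **Measurement** — per label: pixel area, intensity-weighted centroid,
   mean, and `sum = mean x area`, measured on the unfiltered
   background-subtracted image. `maskTransferMeasure()` runs detection
   once on a mask-source image and measures any number of targets with
   identical geometry, which is what guarantees 1:1 punctum
   correspondence across channels and timepoints.

**Defaults and why.** The intensity threshold defaults to a robust
"background mean + 2 SD" (median + 2·scaled-MAD of the subtracted image;
puncta occupy a small pixel fraction, so both statistics are
background-dominated). The noise tolerance defaults to 3 a.u. at the
generator's default gain: the prominence of smoothed noise ripples is
about 2 a.u. (read noise SD 2, shrunk by the 0.75 px filter), while the
dimmest spot that the synthetic suite is required to detect retains a
margin of about 3.4 a.u. above threshold after filter attenuation. Both
parameters are explicit arguments; the test suite checks that detection
quality is insensitive to moderate changes around these defaults by
operating well away from the failure boundary (recall and precision are
≥ 95 % with centroid error below 0.1 px under the suite's conditions,
versus the 0.5 px requirement).

# Optical quantal analysis

`detectEvents()` subtracts the mean of designated non-stimulus baseline
frames, finds above-threshold maxima in each stimulus frame, and accepts
an event only if a local peak persists within a 2 px match radius for at
least `persistence` (default 2) subsequent frames with non-increasing
amplitude (small tolerances, `persistenceFloor` and `amplitudeSlack`,
keep the rule robust to noise). Event coordinates are the maximum pixel —
no sub-pixel fit, matching how such events are located in practice.

`assignEvents()` performs pure nearest-neighbour Euclidean assignment of
events to punctum centroids; `maxRadius` is unlimited by default (the
assignment used in the original workflow), with a finite radius offered
because far-field spurious events are otherwise absorbed by the nearest
AZ. Ties go to the lowest punctum id. `estimatePr()` counts *distinct
stimuli* with at least one event per punctum — release is per-stimulus
binary, so duplicate detections within one stimulus collapse — and
divides by the number of stimuli taken from the stimulus log (experiments
deliver 94–100, not always exactly 100). `correlateIntensityPr()` reports
per-NMJ Pearson r between summed intensity and estimated Pr and the
unweighted mean r across NMJs, excluding (with a report) NMJs with fewer
than 3 AZs or zero variance.

# Paired plasticity analysis

Vehicle correction divides treated after-values by
`f = mean(vehicle after/before)`; with generator noise off this inverts
the simulated imaging drift exactly (the suite checks to 1e-12).
`pairedChangeTest()` gates on the normality of the deltas
(D'Agostino–Pearson for n ≥ 8, Shapiro–Wilk below) and applies a paired
*t* or Wilcoxon signed-rank test; a table of identical before/after
values takes a degenerate path returning p = 1.

`fitScalingModels()` compares two one-parameter hypotheses about
homeostatic channel accumulation: additive (`y = x + c`,
`c = mean(delta)`, the least-squares offset) and multiplicative
(`y = m x`, `m = Σxy/Σx²`, the least-squares factor through the origin).
With equal parameter counts the smaller residual sum of squares wins
outright; `indistinguishable` is declared when the RSS difference is
within 2 % of the smaller (or both are zero, as for `y = x`). AICs are
reported for transparency but cannot change the ranking. The
unconstrained regression line is reported alongside, with a 95 %
confidence interval for its slope computed from HC3
heteroscedasticity-robust standard errors — under the multiplicative
measurement-noise model residual variance grows as x², and homoscedastic
OLS intervals cover the true null slope of 1 in only about two-thirds of
replicates, whereas the robust intervals achieve near-nominal coverage.
Whether the fit uses vehicle-corrected (default) or raw after-values is
an explicit argument, since either convention is defensible.

`tercileChangeAnalysis()` ranks AZs by baseline intensity (stable order
for ties), splits them into three groups whose sizes differ by at most
one (extras go to the lower terciles), and reports the proportion with
`delta <= 0` — the operationalization of "no change or a decrease", the
paper-style criterion, applied after vehicle correction with no
tolerance band — plus all three pairwise two-sided Fisher exact tests.

`populationCompare()` normalizes per-NMJ mean intensities to the control
group mean and selects Student's *t* (equal variances by F test), Welch's
*t*, or Mann–Whitney *U* by the same normality gate; per-AZ cumulative
distributions are emitted for plotting.

# Transients and quantal analysis

The analyte is the ratio R of a Ca²⁺-sensitive to a Ca²⁺-insensitive
channel, which cancels common-mode intensity changes (the suite checks
scale invariance). Single-AP sweeps are aligned on the stimulus grid and
averaged (noise shrinks as 1/sqrt(n)); the peak is the post-stimulus
maximum minus the pre-stimulus baseline mean; τ comes from a
Levenberg–Marquardt fit of `A exp(-t/τ) + B` from the peak onward,
initialized at the observed time-to-1/e with the offset B absorbing an
unreached baseline. Fits that fail to converge or return τ ≤ 0 are
errors, and the quality gate requires a *strictly* sub-250 ms τ. The
train plateau is the mean over the last half of the train window minus
baseline (the averaging window is a free choice; half the 1 s, 20 Hz
train is comfortably past the rise). Outlier exclusion uses the literal
raw 3×MAD rule — `median(|x − median|)` without the 1.4826 consistency
factor — because that is the stated laboratory rule; the scaled variant
is an option. A zero MAD keeps only median-valued points, with a
warning. The rule is applied per NMJ by the calling code; a per-bouton
variant is simply the same function on per-bouton values.

Quantal analysis consumes amplitude lists (event detection from raw
voltage traces is out of scope): the quality gate requires V_rest in
[−80, −60] mV, R_in ≥ 5 MΩ, at least 100 miniature and 20 evoked events;
quantal content is the per-recording ratio of mean EJP to mean mEJP, and
group statistics average those per-recording ratios — not the ratio of
pooled means, which differs whenever miniature amplitudes vary between
recordings (a regression test pins this order of operations).

# The synthetic generator: what it emulates, and what it does not

Ground truth AZ maps place centers uniformly with a minimum spacing of
5 px (0.5 µm at the default 0.1 µm/px — AZs closer than ~0.3 µm are not
resolvable as separate puncta anyway) on a 256×256 px field, by rejection
sampling that errors out after 5000 consecutive rejected proposals.
Channel levels are gamma(2, 1) — right-skewed: mostly low-to-moderate,
few high — optionally shifted by `levelOffset` to impose a minimum spot
brightness. The second channel shares the gamma component plus
independent Gaussian noise sized for a target correlation (default 0.95);
both channels carry the same offset, since a real scaffold channel never
drops to zero at a genuine AZ. True Pr is a clamped affine map of the
min–max-normalized level (`clamp(0.5 z + N(0, 0.06), 0.001, 1)`): the
underlying functional form is unknown — only a strong correlation is —
so an affine coupling is the simplest choice, and with these defaults a
100-AZ map lands in the empirically observed regime (median Pr near
0.11, roughly 90 % of AZs between 0.01 and 0.5, truth-level
intensity–Pr correlation near 0.8).

Images render each AZ as an isotropic Gaussian (sigma 1.2 px ≈ 250 nm
lateral resolution at 0.1 µm/px) whose integrated intensity is
gain × level (gain 200), over a constant background (10) with Gaussian
read noise (SD 2) or optional Poisson noise. Release trials are
independent Bernoulli draws per stimulus and AZ with isotropic 1 px
localization jitter; event movies add geometrically decaying Gaussian
flashes (peak 50, decay ratio 0.5 over 4 frames at 15.3 frames/s) on
baseline frames. Paired tables apply null/additive/multiplicative
transforms with multiplicative measurement noise and a shared vehicle
drift; the vehicle group comes from an independent AZ map, as vehicle
animals are different preparations. Transients are ideal
instantaneous-rise exponentials on a sample grid that contains the
stimulus times exactly; quantal recordings draw miniature amplitudes
from a gamma distribution with specified mean and CV and compose evoked
responses as Poisson sums of quanta.

Deliberately **not** modeled: 3-D optics and optical sectioning,
photobleaching, stage drift and motion (movies are motion-free, so no
frame alignment is needed), multi-vesicular release and indicator
saturation, spontaneous release events, and nonlinear EJP summation.
Passing tests therefore demonstrate correctness of the analysis chain
under a faithful but idealized forward model — not robustness to motion
artifacts, bleaching trends, or detector nonlinearity in real
recordings.

# Numerical choices and degenerate inputs

* Maxima/segmentation tie-breaks are fully deterministic (documented
  above), making the whole pipeline bit-reproducible under a fixed seed.
* `findMaxima` on a constant image returns nothing under default
  thresholding (the threshold equals the constant, and no peak clears it
  by more than the tolerance).
* The D'Agostino–Pearson implementation follows the canonical algorithm
  including its zero-skewness convention (y = 0 is replaced by 1 in the
  skew transform), so statistics agree with the reference implementations
  to ~1e-10 on frozen fixtures.
* Fisher exact p-values come from `fisher.test`; an independent
  first-principles hypergeometric enumeration in the test suite confirms
  agreement to 1e-12 on every 2×2 table with n ≤ 40 (deduplicated by the
  symmetries that leave the two-sided p unchanged).
* Exact-arithmetic examples (vehicle correction f = 0.9 → 90/0.9 = 100;
  MAD example [1, 2, 3, 4, 100] → bounds [0, 6]) are asserted literally.

# Problem sizes used by the automated checks

The test suite exercises the stated study conditions directly: 50 seeded
100-AZ images for detection accuracy; 1000 random instances for the
assignment oracle; 100 AZs × 100 stimuli × 1000 seeds for Pr recovery
(per-AZ bias and 95 % Clopper–Pearson coverage); 100 seeds of 44-AZ NMJs
for correlation recovery; 100 replicates per truth mode for scaling
discrimination (n = 500 AZs, noise CV 0.1); 200 seeded transients for τ
recovery; and two full pipeline runs for determinism. The whole suite
completes in a few minutes on one CPU.

# Known limitations

* Sub-pixel event localization is deliberately absent; at jitter ~1 px
  and AZ spacing ≥ 5 px, nearest-neighbour assignment is already
  essentially error-free, but denser fields would need a finite
  `maxRadius` or probabilistic assignment.
* The rolling-ball background is a greyscale opening, not the exact
  ImageJ sliding-paraboloid; for the constant or slowly varying
  backgrounds modeled here the two are interchangeable.
* `correlateIntensityPr` treats NMJs independently; no hierarchical
  model pools information across animals.
* The scaling-model comparison is restricted to the two one-parameter
  hypotheses; mixed or saturating accumulation models are out of scope.
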