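# azquant

Quantification of presynaptic voltage-gated Ca²⁺ channels at single
active zones (AZs) of the *Drosophila* larval neuromuscular junction, and
of their relationship to single-synapse function and homeostatic
plasticity.

At the fly NMJ, each release site is marked by one fluorescent punctum of
endogenously tagged Cacophony (the CaV2 pore-forming subunit), colocalized
with the scaffold protein Bruchpilot. Channel abundance per AZ is broadly
and right-skewed distributed, and it predicts the probability *Pr* that a
single stimulus evokes vesicle release at that AZ. `azquant` implements
the complete analysis chain for this biology:

* **Punctum detection and quantification** — background subtraction, light
  Gaussian filtering, ImageJ-Find-Maxima-style segmentation (local maxima
  with a prominence *noise tolerance*; descending flood/watershed
  assignment of above-threshold pixels), and per-punctum measurement where
  `sum_intensity = mean x area`. A mask detected on one channel or
  timepoint is transferred verbatim to others, so puncta correspond 1:1
  across channels (Brp mask → Cac channel; after-treatment mask →
  before/after images).
* **Optical quantal analysis** — stimulus-locked event detection in
  postsynaptic Ca²⁺-indicator movies (baseline-frame subtraction, per-frame
  maxima, a persistence-with-decay criterion), nearest-neighbour Euclidean
  assignment of events to AZ centroids, per-AZ release probability
  `Pr = distinct-stimulus event count / n stimuli`, and per-NMJ Pearson
  correlation of channel intensity with *Pr*.
* **Homeostatic plasticity** — paired before/after single-AZ intensities
  with vehicle correction (division by the mean vehicle after/before
  ratio); discrimination of additive (`y = x + c`) versus multiplicative
  (`y = m·x`) scaling by residual sum of squares of the two one-parameter
  fits; tercile change-frequency analysis with pairwise Fisher exact
  tests; population comparisons with normality-gated test selection
  (D'Agostino–Pearson omnibus → Student/Welch *t* or Mann–Whitney *U*).
* **Ca²⁺ transients** — rhod/AF647 ratio traces, sweep averaging, peak
  amplitude and exponential decay constant τ (with a τ < 250 ms quality
  gate), train plateau amplitude, and the raw 3×MAD outlier exclusion
  rule (`keep x in [median ± 3·median(|x − median|)]`).
* **Quantal analysis of intracellular recordings** — recording quality
  gates (V_rest in [−80, −60] mV, R_in ≥ 5 MΩ, ≥ 100 mEJPs, ≥ 20 EJPs)
  and quantal content as the per-recording ratio of mean EJP to mean mEJP
  amplitude, averaged across recordings.
* **A seeded synthetic-data generator** producing every input — ground
  truth AZ maps with gamma-distributed channel levels coupled to *Pr*,
  rendered two-channel spot images, Bernoulli release trials, event
  movies, paired-intensity tables, ratiometric transients and quantal
  recordings — so the entire pipeline is testable against known truth
  with no external data.

## Worked example

```r
library(azquant)

azm    <- simulateAZMap(nAZ = 44, fieldWidth = 192, fieldHeight = 192,
                        levelOffset = 0.5, seed = 7)
img    <- renderPunctaImage(azm, noise = "gaussian", noiseSD = 2, seed = 8)
det    <- detectPuncta(img, backgroundMethod = "constant",
                       backgroundValue = 10)
trials <- simulateReleaseTrials(azm, nStimuli = 100, seed = 9)
movie  <- renderEventMovie(trials, azm, framesPerStim = 3, seed = 10)
events <- detectEvents(movie, threshold = 20)
rel    <- estimatePr(assignEvents(events, det$puncta), nStimuli(events),
                     det$puncta)
rel
#> ReleaseTable: 44 puncta over 100 stimuli; 0 unassigned events
#>   Pr estimate: median 0.22
correlateIntensityPr(det$puncta, rel)
#> CorrelationResult: 1 NMJs, average r = 0.899
```

All 44 planted AZs are recovered as puncta; every detected event is
assigned to an AZ; the estimated per-AZ release probabilities correlate
strongly with measured channel intensity, as they should given the
generator's intensity→Pr coupling. `runPipeline()` (or the thin
`inst/scripts/azquant` wrapper) chains these stages from a YAML config and
writes CSV/JSON/TIFF artifacts with a resolved-config copy and a run log.

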