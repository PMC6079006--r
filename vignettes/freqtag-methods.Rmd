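---
title: "Frequency-tagged analysis of auditory statistical learning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-tagged analysis of auditory statistical learning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When pure tones are played at a fixed rate, the auditory system entrains
and the brain signal acquires a spectral line at that rate ("frequency
tagging", the auditory analogue of steady-state visual evoked
potentials). If the tones are additionally organised into hidden triplets
("tritones" — ordered triples with within-triplet transitional
probability 1), a listener who *segments* the stream develops a second
line at the triplet rate. Tagging therefore turns statistical learning
into a spectral detection problem: a tone-rate response indexes basic
auditory processing, a triplet-rate response indexes segmentation.

`freqtag` implements this full analysis chain as a reusable, tested
pipeline: stream generation, a synthetic multichannel MEG generator used
as study data, neighbour-bin SNR spectra, cluster-based permutation
statistics over sensor topographies, AICc-guided mixed-model selection of
temporal dynamics, and the behavioural 2AFC analyses. Real cohort data
for this design are not publicly deposited, so the package's synthetic
generator defines the study conditions under which every claim is tested.

## Stimulus design

Twelve pure tones (C4–B4, equal temperament, A = 440 Hz) of 150 ms with
5 ms raised-cosine flanks are presented with a 25 ms inter-stimulus
interval; a further 20 ms blank is inserted every three tones. The
effective tone rate is `1/(0.175 + 0.020/3) = 5.505 Hz` and the triplet
rate a third of that, `1.835 Hz`; a triplet cycle lasts exactly
0.545 s. Streams:

* **STAT** — four tritones (G#CD, AC#G, FA#D#, EF#B) concatenated with
  immediate repetition proscribed; the successor triple is drawn
  uniformly from the other three, which yields the design
  triple-to-triple transitional probability of 1/3. A foil set
  (DG#F, D#A#A, BC#F#, GCE) shares no transitional pair and no boundary
  tone with the exposed set and feeds the 2AFC test;
  `generate_tritone_set()` reproduces such sets by rejection sampling
  under the same constraints.
* **RDM** — the same twelve tones, uniform over the 11 non-identical
  successors (tone-to-tone TP 1/11 ≈ 9%), same blank grid.
* **HAB** — ascending/descending scales on the plain 175 ms grid; each
  ascent repeats independently with probability 0.3. We treat the
  design's nominal inter-repetition statistics (12.5 ± 11.3 s on
  average) as emergent from that rate, not as a constraint, and we omit the 20 ms blank here
  because the blank is a segmentation cue specific to the tagged
  streams.

One design ambiguity deserves note: a nominal "5-minute" block is
described both as 300 s and as 560 triplet cycles, but 560 × 0.545 s =
305.2 s. We define the canonical 5-minute epoch as **exactly 560
cycles** so that both frequencies of interest fall on exact DFT bins;
the 1-minute window is 112 cycles = 61.04 s for the same reason.

## The synthetic MEG generator

The sensor model is a 102-chipset helmet-like disc layout (sunflower
spiral), each chipset carrying one magnetometer and two orthogonal
planar gradiometers (306 channels). Chipset adjacency comes from a
Delaunay triangulation of the layout (Bowyer–Watson, implemented in the
package and cross-checked against an independent computational-geometry
implementation during development); typical mean degree is ≈ 5.7. The
layout is synthetic — it stands in for a whole-head system, and no
quantitative match to any vendor geometry or to empirically recorded
topographies is claimed; left/right temporal regions are identified by
coordinate only.

The signal model is deliberately minimal:

* every tone evokes a fixed kernel (damped 10 Hz sinusoid, 80 ms decay);
  only the train's periodicity matters for tagging, so the kernel shape
  is a free, documented choice;
* the tone train is synthesized in the frequency domain as the exact
  Fourier series of the periodic kernel summation, truncated below
  Nyquist. This matters: a naive time-domain train sampled at a rate
  that divides the cycle but not the tone period aliases a small
  spurious line onto the triplet frequency, corrupting the null
  scenario. The band-limited construction has power at tone harmonics
  only, to machine precision;
* segmentation is an extra kernel (6 Hz carrier, 120 ms decay) on
  triple-initial tones with amplitude `tritone_amp`; 0 means no
  segmentation. In the wake scenario the amplitude ramps linearly
  (0.5× → 1.5×) across the exposure, producing the within-session
  build-up the dynamics stage is designed to detect;
* background noise is `1/f` (β = 1) plus white, shaped spectrally in a
  single Hermitian-symmetric draw. The sleep regime multiplies the
  `1/f` profile below 2 Hz by 4 through a smooth logistic roll-off
  (scale 0.25 Hz): a hard spectral step would bias the neighbour-ratio
  SNR of bins near the edge, which no physiological spectrum would do.
  The profile is normalized before boosting, so sleep adds
  low-frequency power without changing the noise floor at the tone
  rate;
* the two gradiometers of a chipset receive the signal split as
  cos/sin of a per-chipset orientation, making combined-gradiometer
  power orientation-invariant; units are arbitrary throughout (SNR is
  unit-free).

Amplitude defaults (`tone_amp = 1`, `tritone_amp = 0.6`,
`pink_noise_sd = 1`, `white_noise_sd = 0.3`) were fixed once, by a pilot
calibration, to reproduce the magnitudes the pipeline is meant to
recover: whole-exposure tone SNR of order 40–150 at temporal sensors and
a wake STAT tritone SNR of roughly 1.4–2 at sensors of interest, with
RDM tritone SNR at baseline 1.

Cohort simulations run at `fs = 200 Hz` (0.545 s = 109 samples exactly)
rather than the canonical 1 kHz of the recording container default: all
analysis frequencies lie below 12 Hz, SNR is sampling-rate-free, and the
reduction keeps a full two-scenario cohort analysis on a single CPU in
minutes. Per-subject topography jitter (patch centre, gain, right-side
dominance) and per-run noise seeds derive from the master seed by a
counter scheme (`derive_seeds()`), so cohorts are reproducible and
extensible.

## Spectral analysis

Epochs start at the trigger following the first 12 tones (transient
skip) and span an integer number of 0.545 s cycles, putting
1.835/5.505 Hz (and their first harmonics 3.67/11.01 Hz, both inside the
1.5–12 Hz band) on exact bins; `foi_bin()` refuses frequencies more than
half a resolution step from the nearest bin, which catches mis-sized
epochs early. Runs are averaged in the time domain (phase-locked
averaging), power is `|X|²/N` of the Hann-windowed DFT (the
normalization cancels in every downstream ratio; a rectangular window is
available for energy checks), gradiometer pairs are combined by summing
power, and the SNR of each bin is its power divided by the mean power of
flanking bins.

Two neighbourhood readings were open: we take "200 neighbouring bins" as
100 per side (40 as 20 per side) for a symmetric local noise-floor
estimate, and "skipping the two closest" as 2 bins per side to guard
leakage symmetrically; both counts are arguments, not constants. Bins
whose neighbourhood is truncated by the band edge are evaluated with the
available bins and flagged. Under a flat spectrum the SNR is exactly 1
in expectation; under `1/f` noise the convexity of the spectrum biases
low-frequency bins a few percent *below* 1, which is visible in the
sleep-null summaries and is a property of the estimator, not a bug.

## Cluster statistics and sensors of interest

Condition contrasts use the standard cluster-based permutation
construction: per-chipset paired t statistics, suprathreshold grouping
by the Delaunay adjacency at the one-sided `t(n−1)` quantile
(cluster-forming α = 0.05 by default), cluster mass = Σt ("maxsum";
cluster size is available), and a Monte-Carlo null from within-subject
sign flips with the plus-one p estimator (p can never be exactly 0).
The tested direction is fixed a priori as STAT > RDM. For small cohorts
the Monte-Carlo p agrees with exhaustive enumeration of all 2ⁿ flips to
±0.01 (tested at n = 8).

Sensors of interest follow two rules: a per-chipset one-sample sign-flip
permutation test of SNR > 1 (uncorrected α = 0.05), and simple
group-mean thresholds (tone SNR > 5 at wake, > 2 in the sleep regime,
minutes 1–2 of RDM; tritone SNR > 1.25 as the shortcut variant). On
wake-effect cohorts the permutation mask and the 1.25 threshold select
nearly the same sensors, which the acceptance suite checks.

## Temporal dynamics and model selection

Each first run is cropped into five 1-minute windows; power spectra of
the four overlapping minute pairs (1–2 … 4–5) are averaged — power, not
complex coefficients; `"Fourier spectra values"` is ambiguous on this
point, and averaging power is the reading consistent with the rest of
the chain, though the epoch-averaging step upstream already removes
non-phase-locked signal. SNR uses 40 neighbours, and SOI-averaged values
per subject × window × stream form the dynamics table.

Model selection is the two-step procedure: step 1 fixes the saturated
fixed model (categorical MINUTES × STREAM, plus GROUP at wake) and
compares the four random structures (intercept; + MINUTES slope;
+ STREAM slope; + both) under REML by AICc; step 2 fixes the winning
structure and compares all hierarchy-respecting fixed models over
STREAM, GROUP and one MINUTES encoding (categorical, continuous 1..4,
or orthogonal quadratic) under ML by AICc — 11 candidates for the
two-predictor design, 47 with GROUP. AICc is `AIC + 2k(k+1)/(n−k−1)`
with `n` the number of observations, the standard small-sample
correction; comparing REML fits in step 1 is valid because the fixed
part is held constant there. Fitting is delegated to `lme4`, with
Satterthwaite p-values for the selected model from `lmerTest`;
the enumeration, AICc accounting and selection logic are this package's.
Non-converging candidates are dropped with a warning and singular fits
are flagged — the procedure's behaviour in that case is a package
decision, since no convention is prescribed for it.

## Behavioural analysis

2AFC scoring counts the trials where the exposed-set tritone was chosen
(percent of 16; 50% is chance). The test against chance is the
one-sample Wilcoxon *signed-rank* test: the design names a "rank sum
test against chance" but reports the `V` statistic, which is R's
signed-rank convention, so the signed-rank reading is implemented and
the naming inconsistency noted. Group comparisons use the
independent-samples Wilcoxon (ties mid-ranked). The JZS Bayes factor
integrates the noncentral-t marginal likelihood over a Cauchy(0, √2/2)
effect-size prior (the conventional default of Bayesian t-test
software), one-sided (scores > 50) for the chance test per the
directional learning hypothesis; a reported between-group "paired"
Bayesian test is implemented as the independent-samples variant, since
the groups are independent. Verdict thresholds are 3 and 1/3.

## What the synthetic cohorts do and do not show

Passing tests on these cohorts demonstrate that the pipeline recovers
planted effects and stays at baseline under planted nulls, at the
printed rates and geometries — parameter recovery, not empirical
replication. The generator omits, among other things: head movement and
its interference correction, realistic source-space mixing (gain maps
are Gaussian patches, not lead fields), sleep microstructure (spindles,
K-complexes, stage transitions), inter-subject latency differences, and
any relationship between behavioural scores and neural responses
(behavioural cohorts are simulated at a flat per-trial success
probability). Group-level empirical values from real participants are
therefore out of reach by design; the acceptance checks target the
stream statistics and the structural null/positive patterns instead.

## Problem sizes and numerical choices

Desk-scale study conditions used by the test and acceptance suites:
10 subjects per scenario, 2 runs per stream, 566-cycle runs analysed as
560-cycle epochs at 200 Hz, 2 000 permutations in cohort-level tests
(10 000 is the config default, used in the analysis scripts), 100
replicates for selection-recovery simulations. Seeds are fixed
everywhere; identical seeds give byte-identical artifact trees (every
table carries an FNV-1a hash of its configuration so mixed-provenance
bundles are detectable). Degenerate inputs — zero-variance chipsets,
all-at-chance scores, epochs short of a full window — raise typed
errors rather than propagating NaNs; zero-variance chipsets inside the
permutation tests yield NA t-values that simply cannot enter clusters.

## Known limitations

The neighbour template is Delaunay on a synthetic layout — analogous to,
not identical with, any vendor-specific template. The SNR estimator's
small negative bias under steep `1/f` backgrounds (and positive bias
below any sharp spectral edge) is inherited from the neighbour-ratio
definition. REML-based AICc comparison of random structures is a
convention, defensible only with the fixed part saturated. The JZS
integration uses adaptive quadrature; for |t| beyond ≈ 30 the noncentral
t density underflows and the Bayes factor saturates — far outside the
regime of the analyses here.
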