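---
title: "Measuring dyadic cooperation from wearable EEG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dyadic cooperation from wearable EEG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopeeg)
```

## The problem

When two operators work a shared task — two pilots flying one aircraft, two
controllers managing one sector — their degree of cooperation is usually
judged subjectively, by an observer scoring behaviour. `coopeeg` implements
two objective, neurophysiological alternatives computed from few-channel
wearable EEG (frontal AFz, AF3, AF4, AF7, AF8 and parietal Pz, P3, P4 at
125 Hz), designed to work *without* hyperscanning, i.e. without
clock-synchronised joint acquisition:

* **CCI** (circular-correlation cooperation index): phase synchrony between
  the two operators' EEG, measured as the circular correlation of their
  instantaneous phases.
* **MICI** (mutual-information cooperation index): statistical dependence
  between the two operators' *mental states*, measured as the mutual
  information between each operator's EEG-derived mental-workload and
  approach-withdrawal time series.

Because no real dyadic recordings ship with the package, a synthetic dyad
simulator with fully known ground truth is a first-class component: every
stage of the pipeline is validated against quantities the generator
controls.

## Preprocessing

Raw recordings pass through a fixed chain: exclusion of movement-prone
channels (AF7, AF8 by default), a 50 Hz notch, a 2–30 Hz 5th-order
Butterworth band-pass, segmentation into 1-s epochs, and an amplitude
artifact rule that marks an epoch artifactual when any retained channel
exceeds ±80 µV. Two choices deserve note:

* **Zero-phase filtering.** Filters are applied forward–backward
  (`signal::filtfilt`). A one-directional filter would add a
  frequency-dependent group delay, which the downstream *phase* metric must
  not inherit. The flag is configurable in `filter_spec()`.
* **Artifact rule scope.** Whether the ±80 µV rule should look at any
  channel or per channel is genuinely open; the default masks an epoch when
  *any retained* channel exceeds the bound (conservative for features that
  mix channels), with `rule = "per_channel"` exposing the per-channel
  exceedance matrix. Because the rule runs after channel exclusion,
  artifacts confined to excluded channels never mask epochs.

Ocular correction by blink modelling is out of scope; a pluggable
`ocular_hook` is provided for users who have one, and the amplitude rule is
the safety net. The trailing partial epoch is dropped: all downstream
windowing assumes fixed-length epochs.

## Spectral features

Band boundaries are anchored per operator to the individual alpha frequency
(IAF), estimated as the peak of the mean parietal Welch spectrum within
7–13 Hz on the eyes-closed calibration segment. A spectrum whose maximum
sits on the search boundary has no genuine alpha peak (typical of pure 1/f
input); the estimator then falls back to 10 Hz with a warning. Bands are
theta `[IAF-6, IAF-2]`, alpha `[IAF-2, IAF+2]`, beta `[IAF+2, IAF+16]` Hz.

**Global field power.** GFP here is operationalised as *mean band power
over a named channel set*: band-pass filter (4th-order Butterworth, zero
phase, applied to the concatenated epochs so epoch edges add no transient),
square, average over time and channels. The classical GFP of full-montage
EEG is a spatial standard deviation; with a six-channel montage, and with
the asymmetry feature applying "GFP" to a *single* channel, a power reading
is the only coherent interpretation that serves both uses. Band power by
time-domain filtering (rather than a spectral estimator) is exact on
sinusoids, which makes the feature unit-testable against closed forms
(a sinusoid of amplitude A has mean square A²/2).

The two state features, per window (default 1 s, one epoch):

* mental workload `W(t) = GFP_theta(AF3, AFz, AF4) / GFP_alpha(P3, Pz, P4)`
  — frontal theta rises and parietal alpha falls with cognitive effort, so
  the ratio rises. Windows whose denominator sits below 1e-12 µV² are marked
  invalid rather than clipped.
* approach–withdrawal `AW(t) = GFP_alpha(AF4) − GFP_alpha(AF3)` — frontal
  alpha asymmetry, indexing emotional approach (positive) versus withdrawal.

Windows with more than 50% artifactual epochs are invalid and propagate as
such; they are never zero-filled.

## CCI: circular correlation of instantaneous phases

Per channel the instantaneous phase is the complex argument of the analytic
signal (FFT construction); a region phase (frontal AF3/AFz/AF4 or parietal
P3/Pz/P4) is the angle of the mean unit phasor across channels — preferred
over averaging channel-pair coefficients because it involves no arbitrary
pairing and reduces exactly to the single-channel phase for one channel.

For two phase series the index is the Jammalamadaka–SenGupta circular
correlation

$$\rho_c(\theta,\phi) =
\frac{\sum_k \sin(\theta_k-\bar\theta)\sin(\phi_k-\bar\phi)}
{\sqrt{\sum_k \sin^2(\theta_k-\bar\theta)\sum_k \sin^2(\phi_k-\bar\phi)}},$$

with $\bar\theta$ the circular mean $\arg\sum_k e^{i\theta_k}$. This form —
with the square root of the product of separate denominator sums — is the
standard one from the circular-statistics literature; it is the only form
that yields 1 for identical series, and it is what the package implements.
It is symmetric, bounded in [−1, 1], and invariant to constant phase
offsets of either series — the property that makes the index usable without
hyperscanning, where a constant clock offset between the two acquisitions is
unavoidable.

Degenerate windows (phase-constant input, undefined circular mean) yield an
*invalid* window, never a zero: zero is a meaningful value of the index.

One behaviour worth knowing: when a phase series wraps uniformly around the
circle, its circular mean is weakly determined, and the coefficient between
two *nearly* (not exactly) identical series fluctuates well below 1. This is
a property of the statistic itself, not of the implementation; it is why
window-level CCI values are treated as a distribution to be compared across
conditions, not as a calibrated synchrony magnitude.

CCI is computed over sliding windows (default 30 s, matching the
behavioural rating cadence; the desk-scale analyses below use 10 s so that
each experimental phase contributes enough windows), on the full 2–30 Hz
band and optionally per IAF-anchored band, with recordings aligned at
session start and truncated to the shorter member for surrogate pairs.

## MICI: Kraskov mutual information between state series

Cooperation is modelled as dependence between the two operators' joint
cognitive–emotional states: $X = (W_1, AW_1)$, $Y = (W_2, AW_2)$, i.e. the
four series enter as two operator-wise 2-D marginals, matching the view of
cooperation as the output of a multivariate system formed by the two
individuals (pairwise 1-D groupings would measure something else — e.g.
workload–workload coupling only — and remain available to users by calling
the estimator directly). MICI exists only on full-band features: W and AW
already commit to fixed bands, so a per-band MICI is not defined.

Mutual information is estimated with a from-scratch implementation of the
Kraskov–Stögbauer–Grassberger k-nearest-neighbour estimator (algorithm 1,
max-norm metric, k = 4 by default, in nats — the digamma-based estimator is
natural-log native):

$$\hat I = \psi(k) + \psi(n) -
\left\langle \psi(n_x+1) + \psi(n_y+1) \right\rangle,$$

where for each point $\epsilon_i$ is the max-norm distance to its k-th
neighbour in the joint space and $n_x, n_y$ count points strictly within
$\epsilon_i$ in each marginal. Neighbour counting is exact O(n²) in
compiled code; a naive pure-R transcription serves as the oracle in the
test suite, and bivariate Gaussians with closed-form MI
$-\tfrac12\ln(1-\rho^2)$ validate the estimates. Tied coordinates, fatal to
neighbour counting, are broken by a seeded jitter of 1e-10 × coordinate
scale with a warning. The raw estimate may be slightly negative for
independent data; the returned value is floored at 0 with the raw value
kept as a diagnostic attribute.

MICI(t) is one estimate per consecutive block (default 30 s = 30 windows of
1 s in the desk-scale analyses: enough points for k = 4 while keeping a
time course; block length is a trade-off the user owns). Features are
z-scored per block — MI is invariant to monotone rescaling asymptotically,
and standardising removes finite-n scale pathologies. A permutation null
(`permutation_null()`, row-shuffles of Y) calibrates observed values.

## Thresholds, cooperation time, surrogate crews, statistics

The session protocol has each operator fly two *calibration* tasks alone
(low and high difficulty) before the joint *cooperation* task. The
cooperation threshold of an index is the pooled median over all valid
calibration windows (even-n median = mean of the central pair); the
**cooperation time percentage** of a phase is the share of valid windows
*strictly* above the threshold (ties count as non-cooperative —
conservative). By the median property, calibration itself sits at ≈50%.

**FAKE crews** are the no-cooperation null: surrogate pairings of operators
from *different* crews (never reproducing a real pairing with matched
phases), truncated to the shorter member, with provenance recorded. By
construction no shared stimulus links the pair, so their cooperation-phase
index must not be elevated over calibration.

Group statistics follow standard normality-gated practice: Shapiro–Wilk at
α = 0.05 on each group, then Student's t (paired or unpaired) or
Mann–Whitney / Wilcoxon signed-rank, with Cohen's d or rank-biserial
effect sizes; phase comparisons use fixed-effects ANOVA with ω² effect
sizes after Shapiro–Wilk (residuals) and Bartlett checks — failures are
reported as caveats and a rank-based alternative (Kruskal–Wallis, or
Friedman on complete crew blocks) accompanies the table. Index-vs-rating
validation uses Pearson correlation of the index aggregated to the 30-s
rating cadence against the crew-level behavioural score (the mean of the
two operators' ratings). Benjamini–Hochberg correction across a report's
comparisons is available but off by default. The cooperation-vs-calibration
*elevation* contrast is paired at the window level (window k of the
cooperation phase against the mean of window k of the two calibration
phases, pooled over the crews of a group): elevation is a within-crew,
directional question, and window pairing uses all the data a session
provides.

## The synthetic dyad generator

The generator emulates exactly the structure the indices assume, with every
nuisance parameter explicit:

* **Oscillators.** Per operator and band, a cosine at the band centre
  (IAF−4, IAF, IAF+9 Hz) whose phase advances linearly plus a Wiener phase
  jitter (0.75 rad/√s, a Lorentzian linewidth of ~0.1 Hz). The jitter rate
  trades realism against statistical stability: faster diffusion broadens
  the spectral peak towards real alpha-peak widths but makes windowed
  phase statistics — for coupled and uncoupled dyads alike — much noisier,
  because the within-window spread of the inter-operator phase difference
  is what the circular correlation actually measures.
* **Coupling.** Operator 2's band phase is the circular mixture
  $\arg\{(1-c)\,e^{i\psi_2} + c\,e^{i\phi_1}\}$ of its own free-running
  phase and operator 1's phase: c = 0 gives independence, c = 1 identical
  phases, and the circular correlation of the generated phases is monotone
  in c — simple and analytically checkable. Coupling (and the latent-state
  correlation below) is active only during configured phases, by default
  the cooperation phase, mirroring the protocol in which calibration is
  flown alone.
* **State realisation.** Per 1-s epoch, oscillator amplitudes are set so
  that the clean-signal features equal the target levels: frontal theta
  amplitude $= A_{pa}\sqrt{W}$ realises the workload ratio; AF4/AF3 alpha
  amplitudes $\sqrt{A_0^2 \pm AW}$ realise the asymmetry difference.
  Targets are per-phase constants modulated by latent AR(1) processes
  (coefficient 0.8 at 1-s steps, ~5 s correlation time; log-workload sd
  0.4, asymmetry sd 0.8) whose innovations are correlated across operators
  by `shared_state_corr` — the ground truth that MICI must detect. The
  latent sds are set so state fluctuations are comparable to between-phase
  target differences and stand clearly above the band-limited background
  noise that the features also integrate; weaker settings would make the
  features mostly measurement noise, which is a statement about the
  generator's signal-to-noise choice, not about the estimator.
* **Noise and artifacts.** 1/f background (spectrally shaped white noise,
  2 µV RMS per channel, slope 1) and stereotyped blinks: 400-ms biphasic
  transients on frontal channels, peak 150 µV, Poisson arrivals. Blinks are
  placed to lie within single 1-s epochs, at most one per epoch (a
  refractory constraint), so the generator's event log is an *exact* oracle
  for the ±80 µV mask — the one deliberate stylisation in the artifact
  model, chosen to make the preprocessing contract exactly testable rather
  than approximately (overlapping biphasic transients could otherwise
  cancel below threshold).
* **Determinism.** All randomness flows through one seed;
  identical scenario + seed gives bit-identical output, and the generator
  restores the caller's RNG state.

What the generator does *not* emulate: volume conduction and realistic
electrode topography, non-stationary artifact regimes (cable sway, muscle
bursts), true EOG waveforms, inter-individual IAF drift within a session,
and any nonlinear cross-frequency structure. Passing the synthetic suite
therefore shows the estimators recover the *modelled* coupling and state
dependence through the full preprocessing chain — it does not certify
performance on real cockpit EEG.

## Desk-scale experiment and problem sizes

`synthetic_crew_experiment()` is the package's reference analysis: 4
high-coupling ("EXP"-like, coupling and shared-state 0.8) and 4
low-coupling ("UNEXP"-like, 0.3) crews, each with 60 s eyes-closed and
120-s low-difficulty, high-difficulty and cooperation phases; 10-s CCI
windows, 1-s feature windows, 30-s MICI blocks; as many FAKE crews as real
ones. These sizes are the package's chosen desk-scale defaults: large
enough that each phase contributes 12 CCI windows and 4 MICI blocks per
crew, small enough that the full experiment (16 analysed sessions) runs in
well under a minute. The test suite repeats the experiment across seeds and
asserts distributional properties (group ordering of cooperation time,
REAL-but-not-FAKE cooperation-phase elevation), not single-run point
values.

```{r experiment, eval = FALSE}
report <- synthetic_crew_experiment(seed = 1)
print(report)
```

## Numerical choices, degenerate inputs, limitations

* Circular means with resultant length < 1e-9 (antipodal cancellation) are
  errors at the primitive level and invalid windows at the pipeline level.
* The KSG estimator requires n > k+1; blocks with fewer jointly valid
  windows are invalid. Ties are jittered (seeded), never silently dropped.
* Strict-inequality thresholding means an index constant at its threshold
  scores 0% cooperation time.
* The Friedman test is available alongside the ANOVA for complete
  crew-blocked designs, as repeated-measures phase comparisons are
  sometimes reported that way; the ANOVA (with checks and a rank fallback)
  is the default.
* CCI windows shorter than ~2 s would under-sample the circular means; the
  implementation refuses them.
* MICI values are not comparable across different block lengths or k; a
  report should fix both (they are logged per run).
* EDF input is not supported — recordings are read/written as CSV/TSV
  (wide or long); the containers are format-agnostic, so adding a reader
  is a contained change.
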