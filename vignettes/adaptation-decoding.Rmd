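---
title: "Decoding stimulus identity from LFP band power in an adaptation paradigm"
author: "adaptdecode authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding stimulus identity from LFP band power in an adaptation paradigm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptdecode)
```

## The scientific question

When a visual stimulus is repeated after a short interval, neural
responses in higher visual cortex decrease ("repetition suppression" or
adaptation). Beyond the drop in response magnitude, the interesting
question is informational: does repetition make the stimulus *harder to
read out* from the population signal, and does the answer depend on
which frequency band of the local field potential (LFP) carries the
information?

`adaptdecode` implements a complete analysis chain for this question in
the classic two-stimulus adaptation design: each trial shows an adapter
stimulus (500 ms), a blank interval (500 ms) and a test stimulus
(500 ms); trials are repetitions (AA, BB) or alternations (AB, BA) of
two stimuli A and B, pseudorandomised under the constraint that a
trial's adapter always differs from the last stimulus of the preceding
trial. The readout is a linear support vector machine (SVM) trained on
per-site band power of a simultaneously recorded laminar population
(up to 16 sites, 1 kHz).

Because no public recordings exist for this paradigm, the package ships
a first-class synthetic session generator with known ground truth, so
that every stage — preprocessing, spectral estimation, decoding,
statistics — is testable end to end.

## The analysis chain

### Preprocessing

* **Notch filter.** A 48–52 Hz band-stop Butterworth filter of order 4
  removes mains interference. It is applied forward–backward
  (zero-phase) so the analysis window is not shifted; the steady-state
  residual at 50 Hz is below 1% of input power while 10 Hz passes with
  less than 1% loss. (Filter-design aside: a "Butterworth FIR" is a
  contradiction in terms — Butterworth prototypes are IIR — so the
  package implements the IIR band-stop and applies it zero-phase.)
* **Trial rejection.** A trial is excluded when any sample on any
  analysed site reaches below 1% or above 99% of the *declared* input
  range of the acquisition system. The range is metadata and is never
  inferred from the data: inferring it would make rejection depend on
  the data being cleaned. Aborted trials are never analysed.
* **Analysis window.** All per-trial quantities are computed in an early
  window from 60 to 310 ms after stimulus onset, taken half-open
  `[60, 310)` so that it holds exactly 250 samples at 1 kHz. The early
  window targets the response phase where adaptation is strongest.

### Spectral estimation

Power is estimated by convolution with complex Morlet wavelets of
constant centre-frequency to spectral-bandwidth ratio
$f_0/\sigma_f = 7$, on an integer grid $f_0 = 1 \dots 170$ Hz
($\sigma_t = 1/(2\pi\sigma_f)$), and squaring the magnitude. Band power
is the arithmetic mean over the grid frequencies inside each band —
alpha 8–12, beta 13–30, low gamma 31–60, middle gamma 61–100, high
gamma 101–170 Hz, edges inclusive so the bands partition 8–170 Hz — and
over the window samples.

Numerical choices:

* wavelets carry unit L2 energy; since every feature is z-normalised
  per site before classification, any per-frequency normalisation
  convention cancels and cannot change accuracies;
* the Gaussian envelope is truncated at $\pm 4\sigma_t$ (tail
  $< 10^{-4}$);
* convolution runs in the frequency domain on a trace segment that
  covers the analysis window plus the full wavelet support, which is
  provably identical (to FFT round-off; tested at $10^{-10}$ relative)
  to convolving the whole trial and windowing afterwards — convolution
  edge effects can therefore never touch the window;
* samples within $3\sigma_t$ of a trace end are edge-flagged and any
  request that touches them errors instead of silently averaging;
  frequencies whose $6\sigma_t$ support exceeds the trace are marked
  invalid rather than returned.

### Decoding

Four two-class conditions are built per penetration, labels always
A vs B:

| condition | trials / epoch | sub-datasets |
|---|---|---|
| Adapter | adapter epochs | AA vs BB; AB vs BA (scored separately) |
| Test_rep | test epochs | AA vs BB |
| Test_alt | test epochs | BA vs AB (label = test stimulus) |
| Test_sameAdapter | test epochs | AA vs AB; BA vs BB |

To make accuracies comparable, a single per-class trial count
$N_\mathrm{tot}$ — the largest even integer not exceeding the smallest
per-class count over all sub-datasets — is used for every condition and
feature set of a penetration ("smallest even number" read as
floor-to-even, which guarantees an exact half/half split). Each of the
(by default 1000) repetitions draws $N_\mathrm{tot}$ trials per class
afresh from the full pool, splits them half/half into train and test,
z-normalises every site with training statistics (a zero-variance
training feature is set to zero everywhere: it carries no information),
trains a linear SVM with soft-margin cost fixed at 1 (the toolbox
default the original analysis relied on is unspecified; the value is
recorded in the result metadata), and scores the held-out half. A test
point exactly on the boundary counts as half correct — unbiased, and a
measure-zero event. Sub-dataset scores of a repetition are averaged
with equal weight. Per-repetition seeds are derived deterministically
from one master seed, so runs are reproducible and order-independent.

Controls mirror the original design: a label-shuffle null (labels
permuted across trials before every split; its mean sits at 50%), a
spike-count comparator (the identical pipeline on per-epoch multi-unit
counts, labelled `MUA`), and a reduced-site control keeping
`round(n/3)` sites — evenly spaced along the probe by default, since
the original site selection rule is unstated; a seeded random option
exists.

### Group statistics

Across penetrations the package provides a balanced repeated-measures
ANOVA (penetration as the blocking factor; one- and two-way, standard
error strata, no sphericity correction by default since the original
analysis reports uncorrected degrees of freedom; a Greenhouse–Geisser
option exists), Bonferroni post-hoc comparisons using the pooled
within-subject error term (the original post-hoc variant is unstated;
the pooled term is the textbook default and is documented here), and
the two-sided Wilcoxon matched-pairs test (zeros dropped, exact up to
25 non-zero differences without ties, normal approximation with
continuity correction beyond).

## What the generator emulates — and what it does not

`simulateSession()` produces per-trial multi-site traces as the sum of

1. $1/f$ background noise (spectral shaping of white noise, unit
   variance, amplitude in a.u.),
2. a 50 Hz line component with random phase,
3. per-band band-limited Gaussian oscillations, created by Butterworth
   band-pass filtering white noise — rather than summing sinusoids — so
   that within-band spectra are realistic and the wavelet estimator
   faces honest estimation error.

Oscillation power in band $b$ during an epoch equals the realised
per-site gain of the presented stimulus; in the test epoch it is
multiplied by `repetitionGain[b]` (repetition trials) or
`crossAdaptationGain[b]` (alternation trials). Epoch transitions are
ramped over 20 ms: the 60 ms window onset skips evoked transients
anyway, and ramps avoid synthetic step artifacts. Setting both
adaptation gains to 1 makes adapter and test epochs exchangeable by
construction (and by permutation test).

Per-site heterogeneity has two knobs. `siteGainSD` scales a log-normal
responsiveness factor applied to both stimuli alike; `siteSelectivitySD`
spreads each site's stimulus contrast around the nominal log gain
ratio. The second knob is what makes sites carry *partially independent*
information — which is why decoding degrades when sites are subsampled.
An earlier design that jittered the A and B gains independently was
discarded: it injects artificial selectivity of magnitude
$\sim\sqrt{2}\,\mathrm{sd}$ at every site regardless of the nominal
contrast, and because power-estimator variance falls with frequency it
made gamma bands decode best — the opposite of the target pattern.

Spiking is Poisson per site and epoch with stimulus-specific rates, the
analysis-window duration as the counting window, and a multiplicative
test-epoch adaptation factor in repetition trials.

Default parameters are the study conditions where stated — 16 sites at
100 µm, 1 kHz, 500/500/500 ms timing, 120 unaborted trials per sequence
type (the reported mean was 123.5), ~5% aborts, adaptation confined to
middle/high gamma with near-unity cross-adaptation. The band gain
magnitudes are genuinely free parameters (no quantitative per-band
spectra are published for these stimuli); they were chosen once so that
the *qualitative* pattern matches the findings — highest accuracies in
alpha/beta, lowest in middle gamma, a repetition deficit only at high
frequencies, spike-count decoding comparable to alpha — and are not
revisited. What passing tests show is therefore that the pipeline
recovers planted effects of realistic size and produces exact chance
level under label exchange; they cannot certify biophysical realism
(no compartmental modelling, no laminar depth profile, no eye
movements, no evoked transients).

A subtlety worth knowing when interpreting single-session results: with
a *fixed* finite trial pool, resampled train/test splits share whatever
accidental class difference the realised pool contains, so the
conditional chance level of one session deviates from 50% by a few
percent even with zero generative selectivity. The label-shuffle
control — which re-permutes labels before every split — is the correct
chance reference and centres exactly on 50%.

## Problem sizes used by the test-suite and acceptance runs

These are the package's own validation choices:

* shuffle-null check: one penetration, 16 sites, 90 trials per sequence
  type ($N_\mathrm{tot} \ge 80$, i.e. at least 40 test trials per
  class), 500 permutations in the alpha band; the acceptance script
  uses the full 120-trial, 1000-permutation setting;
* planted-effect recovery: 20 penetrations, 12 sites (within the
  reported 11–16 range), 60 trials per sequence type, 200 classifiers
  per condition, four bands (alpha, beta, middle, high gamma);
* statistical calibration: 1000 null simulations at 32 penetrations —
  the study's penetration count — for both the RM-ANOVA and the
  Wilcoxon test;
* oracle equivalences (SVM vs exact QP enumeration, wavelet band power
  vs periodogram rank order, Wilcoxon vs sign enumeration, ANOVA vs
  hand-computed sums of squares) run at enumeration-friendly sizes.

## A worked micro-example

```{r example, eval = FALSE}
cfg <- simulationConfig(nSites = 6, nTrialsPerSequence = 10,
                        abortProb = 0.05, seed = 3)
ses <- simulateSession(cfg)
res <- decodeSession(ses, nRep = 100, nShuffle = 100, seed = 5)
resultTable(res)

## multi-penetration run with summary and group statistics
run <- runExperiment(cfg, nPenetrations = 4, nRep = 100, seed = 11,
                     outDir = "run-artifacts")
run$summary
run$anova$band_by_condition
```

## Known limitations

* The generator is phenomenological: band-limited Gaussian processes
  with multiplicative epoch gains, not a biophysical LFP model.
* The SVM cost parameter and boundary-tie scoring of the original
  toolbox are unknown; both are fixed, declared choices here (cost 1,
  half credit).
* The RM-ANOVA assumes a balanced design and reports uncorrected
  degrees of freedom by default; unbalanced designs are rejected, not
  approximated.
* Time-resolved decoding, nonlinear kernels, coherence/phase analyses
  and cross-condition transfer are out of scope.
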