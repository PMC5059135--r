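---
title: "Models and methods: simulating and analysing retinal-wave-driven thalamocortical activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavegate)
```

## The scientific problem

Before eye opening, the rodent visual system is driven by spontaneous
retinal waves. In thalamus (LGN) and visual cortex (VC) this drive appears
as long silent periods interrupted by 3–10 s active periods whose
multi-unit firing is rhythmically modulated — the spindle-burst
oscillation, near 16 Hz during cholinergic (stage II) waves at P5-7 and
20–30 Hz during glutamatergic (stage III) waves at P9-11. A central claim
about this circuit is that corticothalamic feedback is transiently
*excitatory*: it multiplies the retinal drive to LGN (contributing roughly
80% of LGN firing), prolongs activity, and — in the second postnatal week —
accelerates and synchronizes the thalamic rhythm, before feed-forward
inhibition matures around eye opening (P13-14) and the feedback becomes net
inhibitory.

`wavegate` packages the analysis chain used to establish such claims
(inter-spike-interval event detection and continuity, spike spectra from
the autocorrelation, multitaper LFP spectra, PSTH metrics, nonparametric
and permutation inference) together with a synthetic-data generator that
emulates the phenomenology, so that every analysis stage can be exercised,
calibrated and regression-tested without any recorded data.

## The spontaneous-activity generator

`generate_wave_recording()` draws an alternating silent/active timeline
(durations uniform within the age profile's ranges) and emits LGN and VC
spikes from an inhomogeneous Poisson process. Within an active period the
rate is

$$r(t) = r_w \,[1 + d \sin(2\pi f t + \varphi)],$$

with $r_w$ the within-wave multi-unit rate (default 100 Hz — multi-unit
counts pooled on one analysis channel), $d$ the modulation depth (default
0.8 before eye opening, 0.2 after, when prominent spindles are lost), $f$
the age's spindle frequency and $\varphi$ random per period. Between waves
the rate is a near-silent 0.1 Hz. Spikes are drawn bin-wise on a 1 ms grid
(equivalent to thinning a piecewise-constant intensity; all analyses run at
a 1 kHz count resolution). Waves are treated as whole active periods;
sub-second within-wave cluster structure is deliberately not modelled, as
none of the tested statistics resolves it.

Age profiles encode the field's reported values: spindle modulation at
16 / 23 Hz (P5-7 / P9-11) with an intrinsic (cortex-independent) LGN
frequency of 16 Hz; corticothalamic volley latencies of 34.2, 21.5 and
20.0 ms; per-pulse reliabilities of about 0.40, 0.85 and 0.92; and
feed-forward inhibition present only at P13-14.

### Silencing manipulations

Manipulations act from their onset and are *structural*, not just
multiplicative, because the phenomena they emulate are structural:

- **Retinal silencing** (and, for the cortical trace, **LGN silencing**)
  removes the wave process itself. Post-onset active periods are replaced
  by sparse, short (0.5–2 s; 0.3–1 s for cortex-only activity),
  *unmodulated* residual bursts whose time fraction is the residual
  fraction of the normal active fraction; baseline firing scales by the
  residual. This reproduces the joint collapse of rate and continuity
  (≈ −90% at residual 0.1), the loss of the long-duration event tail, and
  the disappearance of the spindle spectral peak.
- **Cortical silencing** acts on LGN according to age, encoding the
  developmental switch in feedback function:
  - *P5-7 (amplification only)*: each wave survives with probability
    $0.42 + 0.58r$; survivors are unchanged. Rates and continuity halve
    while event durations and spectra are untouched.
  - *P9-11 (amplification + prolongation + acceleration)*: in-wave rates
    scale by $0.6 + 0.4r$, active durations by $0.25 + 0.75r$, and the
    rhythm reverts to the 16 Hz intrinsic frequency once the residual drops
    below one half. This yields a ≈ −79% rate change, ≈ −68% continuity
    change and the 23 → 16 Hz peak shift.
  - *P13-14 (net inhibition)*: silencing cortex *disinhibits* LGN — rates
    scale by $1 + 0.11(1-r)$ and active durations extend by up to 20%,
    raising rates ≈ +26% and continuity ≈ +14%.

  These multipliers are calibrations to the reported effect sizes, chosen
  once and documented here; they are emulation targets, not measurements.

## The delayed feedback-loop rate model

`simulate_feedback_loop()` is a mechanistic counterpart to the
phenomenological wave generator. With retinal drive $R(t)$, LGN rate $L$
and cortical rate $C$:

$$L(t) = \max\!\big(\text{floor},\; R(t)\,[1 + g_{fb}\,C(t-d_{V\to L})]
  - g_{inh}\,C(t - d_{V\to L} - d_{inh})\big), \qquad
  C(t) = \max(0,\; a\,L(t-d_{L\to V})).$$

Cortical feedback *multiplies* the retinal drive (the two inputs are
synergistic, not additive). The closed loop echoes drive fluctuations at
the round-trip delay $D = d_{L\to V} + d_{V\to L}$, so the rate spectrum
peaks at $1/D$ — 25 Hz for the default 20 ms + 20 ms delays. The default
gain is set so the loop gain $\bar R\, g_{fb}\, a = 0.8$, making the
closed-loop rate five times the open-loop rate, i.e. 80% of LGN drive
comes from feedback — the amplification arithmetic the circuit is claimed
to implement. Subtractive inhibition delayed by one further round trip
(40 ms) arrives in phase and cancels the echo, suppressing the rhythm; the
integration aborts with a diagnostic if the rate exceeds a configurable
ceiling (supra-critical gain). The default drive is exponentially
correlated noise (mean 10 Hz, CV 0.5, τ = 10 ms); its low-pass spectrum is
what makes the fundamental at $1/D$ dominate its harmonic.

## Stimulation generators

`generate_opto_trials()` emits, per 10 ms light pulse, a cortical volley at
3.5 ms and — with the age's Bernoulli reliability — an LGN volley of ~30 ms
at the age's latency (peak 500 Hz, exponential decay; the peak is set high
enough that a real volley emits at least one spike with probability
> 0.99, so reliability estimates are not biased by empty volleys). With
inhibition enabled, LGN is suppressed to a 0.11 residual during 100–250 ms
after each pulse — calibrated to the reported −89.2% window change — and a
train pulse whose volley falls inside an earlier suppression window fails,
which is what defeats 20 Hz entrainment beyond the second pulse at P13-14.

`generate_evoked_trials()` produces the two-phase flash response: a
gamma-modulated (40 Hz) primary component at 30–200 ms and a spindle-band
secondary component at 200–1000 ms, both as raised-cosine envelopes on
pooled multi-unit scales (350 / 450 Hz peaks); in `P13_14` mode the primary
is brief (25–125 ms) and unmodulated and the secondary is reduced to a
small fraction. Flash timestamps follow the 100 ms flash every 30 s
protocol starting at 0 s.

## Spectral pipeline

Spike spectra are the Fourier transform of the biased autocorrelation of
the mean-subtracted 1 ms count series (Blackman–Tukey correlogram). The
autocorrelation runs to 1 s of lag — enough to resolve the 2–55 Hz
analysis band at 0.5 Hz spacing — and is Hann-tapered to suppress
lag-truncation ripple; small negative numerical power is clipped at zero
with a warning when substantial. LFP spectra use Slepian multitapers
(time-bandwidth 3, 5 tapers; computed from the standard symmetric
tridiagonal eigenproblem and cached) over fixed 2 s windows (0.3 s for
evoked responses), averaged across windows.

The processing order is the conventional one: multiply power by frequency
(1/f compensation), resample onto a 60-point geometric 2–100 Hz grid
(linear interpolation in log-frequency), then divide by the mean 2–55 Hz
power so the in-band mean is exactly 1. Peak extraction takes the in-band
argmax, ties to the lower frequency, and flags peaks under 1.5 times the
in-band median as low-confidence.

Two consequences of compensation are worth knowing. A flat (Poisson-null)
count spectrum is *tilted up* by compensation — by construction, since
power is multiplied by $f$ — so null-flatness checks run on uncompensated
spectra, and the argmax of a compensated spectrum without a real rhythm
drifts toward the top of the search band (such peaks carry the
low-confidence flag). For 0.3 s evoked count windows the spectrum has no
appreciable 1/f trend, so `evoked_spectrum()` skips compensation by
default; it also subtracts the trial-averaged transient per window tile
(isolating induced oscillatory power from the broadband response envelope)
and applies no Gaussian rate smoothing, which would attenuate the gamma
band several-fold more than the spindle band.

## PSTH metrics

PSTHs are trial-aligned counts over 1 ms bins divided by trial count and
bin width. Onset latency is the first post-stimulus bin at which the
lightly smoothed PSTH (Gaussian, sd 0.5 ms) exceeds baseline mean + 3 SD
for 3 consecutive bins, reported at the bin centre; the narrow kernel is
deliberate — wider smoothing advances the apparent onset of a sharp volley
by about its own width, which would exceed the ±2 ms recovery the
estimator is held to. Onsets are computed on the population PSTH (the
per-trial alternative is noisier at neonatal rates). Reliability is the
fraction of cortex-responding trials (≥1 VC spike within 30 ms) with an
LGN spike in the 1–100 ms excitation window; window changes are percent
changes of mean PSTH rate versus the pre-stimulus baseline. Entrainment of
a pulse train requires the train-aligned PSTH spectrum to peak within one
bin of the train frequency *and* the mean response probability at pulses
3..n to stay at least half that of pulse 1.

## Statistics

Paired comparisons use the exact Wilcoxon signed-rank distribution in the
small-n regime (n < 10 animals): untied data through the standard exact
distribution, tied absolute differences through exhaustive enumeration of
the $2^n$ sign assignments of the midranks. Six uniformly signed
differences give the familiar two-sided p = 0.03125. Event-duration
distributions are compared with the two-sample KS test plus
Dvoretzky–Kiefer–Wolfowitz 95% bands around each empirical CDF.

Frequency-wise spectral comparisons use a sign-flip permutation test on
paired, log-resampled, normalized spectra with *pixel-based max-statistic*
familywise correction: the per-frequency statistic is the mean paired
difference, the null is built from sign-flips of each animal's difference
spectrum (exhaustive — all $2^n$ — for n ≤ 12, seeded Monte Carlo
otherwise), and the corrected threshold is the 0.95 quantile of the null
maximum |statistic| across frequencies. The pixel-based variant is the
default because results are reported as contiguous significant frequency
ranges, which the pixel mask yields directly; a cluster-mass variant is
available behind `correction = "cluster"`. Permutation is at the animal
level — the conservative unit for n = 6 reporting; permuting spectral
windows within animals would be the anticonservative alternative.
Between-condition designs with independent groups can reuse the same
max-statistic machinery with label shuffles, which the sign-flip code path
mirrors.

## Problem sizes and numerical choices

The default experiment simulates 6 animals × 2 conditions × 1200 s at 1 ms
resolution — the 20 min before / 20 min after design — and completes in
well under 15 minutes on one CPU. Calibration studies in the test-suite use
60–100 s oscillatory trains (100 s where peak-recovery precision matters,
60 s for familywise-error replicates, of which 500 are run), 100–200
stimulation trials, and 60 s loop integrations. Per-animal seeds derive
from the master seed by fixed offsets, so enlarging a cohort never
perturbs existing animals; every generator draws from a single seeded
stream and identical configurations are byte-reproducible.

Degenerate inputs are handled explicitly rather than silently: all-zero
count series yield a flagged empty spectrum; zero-variance baselines flag
onset latencies as low-confidence; zero denominators (percent change,
normalization, baseline rates) are errors; channel selection returns an
explicit no-selection result when no channel qualifies.

## What the generator does and does not emulate

Passing tests show that the analysis chain recovers the parameters of the
generating process — event structure, active fractions, modulation
frequencies, latencies, reliabilities, suppression windows — at realistic
problem sizes, and that the inference layer is calibrated (familywise
error ≤ 5%, exact small-n p-values). They do not show that the generator
is a faithful model of in vivo recordings: it has no electrode drift,
movement artifacts, spike-sorting ambiguity, non-Poisson firing
(refractoriness, bursting), retinotopy or eye-specific structure, no
biophysical neurons, and no within-wave cluster substructure. The
P5-7 optogenetic mode does not model the temporal dispersion of the
immature corticothalamic volley, so rhythmic 20 Hz stimulation entrains
the simulated P5-7 LGN even though the real circuit at that age does not
follow; the entrainment contrast carried by the model is the
inhibition-based loss at P13-14. Silencing calibrations are emulation
targets taken from reported effect sizes, so experiments that *measure*
those same effect sizes on synthetic data are consistency checks of the
pipeline, not independent evidence about the biology.
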