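---
title: "Measuring heart-sound component timing from paired ECG/PCG recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring heart-sound component timing from paired ECG/PCG recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgseg)
```

## The measurement problem

Each of the two main heart sounds is produced by two valve closures a few
tens of milliseconds apart: mitral then tricuspid for S1, aortic then
pulmonary for S2. The delay of each component from the R-peak of a
simultaneously recorded ECG, and the intra-sound splits, carry information
about electromechanical coupling, ventricular inotropy and right/left
coordination — but they require 1-ms-scale resolution, which neither
auscultation nor echocardiography provides. `pcgseg` implements an
operator-independent pipeline that detects S1 and S2 on a phonocardiogram,
resolves each into its two components, and reports six per-beat timing
parameters (R–S1M, R–S1T, S1 split, R–S2A, R–S2P, S2 split) at the
sampling resolution (1 ms at the nominal 1 kHz).

This vignette explains the model and its assumptions, every tunable
constant, the synthetic validation design, and the numerical choices made
where the procedure leaves room.

## Signal model and assumptions

The pipeline assumes:

* paired single-channel ECG and PCG sampled simultaneously at `fs` (all
  rule constants are expressed in physical units but were designed at
  1 kHz; the package never resamples silently);
* a dominant positive R-wave in the ECG (true of a lead-I-style montage);
* heart-sound energy concentrated in 20–100 Hz, murmurs in 200–600 Hz;
* sinus rhythm with occasional ectopy at most (the method's time
  thresholds are fractions of the mean RR interval).

## Processing stages and their constants

**ECG band-pass (10–35 Hz).** Two cascaded order-250 Hamming-window FIR
stages (high-pass 10 Hz, low-pass 35 Hz) isolate QRS energy. Each
linear-phase stage delays 125 samples, so the cascade delay is exactly 250
samples; `align_signals()` removes it by dropping the first 250 ECG samples
and the last 250 PCG samples. A note on the attainable band: with 251 taps
at 1 kHz the transition width is ~13 Hz, so the response is flat (<1 dB
ripple) over roughly 15–30 Hz and is already ~3 dB down at the nominal
cutoffs themselves — the cutoffs are −6 dB points, as is conventional for
windowed designs. What matters downstream is preserved QRS energy (≥0.9
amplitude at 25 Hz) and strong rejection of baseline drift (≥40 dB below
1 Hz) and mains interference (≥20 dB at 50 Hz); all hold.

**R-peak detection.** A Pan-Tompkins chain: zero-lag five-point derivative,
point-wise squaring, and a centred 150-ms moving-average integration (the
length matches the typical QRS duration). Pulses are accepted by adaptive
double thresholding — running signal and noise level estimates with
threshold `noise + 0.25 (signal − noise)`, levels initialized from the
first 2 s — with a 200-ms refractory period and a search-back pass at
1.66× the running mean RR using half the threshold. Each accepted pulse is
relocated to the ECG maximum within ±75 ms, which places the index on the
R apex. The classical decision rules are kept verbatim because the chain's
published behaviour (including its insensitivity to low-frequency ectopic
morphology) is exactly what the segmentation relies on: premature
ventricular contractions are wide, low-frequency deflections, are strongly
attenuated by the 10–35 Hz band-pass, and are deliberately *not* detected,
so their (typically silent) cycles contribute no sounds.

**PCG band-pass (20–100 Hz).** An order-5 Chebyshev type-I filter with
0.5 dB pass-band ripple ("Chebyshev" unqualified conventionally means
type I; the small ripple limits in-band distortion). Because an IIR filter
distorts phase, it is applied forward and backward, giving an exactly zero
net phase response: a symmetric burst keeps its peak sample, which the
timing measurements require. Edge handling: the record is extended by
odd-symmetric mirror images (up to 2 s per side) before the two passes.
The narrow-band recursion rings for over a second, so the short padding
conventional for forward-backward filtering would let edge transients
reach the retained samples; 2 s brings them below recursion precision
(~1e−6 relative, the accuracy limit of a direct-form order-5 recursion in
double precision — the zero-phase and linearity properties are tested at
that level).

**Shannon-energy envelope.** The second-order Shannon energy
`ES(i) = −(1/N) Σ x² log x²` over a moving window of `N = 20` samples
(20 ms, the typical duration of a single valve component), advanced one
sample at a time so the envelope keeps the signal's 1-ms resolution. The
input is first normalized to `max |x| = 1`; the transform then emphasizes
medium-intensity oscillations over both low-level noise and isolated
high-amplitude samples, and is exactly invariant to polarity and to any
global amplitude scale. Conventions chosen here: natural logarithm (the
base only rescales the envelope and is absorbed by the subsequent
normalization — a test asserts detections are base-invariant);
`0·log 0 := 0`; windows are centred and shrink to the valid part at the
record edges rather than fabricating samples. Higher-order variants give
smoother envelopes but blur exactly the intra-sound structure this package
exists to measure, so they are not offered.

**Moving normalization.** At each sample the envelope is z-scored against
a 1-s sliding window (mean subtracted, divided by the standard deviation),
and negative values are clamped to zero. This equalizes slow
signal-quality drift so that a single global amplitude threshold works for
the whole record. A 2-s window is a valid alternative at very low heart
rates; on clean records the detected component times are unaffected at the
millisecond level (tested: all six mean parameters move <1 ms, ≥95% of
individual component times move ≤1 ms). Stretches where the windowed
standard deviation is zero are genuinely signal-free and map to zero.

**Detection and classification rules.** All constants are fractions of
either the global envelope maximum or the mean RR interval, so the
procedure adapts to heart rate without per-subject tuning:

| constant | default | meaning |
|---|---|---|
| `amp_frac` | 0.05 | amplitude threshold, fraction of envelope max |
| `join_frac` | 0.10 | join segments closer than this fraction of mean RR |
| `fp_frac` | 0.20 | pair pruning bound (fraction of mean RR) |
| `fp_frac2` | 0.40 | triple pruning bound (fraction of mean RR) |
| `s1_pre_ms` | 50 ms | S1 window extension before the R-peak |
| `s1_rr_frac` | 0.18 | S1/S2 boundary as a fraction of the beat RR |
| `se_window_n` | 20 | Shannon-energy window (samples) |
| `norm_window_s` | 1 s | normalization window |
| `prominence_frac` | 0.02 | minimum component-lobe prominence |

Segments are maximal runs above the amplitude threshold, joined across
sub-threshold gaps shorter than 10% of the mean RR (so an intercomponent
dip cannot break one sound in two). Within a segment, the split is the
deepest envelope minimum **between the segment's two dominant lobes**, and
the component peaks are the envelope maxima on either side of it.
False-positive pruning then removes, iteratively until stable, the
lower-envelope member of any pair of first components closer than 20% of
the mean RR, and the lowest member of any triple whose consecutive gaps
are both under 40%. Finally each surviving candidate is referred to its
R-peak (the nearest preceding one, or the following one when the candidate
leads it by ≤50 ms): first components between 50 ms before the R-peak and
18% of the beat's RR after it make an S1 (mitral, tricuspid), later ones
before the next beat's S1 window make an S2 (aortic, pulmonary). At most
one S1 and one S2 survive per cycle (largest first-component envelope
wins); everything else is discarded with a logged reason. Classification
windows are closed at both ends; at the exact 18% boundary a candidate is
an S1. Ties in any argmax/argmin go to the earliest index, making the
whole pipeline bit-for-bit deterministic.

### Numerical design of the split search

Two refinements make the "deepest minimum" rule robust, and they are the
package's main numerical design decision. A literal deepest-interior-
minimum search fails on any realistic envelope: the envelope is *low* on
the segment flanks, so any micro-oscillation there — numerical ripple,
residual carrier harmonics, noise — produces a "minimum" that is deeper
than the true inter-component valley, which sits high between two lobes.
Therefore (a) a local maximum only counts as a component lobe if the
envelope rises and falls around it by at least 2% of the segment maximum
(`prominence_frac`, implemented as a hysteresis scan); and (b) the second
lobe must lie at least half the integration window (10 ms at defaults)
from the dominant one — two peaks closer than that are below the moving
window's resolution and indistinguishable from window ripple. The split is
then the deepest sample between the two largest qualifying lobes. A
segment with fewer than two qualifying lobes is a *degenerate* sound: it
is kept for detection and classification (discarding it would throw away a
real heart sound) but it contributes no timing parameters, because its
single apex locates the merged sound rather than either valve component.

## The six parameters and their summaries

`beat_timings()` reports, per beat, each labeled component's delay from
its R-peak and the two splits; `r_s1m` may be negative because the S1
window starts before the R-peak. `summarize_timings()` gives mean, SD,
median, IQR and the central 95% range per parameter; the 95% range uses
empirical 2.5/97.5 percentiles rather than a Gaussian ±1.96σ so no
distributional assumption is made. With ~600 beats (a 10-minute
recording), the 95% confidence interval of each mean delay is under 2 ms
wide, so 2-ms changes between sessions are resolvable.

`compute_snr()` estimates recording quality as
`20 log10(AS / 4σN)`: `AS` is the peak-to-peak amplitude of the
R-synchronous ensemble-average waveform over one mean cycle (beats whose
full cycle does not fit are excluded), and `σN` pools the beat-aligned
samples in the 70–85% portion of the cycle — late diastole, where no sound
is expected — so `4σN` spans the 95% band of Gaussian noise. Pooling the
samples (rather than averaging per-beat SDs) uses the most data and is the
stabler estimator. A perfectly silent window returns `Inf` with a warning.

`detection_scores()` defines S1 sensitivity as the percentage of detected
R-peaks whose beat carries a classified S1 (likewise S2; overall is the
mean of the two) — the denominator is *detected* beats, mirroring how such
pipelines are validated when every beat is known to be found. With
synthetic ground truth, a sound only counts if each resolved component is
within ±10 ms of its true time (half the 20-ms component window); a
degenerate sound's apex must be within ±10 ms of the nearer true
component. Specificity is the percentage of detected sounds matching a
true sound under the same gate.

## What the synthetic generator emulates — and what it does not

No public data accompany the method, so validation runs on synthetic
records with exact ground truth. `generate_recording()` produces:

* an ECG as a P-QRS-T train of Gaussian deflections at a jittered RR
  interval (only the R location matters to the pipeline);
* a PCG with four Gaussian-windowed cosine bursts per beat at programmable
  delays from the R-peak, plus white noise band-limited to the acquisition
  bandwidth (DC–262 Hz);
* optional systolic murmurs (200–450 Hz band-passed noise, Hann-windowed
  between S1 and S2 — the upper edge of the physiological 200–600 Hz
  murmur band is folded to what 1 kHz sampling can represent);
* optional PVCs: a 150-ms low-frequency biphasic wave replacing a normal
  beat, with no heart sounds.

Key defaults and why:

* **Component delays** `(43.9, 76.0, 371.3, 399.4)` ms — the means of the
  bundled 24-subject healthy-adult table (`healthy_cohort_table()`), which
  spans heart rates 55–87 bpm, S1 splits 13.5–63.6 ms and S2 splits
  10.3–60.3 ms.
* **Beat-to-beat timing jitter** `(4, 6, 5, 8)` ms SD — physiological
  mechanical variability. The table's per-subject SD columns are larger,
  but they include the measurement spread of envelope-based detection
  itself; using them as true mechanical jitter would double-count that
  error (and would destroy the ensemble-average waveform that the SNR
  definition relies on).
* **Burst carrier 60 Hz, duration 30 ms** (Gaussian ±3σ). These sit
  mid-range of the heart-sound band and of the 20–60 ms component-duration
  range, and they keep ≥90% of burst energy inside 20–100 Hz. Shorter
  bursts are too wideband and ring through the order-5 Chebyshev; longer
  bursts merge at physiological splits once convolved with the 20-ms
  envelope window. A pure fixed-frequency cosine is already the
  generator's least realistic feature (see below), and these values avoid
  degenerate carrier-coherence interactions between the two bursts of one
  sound.
* **Amplitudes** `(1.0, 0.85, 0.9, 0.75)` relative — first components
  slightly stronger, S1 slightly stronger than S2; amplitudes are constant
  across beats (respiration-modulated dynamics are out of scope).
* **Noise** — `noise_std = 0.05` by default (ensemble SNR ≈ 25 dB);
  `noise_for_snr()` inverts the SNR definition numerically (ensemble
  amplitude measured on a noiseless calibration run; noise gain from the
  filter cascade's impulse response) so cohorts can be programmed to a
  target SNR within ~1 dB.
* Records start 0.5 s in, contain only complete cardiac cycles, and end
  with a 0.3-s sound-free run-out so delay compensation cannot truncate
  the final cycle.

**What passing synthetic tests does and does not show.** The generator
exercises the pipeline's logic — co-registration, adaptive thresholds,
split resolution, classification windows, pruning, PVC and murmur
rejection — under controlled truth. It does not reproduce real components'
broadband, decaying, mutually incoherent morphology: a deterministic
cosine burst interacts with the 20-ms window through its harmonics in ways
real sounds do not (both more benignly and more maliciously, depending on
carrier and split). Nor does it model amplitude modulation by respiration,
electrode/contact artifacts, S3/S4, or pathological murmurs. Sensitivity
figures on this cohort therefore validate the algorithmic machinery, not
clinical performance on real patients.

An intrinsic limitation the synthetic truth makes visible: when two bursts
overlap (true split below about the burst duration), their envelope lobes
pull toward each other, biasing each component time by up to ~8 ms even
without noise. Per-beat component accuracy of ±3 ms holds for
disjoint-burst beats; *mean* delays are recovered within well under 1 ms
regardless, because the pull is symmetric in the jitter. This mirrors the
behaviour expected of any envelope-based method at small splits — per-beat
split estimates scatter, means remain stable.

## Validation cohort

The acceptance surface (`scripts/acceptance.R`, mirrored by the
test suite) generates 24 records of 10 minutes at 1 kHz, one per row of
the bundled table: heart rate and the four component-delay means from the
table, noise calibrated to the subject's tabulated SNR floored at 13 dB,
per-record seeds derived from one master seed. Each record is segmented
and scored against ground truth with the ±10-ms gate; the mean overall,
S1 and S2 sensitivities across the 24 records are reported. Problem sizes:
~15,000 beats across the cohort; the run takes a few minutes on one CPU.
Unit and property tests run on 20–120 s records (hundreds of beats), with
one 600-s record for the confidence-interval property.

## Known limitations

* The R-peak detector assumes a positive R apex; inverted-lead recordings
  need their ECG negated on input.
* All rule constants presume 1 kHz sampling semantics; other rates are
  accepted but untested territory.
* Sounds whose split is below the 10-ms envelope resolution are reported
  as degenerate (detected, classified, no component timing) rather than
  force-resolved.
* The specificity definition requires ground truth and is therefore only
  computable on synthetic records.
* Real-data performance claims are outside what the synthetic cohort can
  establish.
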