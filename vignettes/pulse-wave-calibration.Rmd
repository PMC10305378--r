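---
title: "Methods: simulating a pulse-wave bench and calibrating a cuffless BP monitor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating a pulse-wave bench and calibrating a cuffless BP monitor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwsim)
```

## The system being modelled

A bench simulator for cuffless blood-pressure monitors consists of an
elastic tube (the arterial phantom) embedded in an arm model, a pulsatile
electric pump playing the heart, a pressurised water reservoir setting the
base (diastolic) pressure, and a reference pressure sensor. The device
under test (DUT) straps onto the arm model and times the pressure pulse at
two sensors `L = 4` cm apart: the pulse transit time (PTT) between the
first peaks seen by the two sensors gives the local pulse wave velocity,
`PWV = L / PTT`.

`pwsim` replaces every physical element with a quantitative model so the
full verification workflow runs in software. This vignette records the
model, its assumptions, the parameters that matter, and the numerical and
design choices behind the implementation.

## Hemodynamic core

The wave speed in a thin-walled elastic tube follows the Moens–Korteweg
(MK) relation `PWV = sqrt(E h / (D ρ))` with an exponentially
pressure-dependent wall modulus `E(P) = E0 exp(γ P)`. Defaults are a
silicone-rubber radial-artery phantom: `D = 4` mm, `h = 1` mm, water
(`ρ = 1000` kg/m³; 1060 for whole blood), and brachial-artery literature
values `E0 = 1428.7`, `γ = 0.031`.

**Units.** The modulus parameters are routinely quoted without units.
This package fixes the convention: `E0` in pascals, `γ` per mmHg with `P`
in mmHg inside the exponential, and all other quantities converted to SI
internally (1 mmHg = 133.322 Pa). Under this convention the default tube
gives PWV ≈ 2.8–9.7 m/s over 100–180 mmHg, inside the physiological band a
radial-artery DUT must handle, which is the reason this reading was
adopted. All conversions live in one internal layer; every exported
function documents its interface units (mmHg, cm, ms, m/s).

The Bramwell–Hill form `PWV = sqrt(V ΔP / (ρ ΔV))` is provided as an
independent route to the same speed; a test checks that a volume increment
constructed from the MK compliance reproduces the MK speed to 1e-6 in the
small-increment limit. The inverse map
`P = (1/γ) ln(pwv² D ρ / (E0 h))` and the error propagation
`ΔP = (2/γ) ln(1 + ΔPWV/PWV)` are exposed because reporting
blood-pressure error bands requires them; the inversion round-trips to
1e-9 relative over 0–300 mmHg. Negative pressures are accepted by the
modulus law (it is mathematically defined there) but rejected by
simulator-level validation.

**Reference pressure.** The bench's reference MAP is defined as the
windowed root-mean-square of the pressure-sensor trace (1 s windows), not
the `SBP/3 + 2 DBP/3` formula. Both are implemented; the RMS convention is
what the calibration uses, because that is what the physical reference
sensor reports.

## Waveform synthesis

No closed form is published for the phantom's beat shape, so the package
uses a three-phase template chosen to reproduce the qualitative morphology
of an invasive arterial trace while giving the detector a unique steep
upstroke: a raised-cosine upstroke from DBP to SBP over the first 40% of
the systolic phase, a cosine decay to a shoulder at `DBP + 0.3 PP`, and an
exponential relaxation to DBP (time constant one sixth of diastole, so the
trace lands on DBP to within 0.3% of PP). The systolic phase occupies
`systolic_fraction = 0.35` of the beat.

The pump's PWM duty cycle maps to pulse pressure affinely with a dead
zone, `PP = pp_per_duty · max(0, duty − duty_min)` with defaults
`pp_per_duty = 125` mmHg and `duty_min = 0.1`; DBP stays at the base
pressure, so SBP and MAP rise monotonically with duty. This calibration
was chosen once so that duty 0.26–0.90 over an 80 mmHg base spans SBP
100–180 mmHg — the standard validation range — and is *not* an empirical
pump curve; users with a measured duty–PP table can supply their own
setpoints.

**Reflection.** The pulse reflects at the distal tube turn with its
transverse displacement reversed. The model adds a delayed, scaled,
inverted copy of the pulsatile component, amplitude ratio 0.3 by default,
with the delay derived as the round trip from the sensing site to the turn
(2 cm away) at the MK speed of the operating pressure. The ratio must stay
below 1: the detector's rejection of the reflected peak relies on its
gradient being smaller than the primary upstroke's.

**Beat timing.** The physical pump is strictly periodic, so beat-period
jitter is off by default; seeded Gaussian jitter is available behind a
flag. A window of `duration` seconds contains
`floor(duration · heart_rate / 60)` complete beats — 75 beats for the
protocol's 60 s at 75 bpm.

## Acquisition chain

Each channel passes the DUT's analog front end (0.6–10.6 Hz band-pass),
receives independent white Gaussian noise at the sampling stage — where
sensor and ADC noise enters the real device — and then passes the digital
FIR band-pass (0.7–9.5 Hz) at the 5 kHz sampling rate.

**Filter design.** Both stages are Hamming windowed-sinc linear-phase FIRs
applied with exactly zero phase, so identical filtering of the two
channels preserves their relative delay. A sub-hertz cutoff at 5 kHz
demands a long filter: the default 16385 taps gives a ~1 Hz transition,
placing DC ≥ 53 dB down while passing the 1.25 Hz pulse fundamental within
0.3%. (A much shorter filter — say ~1000 taps — has a ~16 Hz transition
and cannot separate DC from the pass-band at all.) Filtering is performed
circularly in the frequency domain with the FIR's exact zero-phase
response; for the periodic beat trains the simulator produces, periodic
extension is the natural boundary treatment and costs no edge beats.
Measurement windows are therefore taken to contain a whole number of
beats, as the bench protocol's 60 s at 75 bpm does; on ragged windows the
first and last beats carry wrap artifacts. For traces shorter than the
filter, the FIR is redesigned at the largest odd length that fits.

**Inter-sensor delay.** The distal channel is the proximal trace delayed
by `L / PWV` using windowed-sinc band-limited interpolation (±40 taps,
Hann window), exact to ~1e-4 of the signal amplitude for the ≤10 Hz
content in play. The ground-truth delay is carried through the record so
estimator accuracy can always be audited.

## Transit-time estimation

The DUT's detector exploits one discriminator: the reflected peak's
gradient is smaller than the primary upstroke's. Candidate beats are
rising crossings of the smoothed derivative (15 ms moving average) over an
adaptive threshold — half the trace's maximum upstroke gradient — with a
refractory period of 60% of the expected beat; the peak is the first local
maximum after the crossing. Sub-sample refinement fits a least-squares
parabola over ±6% of the beat period around the discrete maximum. The
wide fit window suppresses in-band noise jitter, and the template bias it
introduces is identical on both identically filtered channels, so it
cancels in the transit time. Refinement can be disabled to evaluate the
raw one-sample timing resolution (0.2 ms at 5 kHz); the noiseless
end-to-end pipeline recovers known delays within one sample across
PWV 1–12 m/s either way.

Proximal and distal peaks are paired nearest-subsequent within a
`max_ptt = 60` ms gate (L = 4 cm at PWV ≥ 0.67 m/s); unpaired beats are
flagged `rejected`, never dropped silently, and beats running off the
window edge are discarded. Degenerate inputs return defined results: a
constant trace yields no peaks, a setpoint with zero accepted beats is an
error naming the setpoint.

## Calibration and agreement

The calibration model is ordinary least squares for
`c = β0 + β1 P_ref + β2 PWV_ref`, fitted by default on the nine
per-setpoint medians (the granularity at which box-plot summaries and
Bland–Altman comparisons are made; a flag fits on all beats instead).
The target is the theoretical MK speed at the measured RMS reference
pressure. Rank-deficient designs (constant pressure or constant PWV
across setpoints) are an error naming the collinear column.

The digital twin ties the phantom's propagation speed to the same RMS
reference-pressure convention the reference sensor uses, which keeps the
twin self-consistent: an unbiased DUT measures the theoretical curve, and
the experiment isolates exactly the distortion injected by the DUT bias
model. That bias model is affine with Gaussian per-beat noise
(`pwv_meas = a·pwv + b + N(0, sd)`) — the simplest family the MLR can
correct exactly, and sufficient to reproduce a near-constant measured
bias.

Agreement is summarised by the mean absolute error and a Bland–Altman
analysis using the sample standard deviation (n−1) and 1.96·sd limits of
agreement (the exact Gaussian 95% convention, rather than the rounded
factor 2), with pairwise means on the x-axis. Each stage's MAE is
propagated through the inverse MK curve into a blood-pressure error band
evaluated at both ends of the 100–180 mmHg range; the band is always
wider at the low-pressure end, where the PWV–pressure curve is flatter.
Published bench studies report device-specific error bands obtained with
particular hardware and unstated unit conventions; the bands this package
prints are model-derived from its own measured PWV errors and are reported
alongside, not equated with, any such figures. Similarly, PWV spreads
quoted in pressure units in parts of that literature are treated as m/s
(the dimensionally consistent reading) wherever a comparison is made.

## Reproducibility and problem sizes

A single master seed drives named substreams (waveform jitter, channel
noise, DUT bias noise) via a deterministic derivation, so every component
is independently reproducible and a fixed configuration plus seed yields
byte-identical trace CSVs and report JSON. Exported files carry
provenance: a config hash, the seed and the package version.

The test suite exercises the full protocol sizes where the guarantee is
about the protocol — 60 s windows at 75 bpm and 5 kHz (75 beats), nine
setpoints, the PWV 1–12 m/s sweep — and smaller whole-beat windows
(8–10 beats at 0.5–1 kHz) where the property under test is scale-free,
such as filter linearity, pairing logic or OLS recovery. The end-to-end
experiment with full protocol sizes runs in seconds.

## What the generator does and does not emulate

The synthesis reproduces the features the estimator and calibration
depend on: a steep unique systolic upstroke, SBP/DBP extremes at the
setpoint values, monotone duty–pressure–PWV relations, an inverted
lower-gradient reflection, band-limited acquisition at 5 kHz, and
white sensor noise. It does not emulate viscoelastic or nonlinear wall
behaviour beyond the exponential modulus, fluid–structure interaction,
Windkessel afterload, hydrostatic elevation, transducer dynamics
(the piezo response is modelled as identity on the pulsatile component),
ADC quantization, clock skew between channels, or arrhythmic and
artifact-laden beats. Passing tests therefore demonstrate the soundness
of the measurement and calibration *procedure* under clean bench physics,
not device performance on real tissue: real phantoms deviate from the MK
curve (that deviation is precisely why the regression calibration exists),
and real devices add noise sources this model idealises away.

## Known limitations

* The beat template and duty→PP map are package calibrations, not fitted
  to any measured pump; absolute PWV values track the MK curve only as
  well as `E0` and `γ` describe the actual tube.
* Circular filtering assumes whole-beat windows; ragged windows distort
  the outermost beats.
* The calibration corrects affine DUT distortions; a strongly nonlinear
  device response would leave structured residuals (visible in the
  Bland–Altman table) that the three-parameter model cannot remove.
* At very low PWV (< 1 m/s) the transit delay approaches the beat
  upstroke duration and first-peak pairing degrades; the `max_ptt` gate
  bounds, but does not eliminate, mispairing there.
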