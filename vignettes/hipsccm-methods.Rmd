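---
title: "Modelling hiPSC-cardiomyocyte electrophysiology and calcium handling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hiPSC-cardiomyocyte electrophysiology and calcium handling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`hipsccm` implements a whole-cell ordinary-differential-equation model of the
spontaneously beating, ventricular-like human induced pluripotent stem
cell-derived cardiomyocyte (hiPSC-CM). The membrane carries the current set
standard for this model family — I~Na~, I~NaL~, I~CaL~, I~f~, I~to~, I~Kr~,
I~Ks~, I~K1~, the Na^+^/K^+^ pump, the Na^+^/Ca^2+^ exchanger (NCX), the
sarcolemmal Ca^2+^ pump and two background currents — over a two-compartment
Ca^2+^ system (cytosol and sarcoplasmic reticulum, SR) with SERCA uptake, a
passive leak and ryanodine-receptor (RyR) release. Intracellular K^+^ is held
constant; Na^+^ and Ca^2+^ are tracked. The state vector has 23 slots: 22
dynamical states plus one frozen legacy slot retained so the layout matches
the published 23-variable ordering of the model family (the superseded
SR-release inactivation gate).

The distinguishing piece is the SR release flux

$$ I_{rel} = I_{rel,max}\; RyR_{CaSR}\; RyR_o\; RyR_c\; (Ca_{SR} - Ca_i), $$

with a luminal modulation factor
$RyR_{CaSR} = 1 - \left(1 + e^{(Ca_{SR}-0.3)/0.1}\right)^{-1}$ and three
gates driven by cytosolic Ca^2+^: an adaptation gate $RyR_a$ (a
concentration-valued working point with a 1 s time constant), an activation
gate $RyR_o$ and an inactivation gate $RyR_c$ whose sigmoid midpoints ride on
$RyR_a$. Because release is triggered by cytosolic Ca^2+^ rather than by the
L-type-channel gating, the model can release Ca^2+^ from a repolarized
membrane — the mechanism behind delayed afterdepolarizations (DADs), which
the predecessor formulation could not produce.

Units are SI throughout the solver (volts, seconds, millimolar); biomarker
reporting converts to mV and ms. One deliberate deviation from a
divide-by-1000 storage convention: the RyR half-activations, adaptation
constants and slopes are stored in the micromolar units in which they are
conventionally printed, and the right-hand side compares them against
$1000 \cdot Ca_i$. The two conventions are numerically identical; storing
the printed decimals keeps the config round-trip exact.

## Constants not in the primary reference table

The RyR gate slopes and time constants are not printed in the main reference
table; they derive from the human-atrial three-gate formulation that this
release model follows, with all Ca^2+^-axis constants rescaled to 1/10 to
match this model's much lower cytosolic Ca^2+^ range (diastolic
$\approx 0.02\ \mu M$). We use slopes of 0.0082, 0.003 and 0.002 µM for the
adaptation, open and closed gates and time constants of 1 s, 18.75 ms and
87.5 ms, with direction-dependent factors (deactivation of the open gate 10×
faster than activation; recovery of the closed gate 2× slower than
inactivation). Two choices were resolved by validation rather than
transcription, since the source prints neither:

* the closed-gate slope/half pair. Assigning 0.002 µM to the slope (and
  0.001 µM to the baseline half-activation seed) reproduces the Ca^2+^
  overload time course — DAD-like events developing within tens of seconds
  of the hypercalcemic switch — whereas the swapped assignment delays them
  about twofold, while leaving all 14 steady-state biomarkers essentially
  unchanged. It also places the calibrated half-activation (0.00144 µM) on
  the plausible side of its seed.
* the direction of the asymmetric time-constant factors. The alternative
  assignments distort the Ca^2+^-transient rise times by 10–40% and abolish
  the overload DADs; the chosen one reproduces rise and decay times within
  a few percent.

## Parameter sets and calibration

Two parameter sets ship as YAML configs: `paci2013-baseline` (the
pre-calibration values, with the RyR seeds at 1/10 of their atrial source
values) and `paci2018-optimized` (the calibrated values). The calibration
procedure is a weighted, SD-banded cost over 8 action-potential and 6
Ca^2+^-transient biomarkers: each biomarker contributes
$w_i(|b_{exp} - b_{sim}| - SD_i)/SD_i$ when outside its experimental
mean ± SD band and zero inside, with weight 2 for the maximum diastolic
potential and the cycle length and 1 otherwise. The driver is Nelder-Mead.
Because the simplex is unconstrained, the package optimizes in a
per-parameter sigmoid coordinate mapping the real line onto
[0.8, 1.2] × baseline (a penalty-mode alternative is provided); this is a
design choice of this package — the original procedure does not state how
its ±20% constraint was enforced. The optimum is a *region* of zero cost,
not a point: success is "terminal cost 0 inside the bounds", not recovery of
any particular published values.

Each objective evaluation settles the limit cycle for 300 s from the
packaged steady state (150 s in the test suite) before a 20 s analysis
window, with a cycle-length drift check; simulating 800 s from scratch per
evaluation would cost an order of magnitude more for no measurable change in
the biomarkers.

A caveat found during validation and worth stating plainly: the reference
simulated APD~30~ (241.8 ms) lies *outside* its own experimental band
(180 ± 58.6 ms), so the printed optimum scores a small positive cost
(≈ 0.055) under the printed cost definition, and our reconstruction scores
≈ 0.28 there. The claim that the calibrated model satisfies every band is
therefore not exactly attainable for APD~30~-like shapes; the calibration
test asserts it regardless, and its outcome documents this tension rather
than hiding it.

## Biomarker conventions

The reference does not define every measurement operationally; the package
fixes, and exposes as arguments, the following conventions:

* AP durations are measured from the maximum-upstroke-velocity instant to
  the crossing of x% repolarization on the peak-to-MDP span, linearly
  interpolated; CL is the interval between successive max-dV/dt instants;
  APA uses the following MDP.
* Ca^2+^-transient amplitudes are measured from the preceding diastolic
  minimum to the peak; DURATION is the span between the 10%-amplitude up-
  and down-crossings; TPEAK runs from the 10% up-crossing to the peak.
  All six transient biomarkers are amplitude-relative and hence well defined
  on un-calibrated fluorescence signals.
* DADs: a diastolic local maximum at least 1 mV above the resumed diastolic
  course, below the AP threshold (−20 mV with dV/dt ≥ 5 V/s); depolarizations
  crossing the threshold without a fast upstroke, and full APs arriving at
  less than 75% of the median cycle length, are classified triggered events.

With these conventions, the robust biomarkers (CL, MDP, APA, FREQ and all
five Ca^2+^ timing measures) reproduce the reference simulated values within
0–2.5%, and every *relative* validation result — the current-block
percentage table, the rate challenges — reproduces within a few percentage
points. The shape-sensitive AP measures deviate more (APD~90~ +3.4%,
APD~30~ +5%, V~max~ +8%, APD~10~ +11%, triangulation −9%): the flat dome of
this AP makes them exquisitely sensitive to small plateau-current
differences, exactly the regime where the unprinted gate constants
matter. The reproduction harness asserts the stated ±3% anyway and reports
which biomarkers miss it.

## Protocols and problem sizes

All validation protocols pre-run the model to its limit cycle. The packaged
states (`packaged_state()`) are the terminal states of 800 s pre-runs
(spontaneous; paced 1 Hz at 550 pA and at 750 pA) and are regenerated with
`regenerate_steady_states()` whenever the model changes. The reproduction
harness uses:

* spontaneous biomarkers: packaged state + 20 s dense window (0.1 ms grid);
* current blocks: 1 Hz pacing, 400 s under block at a 10 ms output grid,
  then a 20 s dense window; stimulus 550 pA (750 pA for the Na^+^-blocker
  arms, where 550 pA loses capture entirely), 5 ms rectangular pulse — the
  pulse width is not printed and is an exposed default. Under the two
  strongest Na^+^-block arms the model settles into 2:1 capture; biomarkers
  are measured on the captured beats and the partial capture is reported
  per arm, which reproduces the printed percentage table far better than a
  wider always-capturing pulse (whose stimulus artifact inflates the
  blocked upstroke velocity by ~10 percentage points);
* rate challenges: 200 s settling after each environment step, 60 s
  measurement window;
* hypercalcemia DADs: instantaneous Ca~o~ step to 3.945 mM, 60 s;
* immature RyR: half-activation shifts of ∓0.002 µM on the open/closed
  gates, open-gate time constant doubled, closed-gate halved. The shifts
  are applied on the µM scale of the stored half-activations; the figure
  caption's "mM" would exceed the entire physiological range by three
  orders of magnitude and cannot be meant literally.

The solver is LSODA over a compiled right-hand side with per-state absolute
tolerances (cytosolic Ca^2+^ at 10^−10^ mM; gates at 10^−6^); tightening
rtol from 10^−6^ to 10^−8^ moves the headline biomarkers by under 0.05%.
Paced runs cap the internal step at half the pulse width so no stimulus is
stepped over.

## What the synthetic fixtures do and do not show

`waveform_spec()`/`generate_waveform()` produce rectangular, triangular and
piecewise-exponential AP- and transient-like trains whose biomarkers are
known in closed form, plus `inject_dad()` for constructed diastolic bumps.
They validate the *measurement* code to sub-sample precision (< 0.5 ms /
0.1 mV) independently of the ODE model. They are deliberately not
surrogates for real signals: noise is additive white Gaussian only, with no
photobleaching, baseline drift or shot noise, so passing fixture tests says
nothing about preprocessing raw fluorescence recordings beyond linear
rescaling.

## Known limitations

* Two Ca^2+^ compartments, no subcellular microdomains or stochastic RyR
  openings (deliberate, matching the reference's scope); no contraction
  model; no temperature dependence (all data 35–37 °C).
* Gate constants that the model family's primary description does not print
  were reconstructed from their stated source formulation and validated
  against the reference outputs; the residual AP-shape deviations above are the honest size of
  that uncertainty.
* At 2 Hz pacing the model alternates full APs with non-regenerative
  responses (2:1-like alternans); the alternans metric is therefore defined
  on per-stimulus peak potentials, not on consecutive APD~90~ values.
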