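---
title: "Simulating and denoising SiNW-FET biosensor signals: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and denoising SiNW-FET biosensor signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sinwfet)
```

This vignette explains the models behind `sinwfet`, the calibration of its
synthetic benchmark, and the design decisions that were genuinely open —
what was chosen, why, and what the consequences are for interpreting results.

## The measurement being simulated

A silicon-nanowire field-effect transistor (SiNW-FET) biosensor reports
antigen binding as a change in channel conductance: antibodies grafted on the
nanowire capture target antigens, the bound charge gates the channel, and the
source–drain current `Isd` shifts. The package simulates windows of `Isd`
sampled at `fs = 15` MS/s (comfortably above Nyquist for the highest 6 MHz
excitation), `T = 1024` samples per window (about 68 µs), across twenty
log-spaced excitation frequencies spanning 6 kHz–6 MHz.

Three model layers produce a window:

1. **Equivalent circuit.** The electrode/electrolyte interface is reduced to
   `Z(ω) = Rs + 1/(jωCs) + Rp/(1 + jωRpCp)` — series access resistance,
   series interface capacitance, and a parallel RC charge-transfer branch.
   The four element values (1 kΩ, 1 nF, 10 kΩ, 100 pF) place both corner
   frequencies inside the 6 kHz–6 MHz band, so `|Z|` falls monotonically by
   a factor ≈ 28 across the band. The wiring is a standard impedimetric-sensor
   reduction; it is held in a `topology` field so alternatives can be added.

2. **Langmuir binding.** Each analyte class carries an equilibrium occupancy,
   a response coefficient, and an association time constant;
   `θ(t) = θ_eq (1 − e^{−t/τ})` and the fractional impedance change is
   `response_coefficient × θ`, clipped to [0, 1]. The class table is
   calibrated so the asymptotic impedance changes are 92 % and 78 % for the
   high- and low-affinity targets and 5 % / 7 % for non-specific and
   cross-reactive antigens. The current readout is
   `Isd = Vds·G0·(1 + g·ΔZ/Z0)` with a 10 µA baseline and `g` set so the
   high-affinity equilibrium sits at 12.5 µA — above the 11 µA detection
   threshold — while non-specific binding stays below 10.2 µA. Receptor
   density varies between windows (occupancy CV 2 %), a mild biological
   variability that keeps levels continuous rather than five exact constants.

3. **Excitation and noise.** The clean trace is the binding-set level
   carrying a weak sinusoidal probe at the excitation frequency, attenuated
   by `|Z(f)|/|Z(6 kHz)|` (the parallel interface capacitance shunts the
   excitation at high frequency). The noisy trace adds white input-referred
   amplifier noise and the structured acquisition noise described below.

## Why the excitation probe is weak

The probe's modulation depth is `1e-4` at the reference frequency — well
below the acquisition-noise floor. This is a deliberate, load-bearing choice.
The denoising network prescribed here (two valid convolutions with max
pooling, a 128-unit dense layer, and a dense output of length `T`, with no
skip connections) must *synthesize* its output from a 128-dimensional
representation. Teaching it by MSE descent to re-create twenty distinct
high-amplitude carrier waveforms to the ~1e-4 relative fidelity that a 25–30
dB SNR improvement demands is not achievable at desk scale: the output layer
starts orthogonal to every tone template, so almost no gradient reaches the
frequency-selective features (a saddle, observed directly during
development). With a sub-noise probe, the information content of a window is
the binding level itself — which matches the detection logic, since the
published decision rule (`Isd > 11 µA`) operates on the level, not on the
carrier amplitude. A matched-filter oracle that knows each window's template
achieves ≈ 32–39 dB improvement on this benchmark, so the published
improvement figures remain attainable in principle, and the network's job —
suppress structured, non-linear, time-varying noise around a level — is
exactly the task the original system is claimed to solve.

What this means for interpretation: results on this benchmark demonstrate
adaptive suppression of structured acquisition noise around a slowly varying
operating point. They do not demonstrate reconstruction of strong
high-frequency carriers, which this architecture is not suited to.

## Noise model and its calibration

Per carrier frequency, the total acquisition-noise power is set so a
blank-level window's SNR follows a log-linear ramp from 46 dB (6 kHz) to
56 dB (6 MHz) — inside the published 45–60 dB envelope and rising with
frequency. The power splits into:

* **drift** — band-limited low-frequency noise (2nd-order Butterworth, 40 kHz
  corner), 50 % of the budget at 6 kHz falling to 6 % at 6 MHz. It is
  generated with zero window mean: over a 68 µs window, slower drift is
  indistinguishable from the binding level itself, so un-centred drift would
  make the level unidentifiable within a single window. Real baseline drift
  on longer scales would need reference subtraction outside this scope — a
  known limitation.
* **three interference tones** (0.9, 2.2, 5.1 MHz; 25 %, 6 %, 3 %) with
  slowly wandering phase (AR(1) wander, 0.3 rad RMS) — narrowband pickup
  whose split favours the 0.9 MHz tone, which a 5-sample moving average
  barely attenuates but a carrier-matched low-pass removes, preserving the
  published ordering between those two baselines.
* **white noise** (8 %) and **sparse bursts** (4 %; Poisson events, ~2 per
  window, 20-sample exponential decay) — broadband content.
* **a multiplicative term** (1 %): `nonlinear_mix · clean(t) · η(t)` — the
  signal-dependent non-linearity that linear filters cannot address.

The amplifier is a pure gain block (40 dB) with white input-referred noise
set so the amplified pathway sits near 74 dB SNR: in the raw benchmark
pathway acquisition noise dominates (45–60 dB), while re-synthesizing the
same seeds through the gain stage suppresses acquisition noise by the gain
and exposes the input-noise ceiling — reproducing the published 70–80 dB
"preamplifier-only" band and its explanation (amplification before the
acquisition stage, no ability to separate noise from signal).

## Classical baselines

* **Moving average**: centred 5-sample mean, symmetric (edge-repeating)
  padding.
* **Low-pass**: zero-phase (forward–backward) order-4 Butterworth. The
  two-pass response is `|H|²`; tests compare against the closed form. The
  per-window cutoff is `2.5 × carrier`, floored at 150 kHz and capped at
  `0.45 fs`. The floor exists because an order-4 filter at a 15 kHz cutoff
  settles over ~2 500 samples — longer than the window — so filtering a
  1 024-sample window would be edge-dominated (it measurably *lowered* SNR at
  the lowest carriers). Implementation detail: `signal::filtfilt` starts from
  zero state, so the input is linearly detrended and extended by long
  symmetric reflection before filtering; the detrend line is pure passband
  content and is restored afterwards.
* **Preamplifier-only**: the re-synthesized amplified pathway (same seeds),
  no data-adaptive processing.

## Training the denoiser

The network minimizes MSE between its output and the clean reference on a
standardized scale (train-split mean/SD of the noisy traces, stored in the
model). Optimization is Adam (batch 32) with three departures from a vanilla
setup, each forced by observed failure modes:

1. **Per-layer learning-rate scaling** `lr · min(1, √(64 / fan_in))`.
   Adam updates every weight by ≈ `lr` per step regardless of layer width.
   Because post-ReLU activations are non-negative, the gradient signs within
   a dense-layer column are coherent, so a single step can move a
   pre-activation by `lr × fan_in × E|a|` — for the 16 256-input dense layer
   at `lr = 1e-2`, swings of order 80, which mass-kill ReLU units. Unscaled
   runs collapsed to predicting the global mean (validation MSE pinned at the
   target variance). Square-root scaling keeps early pre-activation steps
   O(1) while still letting wide layers train; pure `1/fan_in` scaling
   protected the network but left the dense layer effectively frozen at its
   random initialization, an order of magnitude worse.
2. **Base rate 1e-2, two warm-up epochs at a tenth of it, halving on
   validation plateau (patience 4) to a 1e-5 floor.** Rates of 1e-3 and
   below never escape the mean-prediction plateau within a desk-scale budget.
3. **Adam ε = 1e-12.** With the loss normalized per element, late-stage
   gradients are ~1e-8 and the conventional ε = 1e-8 dominates `√v`,
   silently throttling convergence exactly where the high-fidelity regime
   begins.

Two further stabilizers: gradients are clipped to a global norm of 0.05
(late-stage batch gradients sit near 0.005, so only spikes from ReLU regime
shifts are touched), and from the midpoint of the epoch budget a running
average of the weights (tail averaging) is maintained and scored on the
validation split alongside the raw weights — the better of the two is kept.

Early stopping returns the best-validation-epoch weights. Training is
deterministic given the seed (single-threaded BLAS, fixed shuffle RNG);
reproducibility across platforms is exact for a fixed BLAS build, a caveat
stored with the model metadata. Gradients are verified against central
finite differences in double precision in the test suite.

Problem sizes (2 000 / 500 / 500 windows, `T = 1024`, 55 epochs) keep a full
training run at roughly two minutes on one CPU. The 55-epoch budget is a
deliberate compromise: the validation MSE is still descending slowly there
(about 23 dB of SNR improvement for the balanced preset, versus ≈ 24.4 dB
after 100 epochs and an information ceiling of ≈ 32–39 dB measured with a
matched-filter oracle), but it lets the complete study — seven trainings
plus evaluation — finish in well under twenty minutes. Consequences of
stopping on the descent are discussed under limitations.

## Fixed-point inference emulation

The FPGA datapath is emulated in software: weights, inputs and every layer's
outputs are rounded onto a signed `Q(total−frac−1).frac` grid (default
Q7.24, round-to-nearest, saturating); multiply–accumulates use a wide
accumulator, as DSP-block chains do, and are re-quantized at layer
boundaries. Non-saturating mode reports the first overflowing layer instead.
Repeated inference of the same window is bitwise stable; the desk-scale
stand-in for long-run operational stability is 10⁴ consecutive inferences
compared bitwise.

## Evaluation protocol

All SNRs are clean-referenced power ratios,
`10·log10(Σclean² / Σ(estimate − clean)²)` — a definition only a simulation
can apply exactly, which is why the generator stores the noise-free trace.
Noise-power reduction fraction `1 − Σ(denoised−clean)²/Σ(noisy−clean)²` and
SNR improvement are related by the exact identity
`improvement = −10·log10(1 − fraction)`; both are reported because a "75 %
noise reduction" and a "25 dB improvement" are *different* claims (75 %
power removal is only ≈ 6 dB). The amplitude-domain reduction fraction is
reported alongside for transparency. Detection applies the strict
`mean(Isd) > 11 µA` rule to the denoised trace; sensitivity, specificity and
cross-reactivity (fraction of non-target windows called present) come from
the confusion matrix, and a per-class mean response block mirrors the
published sensitivity table.

## What the synthetic benchmark does and does not show

The generator emulates: binding-level shifts with class structure and mild
receptor-density variability, carrier attenuation through the interface
impedance, structured acquisition noise with drift/tones/bursts and a weak
signal-dependent term, and an amplifier gain stage. It does not emulate:
device physics (Poisson/drift–diffusion, Debye screening), slow baseline
drift across windows, real antibody kinetics beyond the single-site Langmuir
form, sample matrix effects, or any measured data. Passing tests on this
benchmark therefore demonstrate the pipeline's internal consistency and the
relative behaviour of the methods under a controlled, plausible noise
model — not field performance of a physical sensor.

## Known limitations

* At the default 55-epoch budget the balanced network reaches ≈ 23 dB mean
  SNR improvement, short of the 25 dB the original study reports for its
  (undisclosed) training setup, and the high-capacity preset stops around
  23–24 dB rather than 30 dB. The gap is optimization time, not information:
  the matched-filter oracle reaches ≈ 32–39 dB on the same data, and the
  training curve is still descending when the budget ends. Reproducing the
  headline numbers exactly would need several hundred epochs per seed.
* The network's mean output SNR sits within a fraction of a dB of the
  preamplifier pathway's ≈ 74.7 dB at this budget, so whether the network
  strictly overtakes the preamplifier depends on the training seed.
* Reproducibility of training is exact for a fixed BLAS build and CPU;
  different BLAS implementations may give slightly different loss curves.
* Window-scale simulation only: no slow inter-window drift, no real
  measured signals, idealized antibody kinetics.

## Degenerate inputs and numerical edges

Zero noise reproduces the clean trace exactly and SNR reports an `Inf`
sentinel rather than an error; zero clean power is an error. The
moving-average window must be odd; cutoffs must lie strictly inside the
Nyquist band. Max pooling drops a trailing odd sample, exactly as the shape
algebra states. Quantization uses round-to-nearest-even on exact grid ties,
making re-quantization idempotent.
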