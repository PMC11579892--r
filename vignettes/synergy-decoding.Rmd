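---
title: "Decoding reach direction from muscle synergies: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding reach direction from muscle synergies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A person reaching from a home position toward one of eight targets on a
circle recruits shoulder and elbow muscles in stereotyped combinations.
Because muscle electrical activity precedes measurable limb motion by the
electromechanical delay (tens of milliseconds in free movement, longer when
the arm is coupled to a robot), a decoder that reads surface EMG can commit
to a movement direction *before* kinematics carry usable information — early
enough for an exoskeleton to assist rather than follow. `synid` implements
that decoding pipeline end to end, together with the assistance statics and
the evaluation battery needed to characterize it, and a seeded synthetic
generator so every stage can be exercised and tested without recordings.

## The model

**Linear envelopes.** Raw EMG sampled at 1 kHz passes a causal chain:
4th-order Butterworth band-pass 20–400 Hz, 2nd-order notch at 50 Hz
(quality factor 30), full-wave rectification, and a 2nd-order Butterworth
low-pass at 4 Hz. All filters are single-pass (causal) because the online
system cannot look ahead. The envelopes are decimated to the 100 Hz control
rate by plain subsampling, which is alias-free after the 4 Hz low-pass.

**Muscle synergies.** Envelopes `E` (6 muscles x time) are factorized as
`E ~ W H` with `W >= 0` (muscles x 4 synergies) and `H >= 0` (4 x time),
by multiplicative updates minimizing the RMS residual. The update rule
never increases the objective; we run up to 1000 iterations per restart,
stop at a relative RMSE change below 1e-6, take the best of 10 seeded
random initializations (uniform entries scaled to the data mean), and
normalize each column of `W` to unit Euclidean norm, folding the inverse
scale into `H` so that offline training features and online estimates live
on the same scale. Four synergies is the standard choice for upper-limb
reaching; the count is a parameter, not an inference.

**Per-direction mixtures.** The activation vectors of each direction's
training trials are modeled by a Gaussian mixture with 3 components, fitted
by expectation-maximization from a seeded k-means initialization. Each
M-step adds `1e-6 x (mean data variance)` to the covariance diagonal:
non-negative least squares produces exact zeros, and without the ridge the
covariances can lose rank.

**Online decoding.** After onset, at every 10 ms control step `k`:

1. `c_k = argmin_{c >= 0} ||e_k - W c||` (Lawson–Hanson active set, exact
   and deterministic);
2. each direction's mixture density is evaluated at `c_k` in the log
   domain and the 8-vector normalized to sum to one — a uniform prior is
   correct because targets appear in randomized order;
3. the cumulative probability vector is updated by element-wise product
   with the new likelihood vector and renormalized (recursive Bayes under
   per-step independence), starting from uniform;
4. the running estimate is the argmax, ties to the lowest direction index
   (E before NE before N, ...).

The estimate may evolve until the accumulation time `T_acc = 0.6 s`
(60 steps) and is frozen afterwards. If all eight densities underflow the
step contributes uniform evidence; if the product underflows the previous
cumulative vector is kept. With the log-domain evaluation these guards
trigger only on pathological inputs, but they define the contract.

**Onset detection.** The six envelopes are summed; at sample `n` the
threshold is `T[n] = mu + h sigma`, with `mu`, `sigma` computed over the
150 ms window ending at sample `n - 1` (the current sample is excluded so
a rising signal does not inflate its own threshold). The first strict
crossing is the onset; one reach per trial is assumed, so later crossings
are ignored. The gain `h` has no principled closed form: it is calibrated
on the generator's rest trials so that the false-positive rate is zero
with headroom. Under the default noise model, per-trial maximum baseline
excursions reach ~9.6 sigma over 1000 rest trials while activation bursts
cross at >= 11 sigma, so the default is `h = 10`. Detection runs at the
100 Hz control rate (15-sample window); a 1 kHz mode is available.

**Assistance statics.** A generic 4-DOF serial chain (shoulder
abduction/adduction, flexion/extension, internal/external rotation about
the humerus, elbow flexion) with segment lengths 0.30 and 0.35 m stands in
for the exoskeleton's active chain; the passive chain is deliberately not
modeled and the global-to-shoulder rotation is a fixed transform. The
virtual-stiffness force is `F = K (x_target - x_hand)` expressed in the
shoulder frame, joint torques follow from `tau = J^T F`, and gravity
compensation uses two point masses (2.0 and 1.5 kg at 0.13 and 0.16 m).
The stiffness defaults `[0.01, 0.03, 0.01]` are kept verbatim; because
forces of 1e-3 N over a 0.25 m workspace are mechanically meaningless, the
simulator exposes a separate gain multiplier (default 1000, i.e., the
printed values read as per-millimeter) so closed-loop behavior is
observable. The first-order hand-space loop
`x[k+1] = x[k] + (v_intent + admittance F) dt` is stable per axis for
`admittance x gain x dt < 2`; defaults (admittance 1, dt 0.01 s) give
0.1–0.3 of the remaining error corrected per step.

**Manipulability.** The per-pose index is
`sqrt(lambda_min / lambda_max)` of `J J^T` — the inverse condition number
of the Jacobian. It is the standard `J J^T`-based measure that is bounded
in [0, 1] and exactly zero at singular configurations, the two properties
the index must satisfy; a Yoshikawa variant (`sqrt(det(J J^T))`,
normalized over a sampled workspace) is selectable. Per movement the index
is the mean over the time-normalized trajectory.

## Evaluation battery

Errors are classified by circular index distance between true and
estimated direction (1 = adjacent 45°, ..., 4 = opposite); the five
percentages are computed over non-excluded trials and sum to 100 exactly.
Modified accuracy is correct + adjacent. Repeatability errors are the
absolute radial and wrapped angular differences between an assisted
movement's final polar position and the centroid of transparent movements
to the same target; signs are discarded because no sign convention is
defined for them. iEMG integrates the MVC-normalized envelope (percent)
over time normalized to [0, 1], so a constant envelope at MVC level scores
100. Movement end is the first sample after the displacement peak at or
below 20 % of the peak. The kinematics benchmark assigns each sample's
polar angle to the nearest 45° bin, with a 1 cm displacement gate below
which the previous estimate (starting at E) is inherited — without the
gate, angle noise at the home position generates spurious estimates. The
adjusted chance level is the smallest count k whose Binomial(n, 1/8) CDF
reaches 0.975, as a percentage of n; for n = 160 this gives 18.125 %,
i.e., 18.1 % at printed precision. The exactly-at-boundary case is
resolved by ">=", which that reproduction pins down.

## What the generator emulates — and what it does not

Each trial is built as follows. Synergy `s` with preferred angle `phi_s`
is recruited toward direction `theta` with amplitude
`max(0, cos(theta - phi_s))^p` (default `p = 1`, plain cosine tuning;
`p = 0` removes all direction information and is the chance-floor
construction). The temporal profile is a Gaussian bell peaking at 50 % of
the movement duration, truncated at the EMG onset: activation switches on
as a burst (the bell's tail value, ~13.5 % of peak at the default width
0.25 of movement duration) and then follows the bell. Real muscle bursts
begin abruptly even when the overall profile is bell-shaped; a smooth
Gaussian rise would be undetectable in principle by any trailing-window
threshold, because a ramp never exceeds its own window statistics by more
than a few sigma.

Envelope noise is colored and signal-proportional: unit-variance Gaussian
noise low-pass filtered at 4 Hz (the envelope bandwidth — white noise at
100 Hz would be inconsistent with the filtering chain that envelopes have
passed), scaled so that the signal-to-noise ratio is constant at every
instant and equals the configured `snr` (default 20) at peak activation.
This matches the behavior of a rectified-and-smoothed signal, whose
fluctuation scales with its level, and gives the onset detector a
physically sensible operating point: near-silent rest, proportional
fluctuation during movement.

Motor variability enters at three levels chosen once at standard
magnitudes: trial-to-trial vigor (lognormal, CV 0.15), within-trial
synergy-drive variability (smooth multiplicative noise, CV 0.2 — this is
the scatter the 3-component mixtures are meant to capture; without it the
per-direction activation distributions collapse to rays), and executed
direction jitter (SD 5°). Kinematics are minimum-jerk reaches (fifth-order
polynomial, zero endpoint velocity and acceleration) to the target with
1 cm endpoint scatter, starting one electromechanical delay (default
0.1 s, the free-movement 0.04–0.07 s lengthened by robot coupling) after
EMG onset. Trials are 2.7 s: 1 s rest, delay, 1.2 s movement, hold.

The generator does **not** emulate: motor-unit structure or raw-EMG
statistics (a crude amplitude-modulated-noise raw mode exists only to
exercise the filter chain), muscle fatigue or electrode lift-off,
cross-talk, non-stationary tuning, or the altered synergy structure of
neurological injury. Consequently, passing the end-to-end tests shows the
pipeline is correct and well-calibrated *under its own model class*; it
does not predict human-subject accuracy. Indeed on synthetic sessions at
snr 20 the decoder saturates near-perfect accuracy, far above what real
recordings yield, and both the synergy decoder and the kinematics
benchmark reach 100 % modified accuracy late in the window — so the
late-window superiority of the kinematics benchmark observed on real data
does not reproduce here, while its early-window inferiority (before the
electromechanical delay, when the hand has not yet moved) reproduces in
every replicate.

## Numerical choices

* NMF: eps-guarded multiplicative updates (denominator + 1e-16); RMSE
  monotonicity is asserted in tests. Column normalization after
  convergence only.
* NNLS: Lawson–Hanson active set; KKT conditions (active gradients ~ 0,
  inactive gradients >= -1e-8) are asserted in tests against an
  exhaustive-support oracle.
* Mixture densities: Cholesky-based log densities, log-sum-exp pooling;
  probability vectors renormalized every step, keeping all stored
  8-vectors within 1e-9 of unit sum over 60 steps.
* Ties: argmax ties break to the lowest direction index; the 45° bin edge
  of the kinematics benchmark (e.g., 67.5°) therefore classifies to the
  lower-index neighbor (NE, not N).
* Inverse kinematics (generator-only): damped least squares, damping 1e-3,
  joint-limit clamping.
* Degenerate inputs: all-zero training envelopes, band edges at or above
  Nyquist, missing MVC values, mixtures with fewer labeled samples than
  `3 x n_syn`, and trials shorter than one onset window all raise typed
  errors naming the offending quantity.

## Problem sizes

The default study shape is 10 training and 20 test trials per direction
(80 + 160 trials) at 100 Hz with 60 decoding steps per trial; the
chance-floor check uses 400 test trials; onset calibration suites use 200
trials of 4–5 s; the time-resolved benchmark comparison uses 10 session
replicates. These sizes keep a full run on one CPU in minutes while
leaving all statistical checks comfortably powered.

## Known limitations

* The exoskeleton chain is generic: lengths, masses and the fixed base
  rotation are placeholders, so manipulability values are not comparable
  to any specific device.
* The accumulation update assumes per-step conditional independence;
  envelope noise is correlated over ~0.25 s, so the cumulative probability
  overstates its own confidence. Direction estimates are unaffected
  (monotone transform), but the probability values should not be read as
  calibrated.
* The adjusted chance level is computed for the nominal trial count; with
  exclusions the per-session value is recomputed for the surviving count.
* MVC surrogates in synthetic sessions are 120 % of the nominal peak
  envelope; iEMG values are therefore internally consistent but not
  comparable to MVC-normalized human data.
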