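---
title: "Associative-memory fall detection: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Associative-memory fall detection: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopfall)
```

## The problem and the method

Falls among elderly users of wearable devices must be recognized from motion
sensors in real time and at low power. `hopfall` implements a deliberately
minimal recognition chain built around a *discrete Hopfield network used as an
associative memory*: instead of fitting a discriminative classifier to a large
training set, a single example of a fall is stored as an attractor of a
25-neuron recurrent network, and incoming activity windows are classified by
how close the network's recalled state lies to that stored pattern. The same
weights admit a direct analog-hardware realization (resistor networks around
summing amplifiers), which this package simulates behaviorally.

The chain is:

1. **Sensor fusion.** A 9-axis IMU stream (gyroscope `Gx,Gy,Gz`, accelerometer
   `Ax,Ay,Az`, magnetometer `Mx,My,Mz`, 50 Hz) is fused per sample into five
   features. `M1 = (|Gx|+1)(|Gy|+1)(|Gz|+1)` and its accelerometer and
   magnetometer analogues `M2`, `M3` are per-sensor motion-intensity products
   (each is at least 1 and grows multiplicatively with motion on any axis);
   `M4 = (Ax·My·Gz − Gx·My·Az)/2` and
   `M5 = (Gx·Ay + Ax·My + Mx·Gy − Gx·My − Ax·Gy − Mx·Ay)/2` are signed
   cross-sensor products sensitive to coordinated rotation and acceleration.
   The formulas are implemented literally; we take no position on whether they
   derive from a quaternion/cross-product posture computation.
2. **Binarization.** Each feature is compared to its own threshold,
   `t = (16, 24, 32, 40, 48)` by default, with a *strict* `>` (a value exactly
   at threshold reads low), giving a bipolar 5×N matrix.
3. **Windowing.** The contiguous 5×5 window with the most `+1` entries (ties:
   earliest) becomes the activity's template; its row-major flattening is the
   25-vector one neuron per matrix cell.
4. **Storage.** Hebbian outer-product learning, `W = η Σ_p p pᵀ` with
   `diag(W) = 0`, stores the fall template. Symmetry and the zero diagonal are
   structural invariants, not numerical accidents: they are what make the
   energy argument below work.
5. **Recall.** From a probe state `v`, neurons update by
   `u_i = Σ_j W_ij v_j + I_i`, `v_i ← sign(u_i)`, asynchronously in a seeded
   random order (default) or synchronously, until a full sweep changes
   nothing.
6. **Decision.** The recalled state is compared to the fall template by cosine
   similarity — for bipolar 25-vectors, `(25 − 2·hamming)/25` — and called a
   fall when the similarity reaches the decision threshold (default 0.8, i.e.
   at most 2 of 25 bits astray). Accuracy is `(TP+TN)/(TP+FP+TN+FN)`.

## Dynamics, energy and the tie rule

With symmetric weights and no self-feedback, asynchronous updates never
increase the energy `E(v) = −½ Σ_ij W_ij v_i v_j − Σ_i I_i v_i`, so recall
terminates in a fixed point. The package records the energy after every
single-neuron update; the monotonicity is asserted over a thousand random
symmetric networks in the test suite rather than assumed.

Two conventions required a decision:

* **Bipolar states.** Neuron outputs are ±1 everywhere (the thresholded
  features are ±1 and Hebbian storage of ±1 patterns produces the signed
  weights the hardware mapping needs). The 0/1 rendering of the threshold
  activation is treated as notation for the same rule.
* **Zero local field.** `u_i = 0` keeps the previous state. Forcing the low
  state instead would make the all-zero-field configuration oscillate and
  would break the equivalence between "fixed point" and "state a sweep leaves
  unchanged". This single rule is used consistently in digital recall, in the
  analog readout, and in the brute-force fixed-point oracle; we deliberately
  did not make it configurable, because a second tie convention would fork
  those three definitions.

For a single stored 25-bit pattern the model is exactly solvable: a probe with
`m` flipped bits gives local field `(24 − 2m)p_i` on intact neurons and
`(26 − 2m)p_i` on corrupted ones, so one synchronous sweep restores the
pattern for every `m ≤ 11` (and the intact neurons sit exactly on the tie rule
at `m = 12`). The test suite checks this exhaustively in `m` with 100 random
flip sets each, and checks by full enumeration on networks of up to 10 neurons
that the recall dynamics' immediate states coincide with the brute-force
fixed-point set.

The learning rate `η` only rescales local fields, never their signs, so recall
is `η`-invariant; `η = 1` is the default and a property test asserts the
invariance rather than trusting the algebra.

## The analog circuit model

The hardware realization replaces each neuron by a summing amplifier: the
other neurons' outputs inject current through connection resistors (Kirchhoff
current balance at the input node), a bias source adds a constant, and the
amplifier saturates. The circuit topology fixes no ODE by itself, so the
package adopts the textbook continuous-Hopfield relaxation of exactly that
circuit:

\[
\tau \dot u_i = -u_i + \textstyle\sum_j G_{ij} v_j + b_i + \xi_i(t),
\qquad v_i = V_{\mathrm{rail}} \tanh(\lambda u_i),
\]

with `G` the conductance realization of `W`: magnitudes proportional to `|W|`
and normalized so `max|G| = 1` (no absolute resistor values are assumed —
only ratios matter to the dynamics), signs routed through the inverting or
non-inverting input, zero weights open circuits. Noise `ξ` is white Gaussian
at the summing node, seeded.

Numerical choices: fixed-step explicit Euler with `dt = τ/100` and a default
horizon of `8τ`, which at gain `λ ≥ 10` settles the node voltages to well
within one readout bit; a numerically checked Lyapunov function (the
continuous energy including the `(1/λ)∫\tanh^{-1}` leak term, evaluated in the
form `½[(1+x)\log(1+x)+(1−x)\log(1−x)]` that stays finite on the rails)
guards the step size; any node exceeding 10⁶ times the rails aborts the run
and is reported as divergence. At high gain the thresholded steady states
coincide with the digital network's fixed points — asserted as a 200-run
agreement experiment, not assumed — which is what justifies using the analog
backend interchangeably in the pipeline.

Op-amp non-idealities (slew rate, offset, finite bandwidth), SPICE-level
device models and power estimates are out of scope.

## The synthetic generator: what it emulates and what it does not

No public recording set accompanies the method, so the package ships a seeded
generator whose defaults *are* the study conditions: 50 Hz, 6 s recordings,
five classes (Fall, SitDown, StandUp, Under, Walk). Each channel is baseline
Gaussian noise (sd 0.1, arbitrary units — the fusion thresholds are taken to
act directly on the fused values) plus a deterministic class envelope:

| class   | envelope                         | peak | crosses (per-feature pairing)   |
|---------|----------------------------------|------|---------------------------------|
| Fall    | half-sine, 0.6 s                 | 6.0  | all five thresholds             |
| SitDown | half-sine, 0.8 s                 | 2.0  | `t₁`, `t₂` only (M1, M2 rows)   |
| StandUp | half-sine, 0.7 s                 | 1.8  | `t₁` only                       |
| Walk    | sinusoid, 2 Hz, whole recording  | 1.2  | none (periodic, sub-threshold)  |
| Under   | none (low-motion class)          | 0    | none                            |

"Under" is not otherwise specified in the field's usage; the generator
documents it as a near-baseline (low-motion) class. The transient's channel
signs are fixed so the signed features come out positive: at peak amplitude
`a` the envelope gives `M1 = M2 = M3 = (a+1)³`, `M4 = a³`, `M5 = 2a²`. The
Fall peak of 6 then yields `M5 = 72 > 48` over roughly 11 consecutive samples
— the binding constraint that guarantees an all-`+1` 5×5 window — while the
SitDown peak of 2 tops out at `M4 = 8`, `M5 = 8`, far below the upper
thresholds. The Fall peak strictly exceeding all other peaks is enforced as a
config invariant, not just a default.

Passing tests on this generator show that the *method* behaves as specified —
storage, recall, energy descent, analog agreement, and that the fusion rules
separate a transient of sufficient amplitude from lesser ones. They do not
show field performance on real falls: real IMU data have gravity offsets,
orientation-dependent axes, colored noise, inter-subject variability and
fall-like confounders (sitting down hard, jumping), none of which the
half-sine model emulates. The end-to-end accuracy the pipeline reports on
synthetic data (bar: ≥ 0.85) is a self-imposed regression check, explicitly
*not* a reproduction of any field accuracy figure.

## Open choices and their resolutions

* **Threshold pairing.** The binarization step can be read as row `i`
  thresholding feature `Mᵢ` (five distinct features, five thresholds) or as a
  thermometer code of one fused value at five levels. Since five distinct
  formulas are computed, the per-feature reading is the default; the
  thermometer reading is available (`binarize(..., pairing = "thermometer")`,
  reading feature `M1` unless told otherwise) and documented as the
  alternative.
* **Template flip.** An optional left–right column reversal of the extracted
  window (`extract_template(..., flip = TRUE)`) is provided but off by
  default: Hebbian storage of a pattern and of its column reversal are equally
  valid templates, and the operation is not otherwise pinned down.
* **Window selection.** "The most active window" is operationalized as
  maximum `+1` count with earliest-start tie-breaking, validated against an
  exhaustive scan. Window starts are reported 1-based, as R indexes columns.
* **One-shot protocol.** The pipeline trains on the template of the *first*
  fall recording and classifies every recording in the dataset (including
  that one). Holding the training recording out changes the accuracy by at
  most one count at the default sizes; one-shot storage is the point of the
  method, so the simpler protocol is kept.
* **Bias inputs.** The external inputs `I` (hardware: bias sources) default
  to zero; no values are prescribed for them anywhere, and with `I = 0` the
  stored pattern and its negation are both attractors (the classifier's
  signed similarity distinguishes them).
* **Multi-pattern storage.** `hopfield()` accepts several templates (the
  classifier then predicts by argmax similarity); the headline pipeline
  stores only the fall template, and capacity analysis beyond the bundled
  property tests is out of scope.

## Problem sizes used by the checks

The shipped verification uses sizes chosen to keep the whole suite
desk-scale: 25-neuron networks throughout; exhaustive enumeration up to
2¹⁰ states; 1,000 random asynchronous trajectories for the energy property;
200 seeded analog runs for the agreement experiment and 100 seeds per noise
level (0, 0.05, 0.1 rails) for the robustness curve; 100 seeded recordings
per class for the separability property; and 10 recordings per class
(50 total) for the end-to-end accuracy. `scripts/acceptance.R` recomputes all
of these from scratch from a single command-line seed.

## Known limitations

* The synthetic generator is a qualitative emulator; claims about real-world
  fall sensitivity/specificity cannot be made from it.
* The analog model is behavioral (ideal op-amps, single time constant, white
  noise); it validates the weight-to-conductance mapping and the attractor
  structure, not a specific silicon implementation.
* Thresholds are fixed operating constants; no adaptive threshold learning is
  provided.
* Binary (±1) storage only; continuous-valued patterns are out of scope.
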