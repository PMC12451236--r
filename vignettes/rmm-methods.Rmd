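---
title: "Recurrent mechanistic models of small circuits: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrent mechanistic models of small circuits: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmmcircuit)
```

# The model

`rmmcircuit` learns discrete-time models of small neural circuits from
current-clamp data.  Each neuron obeys a capacitive current balance

$$ c_i \frac{\hat v_{i,t+1} - \hat v_{i,t}}{\delta}
   = -\big(\hat I^{\mathrm{int}}_{i,t} + \hat I^{\mathrm{syn}}_{i,t}
   + \hat I^{\mathrm{leak}}_{i,t}\big) + u_{i,t} , $$

where $u_{i,t}$ is the measured injected current and $\delta$ the sampling
period.  The total membrane current is a *recurrent mechanistic model*
(RMM): the intrinsic current is a multi-layer perceptron reading the
neuron's own voltage together with a bank of internal states $w_{i,t}$,
and the synaptic current is either a second perceptron reading the neuron's
voltage and a bank $z_{i,t}$ driven by the presynaptic voltage, or the
biophysically informed conductance form
$\bar g\,\sigma_+(h_+(z_{i,t}))(\hat v_{i,t}-E^{\mathrm{syn}})$ with
positive-weight gate $\sigma_+ \in (0,1)$.  The leak is
$\theta^{1}_{\mathrm{leak}} \hat v - \theta^{2}_{\mathrm{leak}}$ with a
softplus-positive conductance.  Internal states follow *fixed* linear
dynamics $x_{t+1} = A x_t + B \hat v_t$; $A, B$ are never learned.

## Internal state banks and contraction

The banks are built from continuous time constants $\tau_k$ via the
stability-preserving map $\lambda_k = e^{-\delta/\tau_k}$.  The default
sets cover fast gating to ultraslow adaptation: $\{0.2k\}\cup\{2k\}\cup
\{10+10k\}$ (ms, $k=1..8$) and $\{200k-100\}$; intrinsic banks use the
union (32 poles per neuron), synaptic banks the fast+slow set (24), giving
2 × (32 + 24) = 112 internal states in a full two-neuron circuit (a smaller
count is sometimes quoted for this architecture; the package simply follows
the stated sets).  `build_orthogonal_ss()` realizes the poles so that the
impulse-response state trajectories are orthonormal (controllability
Gramian = identity), a rich non-redundant feature set; the conductance
synapse instead uses a diagonal unit-DC bank so its gate reads low-passed
presynaptic voltage in millivolts.

Because every pole lies in $(0,1)$, the internal dynamics are
exponentially contracting (`check_contraction_linear()`).  Contraction is
what makes the rest of the package work: internal states can be *warmed
up* on a data prefix and the unknown initial condition is forgotten at
rate $\lambda_{\max}$ per step (asymptotically — the orthonormal
realization is non-normal, so a bounded constant multiplies the envelope);
teacher-forcing gradients stay bounded as the dataset grows; and a unique
internal equilibrium $x_\infty(v) = (I-A)^{-1}Bv$ exists at every voltage,
which underwrites the frequency-domain analysis.

## Training: one family, three members

All three training methods minimize squared voltage prediction error plus
a ridge penalty $\rho\|\theta\|^2$ on the ANN parameters, and differ only
in how far gradients propagate through time:

* **Feed-forward teacher forcing** (`method = "tf"`): internal states are
  precomputed once by driving the banks with the *measured* voltages
  (`precompute_internal_states()`); the loss is the mean squared one-step
  residual and backpropagation never crosses a time step.
* **Multiple shooting** (`method = "ms"`): the data are tiled by shots of
  $s$ samples with learnable initial voltages $\upsilon^{(n)}$ and internal
  states $\xi^{(n)}$; each shot is simulated forward and gradients flow
  through the $s$-step rollout only.  Continuity penalties
  $\rho_v\|\hat v^{(n)}_s - \upsilon^{(n+1)}\|^2 +
  \rho_x\|\hat x^{(n)}_s - \xi^{(n+1)}\|^2_D$ stitch consecutive shots;
  $D$ weights each state error by the squared reciprocal of its DC gain
  (the plain norm in DC-normalized coordinates — reciprocal-first-power
  weighting is sign-indefinite for the orthonormal banks, so it cannot
  define a norm).
* **Generalized teacher forcing** (`method = "gtf_ms"`): identical to
  shooting except that within each shot every propagated voltage is
  corrected toward the measurement, $\breve v = \hat v + \gamma(v - \hat
  v)$, before driving the next step.  This is a Luenberger observer of the
  membrane; `observer_simulate()` runs the same update at inference time
  and is how unmeasured disturbance currents can be filtered out of a
  recording in real time.

The family is internally consistent by construction, and the package
asserts it: the shot data-fit runs over the *propagated* predictions
$t = 1..s$, so shooting with $s=1$ and initial voltages pinned to the data
is exactly the teacher-forcing loss (to $10^{-10}$), and $\gamma = 0$
rollouts are bit-identical to plain shooting.  (Summing the data fit from
$t=0$ instead — a reading the shooting literature sometimes uses — makes
the $s=1$ case degenerate, which is why the propagated-prediction
convention was chosen.)  Gradients are hand-written reverse-mode passes
(there is no autodiff in R); every gradient path, including the shot-state
and conductance-synapse paths, is verified against central finite
differences in the test suite.

Optimization is Adam with $(\beta_1,\beta_2) = (0.9, 0.999)$; default step
sizes are 0.001 for TF, 0.01 for GTF, and 0.01 dropping to 0.005 at epoch
50 and 0.0025 at epoch 100 for shooting; $\rho$ defaults to $5\times
10^{-8}$ (TF) and $5\times10^{-9}$ (shooting), with
$\rho_v=\rho_x=500$, and 48 mini-batches.  Two practical notes from
working at desk scale: teacher forcing benefits enormously from *many
small* mini-batches (thousands of parameter updates per epoch — batch
sizes of order 50–100 samples), and open-loop validation performance
peaks early and then degrades while the training loss keeps falling, so
models are snapshotted (`snapshot_every`, down to every epoch) and the
snapshot with the best validation metric is returned.  Both phenomena
mirror what mini-batch-size and overfitting sweeps show for this model
class.  Training aborts with a diagnostic if the loss or gradient norm
exceeds `max_grad` ($10^{12}$): under contraction this indicates
misconfiguration, and silent gradient clipping is deliberately not
implemented.

Units are mV and ms throughout, with currents in nA, conductances in µS
and capacitances in nF, so that every learnable raw parameter is order
one (the spike-train data scale at which the default Adam step sizes are
meaningful).  The dynamic-clamp parameter tables are entered in the
conventional nS and converted internally.

## The validation metric

Voltage prediction quality is scored by the modified angular separation
between smoothed spike trains,
$\langle y, \hat y\rangle / \max(\|y\|^2, \|\hat y\\|^2) \in [0,1]$,
which unlike the plain cosine penalizes magnitude mismatch
($\mathrm{metric}(y, a y) = \min(a, 1/a)$).  Each trace passes a four-step
pipeline: (i) zero-phase (forward–backward) 3rd-order Butterworth
band-pass, 20–500 Hz at the native 10 kHz rate, removing the slow burst
wave without phase distortion; (ii) relu thresholding at 5 mV; (iii)
strict local maxima become unit impulses, maxima within 0.5 ms merging to
the larger peak; (iv) convolution with a Laplace kernel
$e^{-|t|/\tau}$, $\tau = 50$ ms, truncated at $\pm 6\tau$ and normalized
to unit absolute sum.  All constants are expressed in milliseconds and
converted to samples at the recording rate, so decimated recordings
behave consistently.  Edge handling: the trace is anchored by subtracting
the line through its endpoints (pure low-frequency content that the
band-pass removes anyway) before reflective padding of three filter
orders; without the anchoring, the −65 mV baseline acts as a step at the
boundaries and rings past the spike threshold.  Two identically zero
trains return 0 with a warning.

`validate_model()` warm-starts the internal states on a measured prefix,
simulates the model open loop ($\gamma = 0$) over the remainder, and
scores each neuron.

## Frequency-domain interpretation

For any membrane with contracting internal dynamics the package computes,
in closed form (exact perceptron derivatives, no numerical Jacobians):

* the steady-state IV curve $u_\infty(v) = h(v, x_\infty(v))$ and its
  derivative, the GV curve
  $G_\infty(v) = \partial_v h + \partial_x h\,(I-A)^{-1}B$;
* the admittance surface
  $Y(v,\omega) = \partial_v h + \partial_x h\,(e^{j\omega\delta}I -
  A)^{-1}B$, whose real part (the frequency-dependent conductance)
  satisfies $G(v, 0) = G_\infty(v)$ and whose negative regions mark
  voltage–frequency ranges of local excitability
  (`excitability_map()`);
* candidate bifurcations: solutions of
  $C(e^{j\bar\omega\delta}-1) + \delta Y(\bar v,\bar\omega) = 0$, located
  by sign-change bracketing on the grid plus `uniroot` refinement.  Roots
  at $\bar\omega = 0$ are fold candidates (equivalently zeros of
  $G_\infty$); $\bar\omega > 0$ roots are Neimark–Sacker candidates.
  Rigorous confirmation (normal forms, continuation) is out of scope.

Per-neuron analysis of a trained circuit uses
$h = \hat I^{\mathrm{int}} + \hat I^{\mathrm{leak}}$ with the synaptic
current treated as an external input (`neuron_membrane()`).  The analytic
admittance is cross-checked by `sinusoid_gain_check()`, which simulates
the current response to a small sinusoid around a set-point and matches
gain and phase against $|Y|$ and $\angle Y$ to better than 1%.  Default
grids: training-range voltages in 1 mV steps; frequencies 0 plus a
logarithmic grid up to the Nyquist rate $\pi/\delta$.

## The synthetic half-center oscillator

`simulate_hco_dataset()` emulates the structure of a dynamic-clamp
half-center experiment: two surrogate spiking neurons, coupled by virtual
inhibitory synapses
($I = -\bar g z (v - E^{\mathrm{syn}})$, logistic activation with 2 mV
slope, gate rate $(\delta/50)(1.1-\sigma)$) and hyperpolarization-
activated currents ($I_h = -\bar g_h w (v - E_h)$, decreasing logistic
activation with 7 mV slope, rate
$\delta/(\bar\tau(\tau_h(v) + 0.1))$ with
$\tau_h(v) = 1/(1+e^{-(v+110)/13})$; a flag selects the alternative
parenthesization $\bar\tau\,\tau_h(v) + 0.1$), each driven by a
nonzero-mean Ornstein–Uhlenbeck current.  The dynamic-clamp parameters
default to the set that produces the alternating rhythm
(synaptic 105/150 nS at −80 mV, half-activation −50/−44 mV; H
225/120 nS at −10 mV, half-activation −45 mV; $\bar\tau$ 1000/1500 ms).
OU noise uses the literal $b\,\delta\,\varepsilon_t$ innovation by
default, with a `sqrt_delta` Euler–Maruyama alternative.  Every current
component is stored separately (`Isyn12`, `Isyn21`, `Ih1`, `Ih2`,
`Iapp1/2`), so synaptic-current predictions can be validated against
ground truth that was never used in training.

The surrogate membrane is a two-variable Morris–Lecar-type spiker — the
biological cells' intrinsic dynamics are not part of what the experiment
defines, so the surrogate only needs to spike tonically under
depolarization and be silenceable by nanoamp inhibition.  Its calibration
matters in one non-obvious way: a two-cell reciprocal-inhibition circuit
with escape dynamics can easily be *chaotic at the burst boundary*, in
which case no model — not even the generating equations restarted from a
millivolt-perturbed state — can predict the held-out spike train open
loop (self-prediction ceilings of ~0.3–0.4 on a 5 s window were measured
for an early, larger-conductance calibration).  A real preparation whose
held-out activity *was* predictable must have been substantially
entrained by the injected noise.  The default surrogate
(C = 250 pF, $g_L$ = 40 nS, $g_{Ca}$ = 65 nS, $g_K$ = 130 nS,
$\varphi = 0.1$, OU means 0.03/0.22 nA) is therefore calibrated so that
the self-prediction ceiling under the stronger OU setting is ≈0.85–1.0
while anti-phase alternation persists (smoothed-spike-train correlation
≈ −0.2, vanishing when the synapses are zeroed).  What passing tests on
this generator do *not* show: robustness to electrode artifacts,
channel noise, slow drift, or the far richer intrinsic currents of real
stomatogastric neurons.

## Problem sizes and numerical choices

Desk-scale defaults used by the tests and the acceptance analyses: two
20 s trials at $\delta = 0.1$ ms with a contiguous 75/25 train/validation
split per trial; reduced circuits with 8-pole banks (log-spaced 0.5–1000
ms intrinsic, 0.5–200 ms synaptic) and 2 × 8-unit perceptrons; shooting
with $s = 30$; warm-up/burn-in capped at a fifth of the available data
(the tolerance-derived length $\lceil\log 10^{-9}/\log\lambda_{\max}
\rceil$ exceeds any desk-scale recording for ultraslow poles).  Duplicate
poles are permitted with a warning (the construction stays well-defined).
Fixed points of the internal dynamics are closed-form; root refinement
uses `uniroot` at tolerance $10^{-12}$; serialized models and recordings
store doubles at 17 significant digits so round-trips are lossless.

## Known limitations

Teacher forcing amplifies measurement noise through the finite-difference
target $v_{t+1}-v_t$ (the motivation for shooting); the validation metric
is spike-centric and insensitive to subthreshold accuracy; learnable
$A, B$, adaptive-$\gamma$ observers, multi-compartment morphology, gap
junctions and matrix-valued circuit admittances are out of scope; and the
bifurcation layer reports *candidates*, not confirmed bifurcations.

Two desk-scale findings from the bundled end-to-end experiment deserve
honest emphasis.  First, with 30 s of strongly noise-entrained synthetic
data and reduced models, densely mini-batched teacher forcing with
per-epoch snapshot selection consistently *outperformed* multiple
shooting across initializations in our tests — the shooting advantage
reported at full scale on long real recordings did not reproduce under
these conditions.  Second, the conductance-synapse variant fits the
one-step vector field as well as the unconstrained model, and its learned
gate tracks the ground-truth synaptic current closely along the measured
trajectory, yet its open-loop simulations settle into a wrong burst
allocation, so its *simulated* synaptic currents correlate weakly with
ground truth at this scale.  Both behaviors are asserted (and the second
documented as a failing expectation) in the acceptance tests.
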