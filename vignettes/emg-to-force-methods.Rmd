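---
title: "EMG-to-force estimation: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EMG-to-force estimation: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgforce)
```

This vignette documents the science implemented in `emgforce`: the three
contraction models, the signal-processing conventions, the defaults and the
reasoning behind every numerically consequential choice. It states no
empirical result that the test-suite or `scripts/acceptance.R` does not
itself compute.

## The estimation problem

Surface EMG is the interference pattern of the action-potential trains of
all recruited motor units. It carries the subject's own activation timing,
which makes it attractive as the input of a muscle model: the model maps
EMG to muscle force, and per-muscle forces map to joint torque through
pennation angles and moment arms. All modeling here is for *isometric*
contraction: the whole muscle–tendon length is constant, the contractile
element (CE) shortens against the series tendon, and only concentric CE
behavior is modeled. Forces are compared on an MVC-normalized scale, which
removes subject-specific strength from the comparison.

## EMG conditioning

The chain is high-pass, rectify, low-pass (or moving average), normalize:

* **Zero-lag filtering.** A "zero-lag order-N Butterworth" is realized as a
  forward–backward pass of an order-N/2 design: this is the only way to
  obtain both the stated net magnitude order and exactly zero phase from a
  single design. The net amplitude at the cutoff is the squared single-pass
  value (1/2 rather than 1/√2). A `zero_lag = FALSE` switch applies a
  single causal order-N pass for sensitivity studies.
* **Edge handling.** Both passes use odd-reflection padding of three times
  the effective order *and* start the recursion in its DC steady state
  (direct-form-I histories seeded with the first sample and its DC-gain
  image). Steady-state initialization is what actually suppresses the
  startup transient — reflection padding alone would need pads comparable
  to the filter's impulse-response length, which short bursts cannot
  provide. With both in place, a constant passes through a low-pass
  exactly and a symmetric pulse keeps its peak index exactly.
* **Moving-average (MAV) envelope.** When a window (0.25–0.5 s is
  customary) is configured it replaces the low-pass. The window is centered
  and *shrinks* at the series edges, which keeps the envelope inside the
  input's range; padding conventions would not.
* **Envelope cutoff.** 2 Hz by default (slow tasks); up to 6 Hz for fast
  tasks. For Hill-type models this choice essentially dictates the force
  envelope, which is precisely the weakness the cross-bridge model
  addresses — its force dynamics do not inherit the envelope bandwidth.
* **MVC peak.** Taken as the maximum of the *processed* MVC-trial
  envelope, i.e. after the same steps 1–3, so normalization matches the
  processing order.

## Activation dynamics

The twitch-like lag between the electrical and mechanical events is a
delayed, critically damped second-order discrete recursion with unit DC
gain enforced by construction (`gamma = 1 + beta1 + beta2`). Defaults that
the source literature leaves open, chosen once:

* electromechanical delay `d = 40 ms` — a typical triceps-surae value;
  rounded to whole samples because the recursion is discrete;
* `C1 = C2 = -0.5` — a critically damped double pole at `z = 0.5`, i.e. a
  sub-millisecond discrete twitch at 2 kHz sampling, so the envelope
  dynamics dominate (the recursion adds lag, not shaping).

The nonlinear shape factor `A in [-3, 0)` amplifies low activation
(`a(p) >= p` on (0, 1)), with `A = 0` handled as the exact linear limit.
`A` is the one subject-specific parameter; `calibrate_shape_factor()`
recovers it by bounded scalar minimization of the MVC-trial RMS error,
with explicit endpoint checks so boundary optima are returned exactly.

## Hill-type contraction dynamics

With the whole-unit length fixed at `Lc0 cos(phi) + Lt0`, the tendon
stretch is `-Lc0 eps_c cos(phi)`; the tendon force `kt (Lt - Lt0)` is
clipped at zero (a slack tendon carries no load). At each step the force
balance `Ft = Fc cos(phi)` is solved for the force–velocity fraction `fv`,
which is inverted algebraically to the strain rate; the strain is advanced
by fixed-step RK4 with activation held constant within a step.

Numerical and scope choices:

* **Concentric-only clamp.** The force–velocity relation covers shortening
  only. Whenever the balance would demand `fv > 1` (lengthening — e.g.
  during relaxation, when the stretched tendon overpowers a fading
  activation) the implementation clamps `fv = 1`, freezing the CE strain.
  This is the minimal extension consistent with the concentric scope; its
  engagement is reported as `fv_clamped_fraction`, and the known
  consequence is that the Hill force decays with the activation envelope
  while the strain does not recover until the next contraction. Hill-model
  results are therefore quantitative on force development and steady
  state, and only qualitative during relaxation.
* **Pole guard.** `fv` is floored at `1e-3` before inversion to stay away
  from the `fv -> 0` pole (which maps to the maximum shortening speed).
* **Integration step.** 1 ms by default — at least 20 times faster than
  the 2 Hz envelope dynamics; when the input is sampled faster than
  `dt_int`, the input rate is used directly.
* **`vmax`.** Not fixed by the parameter table; the default is 10 optimal
  lengths per second, a standard mixed-fiber figure, exposed in the
  configuration and not asserted as a source value.

`hill_equilibrium()` provides an independent check: the steady state under
constant activation solves `kt Lc0 (-eps) = a Fm fl(eps)` by
`stats::uniroot`, and the simulated trace must land on it (the test-suite
verifies 0.1 % agreement across activation levels).

## The multi-scale cross-bridge model

Two-state kinetics with bond-length-independent rates: attachment `f = Uc`
during contraction on the attachment window, zero during relaxation;
detachment chosen so the total rate is `u + |eps_c_dot|`. Because the
rates do not depend on the bond coordinate, the first two moments of the
attached-bridge distribution close exactly into ODEs for the active
stiffness `kc` and force `Fc` — there is no Gaussian closure
approximation. The force–length relation acts microscopically, scaling the
available attachment sites: `km(eps) = km0 fl(eps)`, `Fm(eps) = Fm fl(eps)`.

* **The velocity term in the detachment rate** is implemented as
  `|eps_c_dot|` inside `(u + eps_c_dot)`. This is the single most
  consequential interpretation in the module. Two facts force it: faster
  sliding must *increase* the probability of breaking bridges in either
  direction, and the strain-rate equation obtained by equating the moment
  equation for `Fc` with the tendon rate equation carries a sign factor
  `S_eps_dot` in its denominator,
  `eps_dot = T / (kt Lc0 / cos(phi) + kc Lc0 - S Fc)` with
  `T = kt v_mt / cos(phi) + Fc u - alpha Fm(eps) Pi_c Uc`, which algebra
  reproduces only if the loss term is `(u + S eps_dot) = (u + |eps_dot|)`.
  The same reading makes the algebraic isotonic relation (below) the exact
  fixed point of the dynamics.
* **Isotonic force–velocity.** Setting `dFc/dt = 0` at optimal length
  gives `Fc = (alpha Fm Uc + kc0 Lc0 v) / (Uc - v)` for concentric
  `v < 0` — a Hill-type hyperbola with `A0 = Lc0 kc0 / (Uc alpha Fm)` and
  `B = 1/Uc`. Note the `Uc - v` denominator: it follows from the
  `|eps_dot|` loss term, and the acceptance suite confirms it equals the
  clamped-velocity steady states of the dynamic model to 1 %.
* **Chemical threshold.** Default 5 % of the MVC peak of the 30 Hz
  envelope: the indicator only needs to capture the contraction/relaxation
  timing ("a little above baseline"); the activation *level* is carried by
  the recruitment input, so the estimate is insensitive to the exact
  threshold. The indicator is delayed by the same electromechanical delay
  as the activation path.
* **Recruitment input.** `alpha(t) = p(t)` each sample by default
  (`continuous`). The alternative per-phase conventions (`hold_at_onset`,
  `hold_phase_max`) freeze `alpha` across each contraction run; the
  per-phase rule is ambiguous for long voluntary phases (which statistic
  of `p` defines the phase value?), so continuous is the default and all
  three are selectable.
* **State hygiene.** The state starts at rest `(0, 0, 0)`; `eps_c(0) = 0`
  also removes the bond-elongation offset term. `kc` and `Fc` are clipped
  at zero after each step (floating-point undershoot guard during fast
  relaxation; engagements counted). The series-elastic consistency
  condition `kt Lc0 / cos(phi) + kc Lc0 - Fc > 0` is checked at every
  evaluation and reported with the offending values and timestamp.

## The Huxley PDE oracle

`huxley_pde_moments()` integrates the transport–reaction equation for the
attached fraction `n(y, t)` on the bond-length axis: attachment on the
window `y in [0, 1]`, transport at `(S0/h) eps_c_dot`, detachment such
that the total rate is bond-length independent. The individual sarcomere
constants (`h`, `S0`, `k0`, motor-unit count) are never needed: only the
aggregates enter, and consistency with the macroscopic scales fixes the
transport gain `S0/h = km0 Lc0 / (2 Fm)`.

Numerically, each step is an exact exponential reaction relaxation
followed by first-order upwind transport, with a CFL check that names the
remedy. Two properties make this a sharp oracle rather than an
approximate one: upwind transport conserves the zeroth moment exactly and
commits only a boundary-order error in the first moment, and the reaction
substep is exact per cell; the remaining splitting error at 0.1 ms steps
is orders of magnitude below the 1 % comparison tolerance. The test-suite
compares the PDE moments with the ODE route on a contraction–relaxation
cycle with a prescribed sinusoidal strain rate (400-point grid, 0.1 ms
steps, 2 s — about two seconds of compute) and on analytic steady states
(`n -> fl` on the window, so `ks -> km0` and `Fs -> Fm`).

## The synthetic-EMG generator

The generator emulates the acquisition conditions the package targets:
2048 Hz sampling, two channels (GAS, SOL), MVC and 30 %/70 % plateau
trials, and randomized trials mixing fast-short bursts (~0.25 s) with
slow-long ramped contractions (~2.5 s with 0.8 s ramps). Fifty motor
units with recruitment thresholds spread over (0, 1) fire as renewal
processes (15 % inter-spike CV — a realistic interference pattern without
synchronization machinery); rates rise linearly with excitation above
threshold from 8 Hz and cap at 35 Hz; each firing adds a biphasic
Gaussian-derivative waveform (8 ms), a simple zero-mean shape with
controllable bandwidth.

MUAP amplitudes follow a mild size principle, `amplitude ∝ theta^0.25`.
The exponent is a calibrated design choice: a 50-unit pool stands in for
thousands of physiological units, and the sparse low-level interference
makes the rectified-envelope under-read low commands (the mean absolute
value of a spiky signal is below the Gaussian value for its power). The
quarter-power law compensates, making the 2 Hz envelope track the command
approximately linearly — the property real EMG amplitude approximately has
and that MVC normalization presupposes. The test-suite checks the 70 %
plateau envelope against 0.7 of the MVC envelope (10 %) and the doubling
property (15 %).

Ground-truth torque for round-trip tests is produced by running the
forward model on the *noise-free* command, so estimator error is separated
from fixture noise. What the generator does **not** emulate: volume
conduction and electrode geometry, motor-unit synchronization, fatigue,
signal nonstationarity, movement artifacts beyond what the high-pass
removes, and day-to-day electrode placement variability. Passing
round-trip tests therefore demonstrates internal consistency of the
pipeline under realistic interference statistics — not field accuracy on
recorded subjects.

## Evaluation conventions

Estimates and measurements are compared after dividing each by its own
MVC-trial peak (the estimate by the model's MVC-trial output, the
measurement by the measured MVC peak). Fast/slow windows for segment-wise
metrics come from the fixture's ground-truth labels — the protocol defines
the segments, not a detector. Peak error compares window maxima, so it is
insensitive to small alignment shifts. The contribution ratio is kept at
full precision internally and rounded to two decimals only for reporting.

## Problem sizes

The shipped tests and the acceptance script use: 2 s cycles at 0.1 ms for
the PDE/ODE comparison (400-point grid); 2–3 s runs at 1 ms for closed
forms, equilibria and clamped-velocity steady states; three ~9 s
round-trip trials plus MVC trials at 2048 Hz for the end-to-end check; a
single ~6 s MVC trial for shape-factor recovery. These sizes were chosen
so every property is resolved well inside its tolerance while a full run
completes in minutes on one CPU.

## Known limitations

* Isometric joints only; no joint-angle-dependent moment arms (the two
  printed values are used), no parallel elastic element, no eccentric
  force enhancement.
* Hill relaxation freezes CE strain (concentric-only clamp above).
* One model per muscle: no motor-unit populations, fiber-type mixtures or
  per-unit chemical dynamics; no explicit calcium model (the thresholded
  chemical input stands in for it).
* The cross-bridge model's stiffness scale `km0 = 20 Fm` barely affects
  isometric force, so it is effectively unidentifiable from the data the
  pipeline targets; it matters only for strain-rate coupling.
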