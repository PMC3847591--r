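# emgforce

Estimation of muscle force and isometric joint torque from surface
electromyography (EMG), for researchers in neuromuscular biomechanics,
rehabilitation and neuroprosthetics who need a tested, scriptable
EMG-to-force pipeline. The package implements and compares three models of
the contractile element (CE) inside one common muscle–tendon architecture
(CE in series with a linear tendon of stiffness *k<sub>t</sub>*, rotated by
the pennation angle *φ*; no parallel element, since the whole-unit length is
held fixed):

1. **Linear Hill model.** The conditioned EMG envelope *e(t)* (zero-lag
   Butterworth high-pass at 30 Hz, rectification, zero-lag low-pass at 2 Hz
   or moving average, MVC normalization) drives a delayed second-order
   recursion

   *p(t<sub>k</sub>) = γ e(t<sub>k−d</sub>) − β₁ p(t<sub>k−1</sub>) −
   β₂ p(t<sub>k−2</sub>)*,  β₁ = C₁ + C₂, β₂ = C₁C₂, γ − β₁ − β₂ = 1,

   and the CE force is *F<sub>c</sub> = a·f<sub>l</sub>(ε<sub>c</sub>)·
   f<sub>v</sub>(ε̇<sub>c</sub>)·F<sub>m</sub>* with *a = p*, a Gaussian
   force–length relation *f<sub>l</sub> = exp(−(ε<sub>c</sub>/b)²)* and a
   hyperbolic concentric force–velocity relation with parameters
   *V<sub>sh</sub>*, *v<sub>max</sub>*.
2. **Nonlinear Hill model.** As above, with the exponential shaping
   *a = (e^{Ap} − 1)/(e^{A} − 1)*, *A ∈ [−3, 0)*, which corrects the
   well-documented underestimation at low activation; *A* is the single
   subject-specific parameter and is calibrated on the MVC trial.
3. **Multi-scale cross-bridge model.** Two-state attachment/detachment
   kinetics of actin–myosin cross-bridges, triggered by a chemical input
   *u(t) = Π<sub>c</sub>U<sub>c</sub> + (1 − Π<sub>c</sub>)U<sub>r</sub>*
   (the contraction indicator *Π<sub>c</sub>* comes from thresholding the
   30 Hz EMG envelope) and scaled by a recruitment ratio *α(t) = p(t)*.
   Because the kinetic rates do not depend on the bond coordinate, the
   first two moments of the attached-bridge distribution — the active
   stiffness *k<sub>c</sub>* and force *F<sub>c</sub>* — obey closed ODEs:

   *k̇<sub>c</sub> = −(u + |ε̇<sub>c</sub>|)k<sub>c</sub> +
   α k<sub>m</sub>(ε<sub>c</sub>) Π<sub>c</sub> U<sub>c</sub>*,
   *Ḟ<sub>c</sub> = −(u + |ε̇<sub>c</sub>|)F<sub>c</sub> +
   α F<sub>m</sub>(ε<sub>c</sub>) Π<sub>c</sub> U<sub>c</sub> +
   k<sub>c</sub> L<sub>c0</sub> ε̇<sub>c</sub>*,

   coupled to the series tendon through an explicit strain-rate equation.
   A first-principles Huxley PDE solver for the full distribution is
   included as an independent oracle of these moment equations.

Per-muscle forces (gastrocnemius and soleus by default, with literature
parameters and printed moment arms 0.0515 m / 0.0464 m) are combined into
ankle plantar-flexion torque and compared with measured torque on an
MVC-normalized scale (RMS and peak-error metrics). A motor-unit-based
surface-EMG simulator generates fully synthetic, labelled trials (MVC,
30 %/70 % plateaus, fast-short and slow-long contractions) so the entire
pipeline is testable without recordings.

The key behavioral difference between the model families: in the
cross-bridge model the *derivative* of force is set by the neural command,
so force builds over the duration of a contraction (time hysteresis) —
a 0.2 s burst reaches much less force than a 2 s contraction of the same
EMG amplitude — while Hill-type force tracks the activation envelope and
peaks at nearly the same value for both.

## Worked example

```r
library(emgforce)

## maximal-torque contribution of each muscle at the ankle
round(contribution_ratio(joint_config()), 2)
#>  GAS  SOL
#> 0.41 0.59

## contraction-time hysteresis: equal-amplitude commands, 0.2 s vs 2 s
fs <- 512
burst <- function(dur) build_command(data.frame(
  label = c("rest", "burst", "rest"), duration = c(0.5, dur, 2.5),
  level = c(0, 0.6, 0), ramp = c(0, 0.02, 0.02)), fs)$command
for (m in c("hill_linear", "physio")) {
  r <- max(forward_torque(burst(0.2), m)$values) /
       max(forward_torque(burst(2.0), m)$values)
  cat(sprintf("%-12s short/long peak-torque ratio: %.2f\n", m, r))
}
#> hill_linear  short/long peak-torque ratio: 0.98
#> physio       short/long peak-torque ratio: 0.68

## round trip: synthetic EMG in, normalized torque out
trial <- generate_reference_trial(build_command(segments_plateau(0.7), 2048),
                                  synth_trial_config(seed = 1), "physio")
mvc   <- generate_reference_trial(build_command(segments_mvc(), 2048),
                                  synth_trial_config(seed = 2), "physio")
est <- estimate_torque(trial, mvc, model = "physio")
est
#> <torque_estimate> model = physio, 13312 samples, peak = 0.755 (normalized), MVC = 141.49 N m
measured <- uniform_series(trial$torque$values / max(mvc$torque$values),
                           dt = trial$torque$dt)
cat(sprintf("whole-trial RMS vs ground truth: %.3f\n",
            rms_error(est$torque, measured)))
#> whole-trial RMS vs ground truth: 0.046
```

The Hill model holds 98 % of its long-contraction peak on the short burst;
the cross-bridge model reaches only 68 % — the short burst genuinely
develops less force. The 70 %-of-MVC trial is recovered from noisy
synthetic EMG with a normalized RMS error under 0.05.

## Command line

A thin wrapper over the package functions lives in `inst/cli/emgforce.R`:

```sh
Rscript inst/cli/emgforce.R synth --config cfg.yaml            # 5 labelled trials
Rscript inst/cli/emgforce.R estimate --trial trials/plateau30.csv --config cfg.yaml
Rscript inst/cli/emgforce.R compare  --trial trials/random1.csv --config cfg.yaml
Rscript inst/cli/emgforce.R calibrate-A --config cfg.yaml
```

The YAML config selects the model and all shared parameters (see
`?load_run_config`); one config drives all models so comparisons share
every common parameter.

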