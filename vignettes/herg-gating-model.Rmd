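---
title: "A deterministic nucleation-and-growth model of hERG gating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A deterministic nucleation-and-growth model of hERG gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hergng)
```

## The model

The hERG (Kv11.1) potassium channel shapes the repolarization of the
cardiac action potential.  Its gating cycle involves four transitions:
slow activation (the stepwise outward movement of the four S4 voltage
sensors), fast inactivation (collapse of the selectivity filter),
fast recovery on repolarization, and slow deactivation (plugging of the
open pore by the channel's own N-terminal "endogenous blocker").
Markov-chain treatments of this cycle typically need well over ten free
parameters.  The model implemented here is deterministic and needs one
or two: it assumes the potassium flux grows in proportion to the number
of S4 sensors that have moved out, and treats the accumulation of 'out'
sensors as a two-dimensional nucleation-and-growth (aggregation)
process on the membrane.

Writing $S \in [0,1]$ for the fraction of subunits whose S4 is out —
which is also the gating charge normalized to unity — the kinetics are
the classical Avrami bookkeeping.  Clusters of 'out' subunits nucleate
at rate $k_N$ and their radii grow at rate $k_R$, both in proportion to
the coverage $\theta\,p\,(1-S)$ by 'in' subunits available to move,
where $p$ is the steady-state open probability at the applied potential
and $\theta$ the (unit) subunit coverage.  Repeated differentiation of
the extended-area double integral reduces the model to four ODEs,

$$\frac{dS_x}{dt} = 2\pi k_R\,p f_1 f_2, \qquad
  \frac{df_2}{dt} = k_R\,p f_1 f_3, \qquad
  \frac{df_3}{dt} = k_N\,p f_1, \qquad
  \frac{dS}{dt} = (1-S)\frac{dS_x}{dt},$$

with $f_1 = \theta(1-S)$.  $S_x$ is the *extended* area (cluster
overlap ignored); the last equation is the Avrami correction and is
equivalent to $S = 1 - e^{-S_x}$, an identity the integration tests
verify to below $10^{-6}$ along every trajectory.  The nucleus size is
one subunit: no threshold machinery exists, and nucleation is simply
the first S4 moving out.

Two algebraic maps turn $S(t)$ into currents:

* **outward**: $I_{out} = \mathrm{scale}\;\theta\,p_{act}(\phi)\,S(t)\,
  y(\phi)$, where $y(\phi) = -0.00944\,\phi + 0.472$ is the empirical
  linear damping factor representing fast inactivation, clamped to
  $[0,1]$;
* **inward**: $I_{in} = -\mathrm{scale}\;\theta\,p_{in}(\phi)\,S(t)\,
  (1 - e^{-k_h(1-S(t))})$, where the last factor is the driving force
  of slow deactivation: the Coulomb attraction pulling the positively
  charged N-terminal blocker into the pore grows with the charge the
  departing S4 segments leave behind, i.e. with $S$ itself, and $k_h$
  collapses that interaction into a single dimensionless decay
  constant.

The gating current is $dS/dt$, taken from the ODE right-hand side
rather than by differencing.

Each computation uses its own experimentally fitted Boltzmann curve as
$p$, both inside the ODE and in the prefactor: activation
($z = 2.4$, $\phi_{1/2} = -5.6$ mV) for outward currents, the inward
open probability ($z = 2.2$, $\phi_{1/2} = -9$ mV) for inward ones.
The steady-state inactivation curve ($z = 1.1$, $\phi_{1/2} = -82$ mV,
decreasing) is available for an optional multiplicative correction of
inward traces by the recovered fraction $1 - p_{inact}(\phi)$; it is
off by default because the inactivation curve is already small at
potentials where the channel conducts, and because applying it
silently would hide a modelling judgement the user should make.  The
Boltzmann sigmoid is the standard single-gate form
$1/(1 + e^{\mp z(\phi - \phi_{1/2})/V_T})$ — the only form consistent
with both the published pre-exponential $a = e^{-z\phi_{1/2}/V_T}$ and
a half-maximum at $\phi_{1/2}$ — with the thermal voltage fixed at
25.6 mV exactly as published, not recomputed from temperature.

## Parameters

| parameter | units | default | meaning |
|---|---|---|---|
| `k_N` | s$^{-1}$ | $10^2$ | nucleation rate constant (rate of a single S4 moving out) |
| `k_R` | s$^{-1}$ | $10^5$ | radial growth rate constant of an 'out' cluster |
| `theta` | — | 1 | subunit surface coverage; formally set to unity |
| `k_h` | — | 1 | blocker decay constant of the inward driving force |
| `scale` | a.u. | 1 | amplitude conversion factor to experimental units |

Only the product $k_N k_R^2$ (default $10^{12}\ \mathrm{s^{-3}}$)
enters $S(t)$ — rescaling $(k_N, k_R) \to (a k_N, a k_R)$ rescales
time exactly, a property the tests assert numerically — so the
simulation of an outward family has a single free parameter, and an
inward family has two ($k_N k_R^2$ and $k_h$), plus the amplitude
scale.  `rates_from_product()` realises a given product with `k_N`
held at its default.  All times are in seconds; potentials in mV.

The standard protocol steps from a holding potential of $-110$ mV
(where $p_{act} \approx 6\times10^{-5}$: the channel is shut and the
ODE state starts at zero) to the five potentials $-50, -30, -10, +10,
+30$ mV.

## Numerical choices

* **Integrator.** Classical fixed-step fourth-order Runge–Kutta, the
  method named by the model's formulation, with the open probability
  constant per segment.  The default step is `duration/5000`.
  `solve_gating()` repeats the integration at half the step and stores
  the change in $S(\mathrm{end})$ as a convergence diagnostic
  (`converged` when below $10^{-6}$, a warning above $10^{-4}$).  The
  suite cross-checks the integrator against an independent adaptive
  solver (`deSolve::lsoda` at `rtol = 1e-10`) to below $10^{-5}$ in
  $S$.
* **Time scales.** With the default rates, $S$ rises on a time scale
  $\left((\pi/3)k_Nk_R^2 p^3\right)^{-1/3}$, from ~0.1 ms at $+30$ mV
  to ~5 ms at $-50$ mV.  Saturation is algebraic, not exponential:
  near $S = 1$, $dS/dt \propto (1-S)^2$, so $1-S$ decays like $1/t$.
  End-of-pulse "asymptote" checks therefore use 50 ms pulses and
  per-mille tolerances rather than machine precision.
* **Short-time law.** For small $S$,
  $S \approx (\pi/3)k_Nk_R^2(\theta p)^3 t^3$.  The exact expansion is
  $S = a t^3(1 - \tfrac{5}{4}a t^3 + O(S^2))$ with
  $a = (\pi/3)k_Nk_R^2(\theta p)^3$, so the cubic law's relative error
  is $\tfrac54 S$: about 0.6% at $S = 5\times10^{-3}$ and already
  ~1.3% at $S = 10^{-2}$.  The property tests assert the law where it
  actually holds to 1% ($S < 5\times10^{-3}$).
* **Charge bookkeeping.** `gating_charge()` integrates $dS/dt$ by
  composite Simpson quadrature; at `dt = 1e-6` over the 300 ms
  square-wave segment the quadrature agrees with $S(\mathrm{end})$ to
  well below $10^{-6}$.
* **OFF step of the square wave.** The formalism only describes
  depolarising segments.  The repolarising (OFF) transient is modelled
  by the same ODE system applied to the returning fraction $S'$ with
  $p_{off} = 1 - p_{act}(\phi_{hold})$, and reported as
  $-S_{ON}(\mathrm{end})\,dS'/dt$.  This guarantees ON/OFF charge
  balance by construction and is a modelling choice that goes beyond
  the forward model; it is not a fit to deactivation data.  A step to
  the holding potential itself is special-cased to a zero trace: the
  solver describes perturbations from holding equilibrium, and without
  a potential change there is nothing to relax.
* **Degenerate inputs.** Potentials beyond $+50$ mV clamp the damping
  line at 0 and outward traces are reported as identically zero with a
  warning; non-finite potentials are rejected; `dt` must resolve the
  segment (`dt <= duration/100`); all-zero traces get a flagged
  $(0, 0)$ peak.

## Parameter estimation

`herg_fit()` minimises the sum of squared residuals between model and
data over log-parameters (so estimates stay positive) with
Levenberg–Marquardt (`minpack.lm::nls.lm`), integrating the ODE
directly on each trace's time grid.  Outward fits estimate
$(k_Nk_R^2, \mathrm{scale})$; inward fits add $k_h$.

Residual weighting is uniform by default.  The synthetic generator's
noise is homoscedastic — one standard deviation for the whole family,
expressed as a fraction of the family's maximum current — and for such
noise ordinary least squares is the efficient estimator.  The
alternative `weighting = "trace_max"` normalises each trace by its own
peak, which equalises the visual influence of small and large traces
but up-weights the smallest, noise-dominated traces (at $-50$ mV the
family-level noise is over half that trace's peak) and measurably
degrades recovery of both $k_Nk_R^2$ and $k_h$; it is appropriate when
noise genuinely scales with each trace's amplitude.

$k_h$ and the scale are strongly correlated along the decaying limb
(where the driving force is nearly linear in $1-S$), so single-dataset
$k_h$ estimates at 2% noise scatter with a relative spread of roughly
10–20%; the median error across repeated noise realizations is under
10%, and that median is what the acceptance suite asserts.

## What the generator does and does not emulate

`generate_synthetic()` produces model traces at known parameters with
additive white Gaussian noise, reproducible under a seed and with the
caller's RNG state restored.  It emulates the amplitude structure and
time courses of voltage-clamp current families; it does **not**
emulate capacitive transients, leak or endogenous background currents,
series-resistance artifacts, correlated (1/f or line-frequency) noise,
or cell-to-cell variability of the Boltzmann parameters.  Passing the
recovery tests therefore shows identifiability of
$(k_Nk_R^2, k_h, \mathrm{scale})$ under the model's own assumptions,
not robustness of the estimator to real recording artifacts.

Problem sizes throughout the suite are the package defaults: 5-potential
families of 50 ms traces at 10 µs sampling (5001 samples per trace),
and 20 noise realizations for the recovery experiment.

## Known limitations

* The damping line is an empirical fit over roughly $-40$ to $+40$ mV;
  outside it the clamp to $[0,1]$ is a pragmatic extrapolation, and the
  line is frozen rather than refit per dataset (slope and intercept are
  exposed as configuration).
* The OFF-step construction above is the package's own; experimental
  deactivation time constants (mono- or biexponential fits) are not
  modelled, and the shoulder sometimes seen after the ON peak of
  gating currents is not reproduced.
* Only piecewise-constant voltage protocols are supported — no ramps
  and no action-potential clamp — and currents are in arbitrary units
  (one multiplicative scale; no capacitance normalization).
* Stochastic single-channel behaviour is out of scope by design; the
  model is deterministic.
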