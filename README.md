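# hergng

Deterministic nucleation-and-growth simulation of hERG (Kv11.1)
potassium-channel gating, for electrophysiologists and modellers who
want the channel's outward and inward K⁺ current families, gating
currents and activation kinetics from one or two free parameters
instead of the ten-plus of Markov gating schemes.

## The model

The four S4 voltage sensors of the channel move outward stepwise under
depolarization, and the K⁺ flux is assumed to grow in proportion to the
number of 'out' sensors.  Treating the accumulation of 'out' subunits
as two-dimensional nucleation and growth gives four ODEs for the
normalized gating charge *S* (the covered fraction), the extended area
*S*ₓ and two auxiliary integrals *f₂*, *f₃*:

    dSx/dt = 2π kR p f1 f2     df2/dt = kR p f1 f3
    df3/dt = kN p f1           dS/dt  = (1 − S) dSx/dt,   f1 = θ(1 − S)

with the Avrami identity *S* = 1 − exp(−*S*ₓ) built in, *p* the
Boltzmann steady-state open probability at the step potential, and
*k*_N = 10² s⁻¹, *k*_R = 10⁵ s⁻¹ (only the product *k*_N*k*_R² = 10¹²
s⁻³ matters).  The system is integrated by classical fixed-step RK4.
Currents follow algebraically:

    outward:  I =  scale · θ p_act(φ) S(t) · (−0.00944 φ + 0.472)
    inward:   I = −scale · θ p_in(φ)  S(t) · (1 − exp(−k_h (1 − S(t))))

where the linear factor is the empirical fast-inactivation damping
(clamped to [0, 1]) and the last inward factor is the driving force of
slow deactivation by the channel's N-terminal blocker, with a single
dimensionless constant *k*_h.  The gating current is d*S*/d*t*.  The
three built-in Boltzmann parameter sets are the published hERG fits:
activation (z = 2.4, φ½ = −5.6 mV), inactivation (z = 1.1, φ½ = −82
mV, decreasing) and the inward open probability (z = 2.2, φ½ = −9 mV).

The package also generates synthetic noisy trace families and recovers
(*k*_N*k*_R², *k*_h, scale) from traces by Levenberg–Marquardt least
squares in log-parameter space (`herg_fit()`, a classed model object
with `print`/`summary`/`coef`/`predict`/`plot`/`residuals`/`simulate`
methods).

## Worked example

```r
library(hergng)

# published Boltzmann prefactors a = exp(-z*phi_half/25.6)
sapply(herg_curves(), boltzmann_prefactor)
#>              activation            inactivation inward_open_probability
#>                1.690459               33.900762                2.167203

# gating charge at a -10 mV step
solve_gating(phi = -10, duration = 0.05, dt = 1e-5)
#> Gating trajectory: phi = -10 mV, p = 0.3983, 5001 samples over 0.05 s
#>   S(end) = 0.999523; dt = 1e-05 s; converged: TRUE

# inward current family over the standard five step potentials
current_family(voltage_step_protocol(), "inward", k_h = 1)
#> inward current family, 5 traces:
#>   phi =  -50 mV: peak -0.0057118 a.u. at t = 0.00405 s
#>   phi =  -30 mV: peak -0.028164 a.u. at t = 0.00082 s
#>   phi =  -10 mV: peak -0.095378 a.u. at t = 0.00024 s
#>   phi =  +10 mV: peak -0.16674 a.u. at t = 0.00014 s
#>   phi =  +30 mV: peak -0.1926 a.u. at t = 0.00012 s

# recover the parameters from a noisy synthetic family
fit <- herg_fit(generate_synthetic("inward", noise_sigma = 0.02, seed = 42))
fit
#> hERG gating-model fit (inward current, 5 traces)
#>    k_NkR2       k_h     scale
#> 1.041e+12 1.145e+00 8.904e-01
#> residual norm 0.6142 (data norm 1.422); converged in 4 iterations
```

The prefactors are the constants quoted with the experimental curve
fits; the peak inward currents grow with depolarization (the model's
signature behaviour) while each trace rises as the channel opens and
decays as the blocker plugs the pore; the fit recovers the generating
values *k*_N*k*_R² = 10¹², *k*_h = 1, scale = 1 to within the sampling
scatter of a single 2%-noise realization.

A command-line wrapper around the same functions is installed at
`system.file("cli/herg.R", package = "hergng")` with subcommands
`steady-state`, `gating`, `simulate`, `family`, `synth` and `fit`
writing CSV traces plus JSON metadata sidecars.

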