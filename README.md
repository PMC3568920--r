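# cleftsim

Monte Carlo simulator of **glutamate electrodiffusion in the synaptic
cleft** of the cerebellar mossy-fiber → granule-cell (MF-GC) synapse.

Glutamate carries a net charge of −1, and the synaptic currents it evokes
flow through a 16-nm-high, electrically resistive cleft. The resulting
intracleft electric field acts back on the transmitter: currents at a
hyperpolarized holding potential push the anion out of the cleft, while a
depolarization — a voltage step or a single postsynaptic action potential
(AP) — transiently retains it. cleftsim couples

- **Brownian particle dynamics** of 3,000 released molecules (fixed-length
  steps `sqrt(6 D dt)`, two-zone diffusivity 0.25/0.4 µm²/ms, reflective
  glomerular cuboid lattice, absorbing shell),
- the **steady-state cleft voltage profile** of the thin-disc cable
  problem, `V(r) = Vo·I0(r/λ)/[I0(L) + L·I1(L)·ln(R/ra)]` inside the
  active zone (logarithmic continuation outside), with shunt parameter
  `L = sqrt(γNP·Rex/(πδ))` set by the instantaneous open conductance, and
  drift velocity `v_r = μ·dV/dr`, `μ = DqF/RT`,
- **mean-field Markov kinetics** of 125 AMPARs (10 pS), 50 NMDARs (25 pS)
  in the 160-nm PSD and perisynaptic mGluR1s on a 15-nm annulus at 360 nm
  diameter, propagated by an exact uniformization stepper, with
  competitive-antagonist (γ-DGG) and fractional-block (NBQX) transforms
  and Q10 temperature scaling,
- **intracleft ion bookkeeping** (Na⁺/K⁺/Cl⁻ perturbed by the channel
  currents, diffusing radially against bath-clamped edges), and
- a **membrane-potential process** (holding voltages plus template or
  Hodgkin-Huxley AP waveforms)

into a deterministic 0.1-µs duty cycle, and ships the virtual experiments
of the underlying study: voltage sweeps, spike-release pairing, γ-DGG /
NBQX antagonist runs, driving-force (NMDG-style) scaling, and timestep
convergence. Intended users are synaptic biophysicists exploring how
sub-millisecond electric fields shape transmitter escape and perisynaptic
receptor activation.

## Worked example

A single release at −70 mV with all defaults:

```r
library(cleftsim)
ts <- run_simulation(list(run = list(seed = 1)))
ts
#> TraceSet: 50000 steps of 0.1 us (5 ms), seed 1, 3.77 s wall
#>   peak |I_AMPAR| 22.2 pA | peak |I_NMDAR| 10.4 pA | peak mGluR1 activation 0.19
#>   cleft count 3000 -> 1 | max ion perturbation 26.4%
```

The EPSC peaks near −22 pA (the amplitude scale of a single MF-GC
connection), the in-cleft molecule count decays from 3,000 over a couple
of milliseconds, the perisynaptic mGluR1s reach ~0.19 peak activation, and
the K⁺ level in the postsynaptic-density bins is transiently perturbed by
~26% relative to its 3 mM bath value (K⁺ shows the largest relative change
because its baseline is low; Na⁺ moves by only a few percent of 151 mM).
Fitting the decay and pairing with a spike:

```r
fit_decay_tau(ts$traces)$tau_ms        # mono-exponential EPSC decay (ms)
#> [1] 0.5491764

pr <- protocol_ap_pairing(list(), seeds = 1:10)   # ~2 min on one core
mean(pr$fold_per_seed)                 # AP-driven tail fold-change
#> [1] 2.983324
```

The pairing protocol simulates each seed twice — with and without an AP
whose onset leads release by 0.5 ms — and reports how the AP transiently
multiplies the number of molecules remaining in the cleft (the tail
fold-change), together with the peak AMPAR/NMDAR open probabilities (which
the AP shifts by only a few percent) and the perisynaptic mGluR1
activation (which it boosts). `run_protocol()` dispatches the other
virtual experiments by name.

A command-line front end is available for shell use:

```sh
Rscript scripts/cleftsim run --seed 1 --out out/ --duration 2
Rscript scripts/cleftsim run --protocol voltage_sweep --seed 1 --out sweep/
```

## Configuration

Every model constant lives in a nested configuration (JSON or YAML on
disk, a plain list in R); `default_config()` documents the full set, and
partial configurations are merged over it with unknown keys rejected.
Receptor kinetic schemes are JSON parameter files
(`inst/extdata/schemes/`) with **generic placeholder rate constants** —
see the methods vignette (`vignettes/cleft-electrodiffusion.Rmd`) for the
model description, the calibration of the one free constant (the
intracleft resistivity `Rex`), numerical choices and known limitations.
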