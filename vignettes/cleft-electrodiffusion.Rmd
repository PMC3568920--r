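---
title: "Modeling glutamate electrodiffusion at the mossy-fiber/granule-cell synapse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling glutamate electrodiffusion at the mossy-fiber/granule-cell synapse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

cleftsim simulates what happens to a packet of glutamate released into the
16-nm synaptic cleft of a cerebellar mossy-fiber/granule-cell (MF-GC)
synapse when the receptor currents it evokes are themselves allowed to act
back on it. Glutamate carries a net charge of −1 at physiological pH, so
the electric field generated by synaptic currents in the thin, resistive
cleft biases its escape: currents at a hyperpolarized holding potential
push the anion out of the cleft, and a depolarization — a voltage-clamp
step or a single postsynaptic action potential (AP) — transiently pulls it
back. Because perisynaptic metabotropic receptors (mGluR1) sit outside the
cleft and sense the late, low-micromolar tail of the transient, a brief
retardation of escape can change their activation substantially while
leaving the nearly saturated intrasynaptic AMPARs and NMDARs almost
untouched. That dissociation — AP retards escape, mGluR1 activation is
boosted, AMPAR/NMDAR activation is not detectably changed — is the central
prediction the simulator reproduces, together with the voltage asymmetry of
the EPSC decay and its collapse when the driving force or the field
feedback is removed.

Three coupled descriptions run on a common 0.1-us clock (the "duty
cycle"); each step performs, in this order:

1. **Particles.** Each of the 3,000 released molecules takes a Brownian
   step of fixed length sqrt(6 D dt) in a uniformly random 3-D direction
   (D = 0.25 um^2/ms inside the crowded cleft, 0.4 um^2/ms in the
   glomerular space), plus, while inside the cleft, a radial drift
   displacement mu E dt from the previous cycle's field. Membranes and
   neighboring structures reflect; an absorbing shell at 1.5 um stands in
   for glomerular dilution and uptake.
2. **Concentration.** In-cleft molecules are binned into 20-nm annuli
   around the release axis, giving the radial profile C(r, t) in mM.
3. **Receptors.** Every receptor propagates its Markov state-probability
   vector under its bin's concentration (mean-field master equation).
4. **Currents, ions, field.** Open probabilities yield per-type currents
   I = N gamma P_open (Vm − Erev); the channel currents perturb the
   pre-equilibrated intracleft Na+/K+/Cl− pools; and the total open
   conductance sets the next cycle's voltage profile.

## The intracleft field

Under rotational symmetry the steady-state voltage profile in a thin
resistive cleft shunted by an open conductance spread over the active zone
(radius `ra`) is the classic two-branch Bessel/logarithm solution

\[
V(r) = V_o \frac{I_0(r/\lambda)}{I_0(L) + L I_1(L)\ln(R/r_a)}, \quad r < r_a
\]
\[
V(r) = V_o \frac{I_0(L) + L I_1(L)\ln(r/r_a)}{I_0(L) + L I_1(L)\ln(R/r_a)}, \quad r_a < r < R
\]

with \(L = \sqrt{\gamma N P\, R_{ex} / (\pi \delta)}\) and
\(\lambda = r_a / L\). Here \(\gamma N P\) is the instantaneous total open
conductance, \(R_{ex}\) the extracellular resistivity of the cleft,
\(\delta\) the cleft height, and \(V_o\) the membrane potential outside the
cleft. \(V(r)\) is the *local transmembrane driving potential* (it equals
\(V_o\) at the edge where the extracellular potential vanishes); the
extracellular cleft potential is \(\phi(r) = V_o - V(r)\), and it is
\(\phi\) whose gradient exerts the in-plane force on the charged
transmitter:

\[
v_r = -\mu \frac{d\phi}{dr} = \mu \frac{dV}{dr}, \qquad
\mu = \frac{D q F}{R T}.
\]

With \(q = -1\), this retains glutamate when the cleft interior is
relatively depolarized (positive \(V_o\), or a depolarizing spike riding on
a negative holding potential) and expels it at hyperpolarized potentials —
the sign structure behind every directional result of the model: the decay
asymmetry \(\tau_{+40} > \tau_{-70}\), its collapse when the field feedback
is disabled or the driving force reduced, and the AP-driven retardation of
escape. The square-rooted form of \(L\) is the radial cable solution of the
thin-cleft problem (\(\lambda = \sqrt{\delta/(g_A R_{ex})}\) with \(g_A\)
the open conductance per active-zone area).

The field is recomputed once per duty cycle from the aggregate open
conductance and held constant within the cycle (the spatial relaxation of
the field is orders of magnitude faster than diffusion); each cycle's
displacement uses the previous cycle's field.

### The cleft resistivity `Rex`

All parameters of the field except \(R_{ex}\) are fixed by the synapse
(\(\delta\) = 16 nm, \(r_a\) = 80 nm, \(R\) = 300 nm, 125 x 10 pS + 50 x
25 pS channels). \(R_{ex}\) — the effective resistivity of the
glycoprotein-packed cleft interior — is not measurable directly and is the
single calibration constant of the model. Its choice matters because the
well depth \(\phi(0)\) scales with \(L^2 \propto R_{ex}\) at small L:
with bulk-tissue resistivity (~250 Ohm cm) the maximal well is below 1 mV
(≪ kT/e = 26 mV) and every electrodiffusive readout of the model is a
sub-5% effect, which contradicts the multi-fold AP-driven retardation this
synapse model is known to produce. We therefore calibrated \(R_{ex}\)
against that printed model outcome (a 3-4x tail fold-change under
AP pairing) over a sweep `Rex in {250, 1000, 2500, 5000} Ohm cm` — the
sweep can be re-run with `protocol_ap_pairing()` at each value — and ship
the calibrated value as the default (see `default_config()`), documented
here and exposed in the `field` config block. Crowding-based estimates of
intracleft resistivity an order of magnitude above bulk are physically
plausible for a 16-nm gap occupied by adhesion complexes; users who prefer
the conservative bulk value can set it and will obtain a qualitatively
identical but much weaker field coupling.

## Geometry

The glomerular environment is a square lattice of pre/postsynaptic cuboid
pairs (600 x 600 nm footprint) separated by 50-nm gaps; the central pair
encloses the 16-nm cleft with a 160-nm PSD carrying 125 AMPARs and 50
NMDARs and a perisynaptic annulus (15 nm wide, 360 nm diameter) carrying
the mGluR1s (count not known anatomically; default 30, config-exposed).
The cuboid height is set to the escape radius (1.5 um), so the
neighborhood is a network of 50-nm channels — a packed glomerulus. This
choice is deliberate: with short cuboids the space above and below the
structure layer is open half-space, released glutamate dilutes
irreversibly within ~1 ms, and the cleft tail that the perisynaptic
receptors read out dies out an order of magnitude too fast compared with
the 1-2 ms transients this synapse sustains. The field formula assumes
rotational symmetry while the environment is cuboid; the field is
evaluated in the equivalent radial coordinate and switched off in the
square corners beyond r = 300 nm.

## Receptor kinetics

Receptors are propagated as mean-field state-probability vectors — the
average occupancy of each state of the kinetic scheme — rather than by
stochastic single-channel gating. Schemes live in JSON parameter files
(`inst/extdata/schemes/`): a 6-state AMPAR (two sequential glutamate
bindings, one open state, desensitized states off the mono- and
double-liganded closed states), a 5-state NMDAR (two bindings, slow
unbinding, one open and one desensitized state) and a 3-state mGluR1 chain
(rest -> bound -> active, the topology of conformational-FRET readouts of
mGluR1 activation). The mGluR1 chain uses GPCR-like kinetics — ligand
binding an order of magnitude slower than at ionotropic receptors
(1e6 /M/s, Kd 100 uM) and a slow conformational step — so a brief synaptic
transient activates the perisynaptic receptor sub-maximally and the late
(tail) glutamate, the part of the transient the field acts on most,
controls its response. **The shipped rate constants are generic, physiologically shaped
placeholders** (round numbers giving sub-ms AMPAR activation, ~0.5 ms
deactivation, ms-range desensitization, slow NMDAR kinetics); the sources
that published fitted constants for this synapse should be consulted for
quantitative receptor-level work, and any scheme in the same JSON format
can be dropped in. NMDAR and mGluR1 rates are referenced to room
temperature and scaled by Q10 = 2 to the 33-35 C (307 K) default;
the AMPAR file is already referenced to 307 K.

Antagonists: the low-affinity competitive blocker (gamma-DGG, Kd = 1 mM
with fast dissociation) is modeled by `add_competitive_antagonist()`,
which builds the product scheme in which antagonist molecules occupy
agonist sites of every state that has free sites, with statistical-factor
bookkeeping; its relative block falls as the glutamate transient grows,
which is what makes it a reporter of intracleft concentration. The
high-affinity blocker (NBQX) is a concentration-independent fractional
removal of conducting receptors (`block_fraction()`). NMDAR Mg2+ block is
off by default (recordings in zero Mg2+); a standard voltage-dependent
block factor can be enabled via `receptors$mg_mM`.

### Numerical propagation

The point release puts all 3,000 molecules in the innermost bin for the
first few steps, so local binding rates transiently reach
\(k_{on} C \sim 10^6\,/ms\) and \(\Lambda dt\) of order \(10^2\): plain
forward Euler diverges there no matter how small its guard. The engine
therefore advances each state vector with the uniformization
(randomization) expansion of \(\exp(Q\,dt)\) — a positivity- and
probability-preserving series that is exact to machine precision for the
within-step-frozen generator, with internal splitting when \(\Lambda dt\)
is very large. `step_occupancy()` also provides the plain Euler stepper
with a stability guard (`max exit rate x dt < 0.1`) for reference and
testing. Receptors of one type whose positions fall in the same 20-nm
concentration bin follow identical dynamics and are collapsed into one
state vector with a count.

## Ions

The ion module tracks Na+, K+ and Cl− on the same radial grid,
pre-equilibrated to the recording solution (Na 151.25, K 3, Cl 135 mM from
124 NaCl + 26 NaHCO3 + 1.25 NaH2PO4 + 3 KCl + divalent chlorides). Each
channel's current is split into per-ion components by configurable
conductance fractions with per-ion reversal potentials (defaults
f_Na = f_K = 0.5, E_Na = +65 mV, E_K = −95 mV): at −70 mV the nonselective
cation channels carry Na+ into the cell (depleting the cleft) and K+ out
of it (enriching the cleft — and because the K+ bath level is only 3 mM,
K+ shows the largest *relative* perturbation). Cl− redistributes
electroneutrally with the net cation change. Bins mix by explicit
conservative radial diffusion (in-cleft ion D halved from free solution
for crowding, config-exposed) with the edge bin clamped to bath, and the
solver substeps automatically to respect the explicit-diffusion stability
bound. This module is a deliberately simple, config-driven approximation —
its role in the model is the summary perturbation magnitude, and its
feedback on the synaptic currents is not modeled (consistent with the
finding that the perturbation has little effect on the currents).

## Membrane

`membrane_protocol()` provides Vm(t): a holding potential overridden by AP
events. The default AP is a closed-form biexponential template (rise
0.2 ms, decay 0.6 ms, peak +30 mV, ~2.5 ms event, linearly tapered to end
exactly at the holding level); an `hh` mode integrates the standard
single-compartment Hodgkin-Huxley equations (RK4, fixed step) and offsets
the spike onto the holding level — adequate because the granule cell is
electrically compact and its AP waveform is nearly uniform across
compartments. The spike-release pairing protocol places the AP onset
0.5 ms before release, matching the physiological pairing experiments.

## Randomness and determinism

All particle randomness comes from counter-based per-particle streams:
each draw is a pure hash of (seed, particle id, step, counter). Runs are
bit-reproducible, independent of particle update order, resumable
(`step_duty_cycle()` continues a run bit-identically), and two runs
sharing a seed share per-particle streams regardless of their time step —
the variance-reduction device used by the convergence protocol. No run
proceeds without an explicit seed.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `run$dt_ms` | 1e-4 | ms | engine clock (0.1 us); convergence protocol quantifies its residual |
| `run$duration_ms` | 5 | ms | covers the full fast transient; tails are flat afterwards |
| `geometry$cleft_height_nm` | 16 | nm | cleft height delta; enters both the field (L, 1/sqrt(delta)) and escape |
| `particles$n_released` | 3000 | — | released glutamate |
| `particles$D_cleft/D_out` | 0.25 / 0.4 | um^2/ms | two-zone effective diffusivity |
| `field$rex_ohm_cm` | 2500 | Ohm cm | intracleft resistivity; the calibrated constant (see above) |
| `field$temperature_K` | 307 | K | 33-35 C; also drives Q10 scaling |
| `receptors$n_ampar/n_nmdar/n_mglur` | 125/50/30 | — | receptor complements (mGluR count is a config default) |
| `ions$f_na, f_k, e_na, e_k` | 0.5/0.5, +65/−95 | —, mV | per-ion split of channel current |
| `membrane$ap_*` | +30 mV, 0.2/0.6 ms | | template spike shape |

## What the simulations do and do not show

The engine *is* the data generator: every quantitative statement in the
README and the acceptance outputs is recomputed at run time from these
rules. The model emulates a single release site at an idealized cuboid
synapse with uniform receptor zones; it does not include multiple release
sites, reconstructed glomerular anatomy, astrocytic uptake kinetics,
transporter binding, inter-particle electrostatics, stochastic
single-channel gating, downstream G-protein signaling or the
mGluR-to-NMDAR facilitation itself — the model's role ends at mGluR1
activation. Receptor-level magnitudes inherit the placeholder rate
constants; the package's quantitative surface is therefore the
*electrodiffusive* observables (escape curves, fold-changes, decay
asymmetries, ion perturbations, convergence), which are robust to
reasonable rate choices, and the directional receptor dissociation, not
absolute open probabilities.

## Problem sizes used by the shipped tests and acceptance script

The acceptance script runs the pairing protocol at full scale (3,000
molecules, dt = 0.1 us, 10 seeds x 2 conditions, 5 ms post-release), one
default EPSC run for the ion summary, and the convergence pair over a 2-ms
window at dt = 0.1 and 0.01 us with 10 seeds per step size (the per-seed
peak has ~1% Monte Carlo scatter, so the sub-percent discretization
residual is resolved by averaging). The test suite exercises the
same protocols at full particle count but the voltage-sweep family over a
3-ms window (2 ms for the exactly voltage-independent field-off controls),
and uses miniature configurations (hundreds of molecules, coarsened clock)
for engine contracts; these sizes are stated here as the package's choices
for a desk-scale machine and can all be raised by config.

## Known limitations

- The cuboid/radial hybrid: the field is rotationally symmetric while the
  geometry is square; in the corner regions the drift is switched off.
- The mean-field receptor description ignores binding-site depletion of
  free glutamate (receptor sites are few relative to 3,000 molecules) and
  channel-noise correlations.
- The ion module does not feed back into the field solution (the field
  uses Vo and conductance only).
- `Rex` is a calibrated constant, not a measurement; all field-dependent
  magnitudes scale monotonically with it.
- The biexponential AP template is a surrogate; HH mode is provided but
  its parameters are the classic squid set offset to the holding level,
  not a granule-cell fit.
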