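---
title: "Kinetic modelling of monoamine transporter cycles with slc6sim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of monoamine transporter cycles with slc6sim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(slc6sim)
```

## The model

The plasmalemmal monoamine transporters DAT, NET and SERT (SLC6 family)
move their substrates uphill by coupling translocation to the
transmembrane Na⁺ gradient. `slc6sim` represents each transporter as a
Markov state model of the alternating-access cycle: a set of
conformational states joined by reversible transitions, each transition
carrying

* base forward/reverse rate constants `k0` (s⁻¹, or M⁻¹s⁻¹ for
  ligand-coupled directions),
* an *equivalent charge* `zQ` — the number of elementary charges moved
  inward across the membrane field during the forward step, and
* optional ligand couplings: the concentration of a named species on a
  named side multiplies that direction's rate (sequential, bilinear
  binding; multi-ion steps are decomposed into consecutive transitions).

Voltage enters through a symmetric Eyring barrier,

$$k_{ij}(V) = k^0_{ij}\, e^{-z_{Q,ij} F V / 2RT},$$

with the reciprocal factor on the reverse rate, so the product of the two
scaling factors is exactly 1 at every voltage. `V` is intracellular minus
extracellular potential in volts; with this sign convention inward
movement of positive charge accelerates at hyperpolarized potentials,
which is what makes uptake fastest at −90 mV in the electrogenic models.
Constants default to F = 96 485 C mol⁻¹, R = 8.314 J K⁻¹ mol⁻¹,
T = 293 K, N_A = 6.022 × 10²³ mol⁻¹ (`phys_constants()`).

State occupancies `p(t)` obey the master equation `dp/dt = Q(t) p` with a
generator assembled from the voltage-scaled, concentration-multiplied
rates (`build_generator()`); columns of `Q` sum to zero, which conserves
total probability. Steady states are computed by a null-space (SVD)
solve.

## The three transporter fixtures

All three models share a core: Na⁺ binds to the outward-open, Cl⁻-bound
carrier, substrate binds, the loaded carrier occludes and translocates,
Na⁺ and then substrate are released inside. In DAT/NET the loaded limb
is resolved into a fast, electrogenic occlusion (`ToClNaS → ToccClNaS`,
0.17 equivalent charges — the main carrier of the transient peak current)
followed by a slow, electroneutral opening of the inner gate whose rate
is substrate-specific: ~1.8 s⁻¹ for the bulky fluorescent substrate APP⁺
(this slow committed step is what raises APP⁺'s Michaelis constant
toward its dissociation constant) versus fast for the compact cognate
substrates. The forward/reverse ratio of the translocation step is fixed
by the core, so all substrate instances of a transporter share the same
thermodynamic closure. The models diverge on the return limb, which is
where intracellular K⁺ is handled:

* **DAT/NET**: K⁺ binds the inward-open state (electrogenic), but the
  site loses affinity on the trajectory to the occluded conformation, so
  K⁺ is shed back into the cytosol before the return step. The return of
  the empty carrier moves the transporter's intrinsic negative charge
  outward (implemented as `zQ = +1` inward for the inward→outward
  direction), making the cycle electrogenic and uptake voltage-dependent.
  NET is identical to DAT in every core parameter; only its substrate
  binding/unbinding kinetics are slower, which is sufficient to produce
  its order-of-magnitude smaller turnover and the absence of measurable
  steady currents.
* **SERT**: K⁺ stays bound through an electroneutral return and is
  released outside — true antiport. The K⁺ charge movements cancel
  the +1 of the return limb exactly, so the full antiport cycle carries
  zero net charge and uptake is nearly voltage-independent. An
  alternative branch antiports a proton and sustains slower cycling when
  internal K⁺ is absent. A third return branch models Na⁺ occupancy of
  the same inward-facing cation site (Na⁺ and K⁺ binding there are
  mutually exclusive, consistent with the identical peak-current voltage
  dependence under high internal Na⁺ and K⁺): with internal Na⁺ raised to
  163 mM this branch carries the return step and the transporter shifts
  into the fast exchange mode, while at the physiological 6 mM it is
  essentially unoccupied and its reverse — a Na⁺ leak — is kept small by
  the thermodynamic closure. A dead-end intracellular Li⁺ complex is
  available behind a flag. Cl⁻ is treated as co-bound throughout (state
  names carry it) with no Cl⁻-coupled step.

A channel-like conducting state `Tcond`, in rapid equilibrium with the
K⁺-bound inward-facing conformation, carries the uncoupled current
component `I = P_o γ N_C (V − V_rev)` with γ = 2.4 pS and
V_rev = +100 mV. It is enabled by default in DAT and SERT and disabled in
NET, whose steady current is below detection either way; a flag restores
it.

### Thermodynamic consistency

Around every independent reaction loop the product of forward/reverse
base-rate ratios is constrained to 1 (standard state 1 M), with one
dependent rate per loop solved at build time. All net driving therefore
comes from ion gradients and voltage, never from the parameterization
itself: at equalized concentrations and 0 mV every loop free energy is
zero to numerical precision, and `loop_profile()` satisfies
`ΔG(V) − ΔG(0) = Σ zQ · F · V` exactly. Ligand chemical potentials enter
through the pseudo-first-order rates, which is what makes these loop
identities exact rather than approximate. DAT and NET substrate sites
are symmetric (same kon/koff on both faces), so substrate kinetics drop
out of the closures and the two cores remain parameter-identical; the
SERT serotonin site is asymmetric (fast extracellular dissociation),
which the closure absorbs into the empty-return step.

### Calibration

The figure-level rate constants of the source models are not tabulated
anywhere accessible, so the shipped fixtures were calibrated: starting
from the prior sequential-binding models of DAT and SERT, a handful of
rates and charge allocations were tuned — by one-dimensional root finding
where targets decouple and by joint derivative-free minimisation where
they do not — until the simulated protocols reproduce the printed
benchmarks — the
two-pulse recovery rates (3.74/4.45 s⁻¹ for DAT with/without internal
K⁺, 0.15 s⁻¹ for NET, 1.61/0.74 s⁻¹ for SERT with K⁺/with the proton
branch), and the +30 mV/−90 mV uptake ratios (≈25%, 35%, 80%). Tuned
quantities per model: the occlusion rate, K⁺-branch occlusion rate,
loaded-occlusion equivalent charge and APP⁺ inner-gate rate (DAT core,
jointly fitted), the substrate-edge charges and cognate dissociation
rate (NET), and the K⁺-, H⁺- and Na⁺-return rates plus the
substrate-edge charge split (SERT, jointly fitted). Everything else was fixed once at plausible values
(diffusion-limited or near-diffusion binding, millimolar-range Na⁺/K⁺
affinities on the appropriate faces) and not revisited. The calibrated
constants are frozen in the builders; `inst/extdata/models/` carries the
same fixtures as serialized text for round-trip use.

The fluorescent substrate APP⁺ uses the published binding constants
(9×10⁵ M⁻¹s⁻¹ / 30 s⁻¹ for DAT, 3×10⁵ / 1 for NET, 1×10⁵ / 1 for SERT);
cognate-substrate kinetics are part of the calibration.

## Virtual experiments

`simulate_application()` integrates a voltage-clamped substrate
application. Concentration steps are never instantaneous: each protocol
segment's external targets are approached exponentially with
τ = 10 ms, emulating a rapid superfusion system; initial occupancies
default to the steady state at the holding potential in the
pre-application bath.

Observables follow the measurement definitions used in whole-cell patch
fluorometry:

* coupled current `I = −F·N_C/N_A · Σ zQ_ij (p_i k_ij − p_j k_ji)` over
  all charged transitions (inward negative, N_C = 4×10⁶
  transporters/cell),
* uncoupled current through `Tcond` as above; total = coupled +
  uncoupled,
* uptake flux `(p_TiClS · koff − p_TiCl · kon · S_in) · N_C`
  molecules s⁻¹ through the intracellular release step (voltage-scaled
  rates of that edge), integrated into a cumulative fluorescence ramp.
  `S_in` defaults to 0 — dilution into a large cell volume, consistent
  with the linearity of measured ramps — with an optional finite cell
  volume for back-reaction studies.

Amplitude extraction uses a 200 ms post-onset window for the transient
peak and the final 20% of the application for the steady current; neither
window is dictated by the data source, they were chosen once to separate
the ~10 ms solution-exchange transient from cycling behaviour. Uptake
slopes are least-squares fits over the application window with 0.5 s
trimmed at each edge.

Protocols: `run_concentration_response()` (15 s applications over
1–600 µM, hyperbola fits, normalization to 600 µM),
`run_iv()` (−90…+30 mV in 20 mV steps; uptake normalized to −90 mV,
currents to −60 mV; both Boltzmann and line fits stored with the
lower-residual family preferred, mirroring the pragmatic choice used for
presentation of such data), `run_two_pulse()` (paired pulses with
log-spaced washes, mono-exponential fit of normalized test peaks → the
catalytic rate), and `run_ion_sweep()` across intracellular condition
presets. Pulse lengths are 0.5 s (DAT/SERT) and 2 s (NET, whose slower
loading needs a longer pulse); the default wash grid spans 0.05–60 s,
about five recovery time constants for turnover rates between ~0.1 and
~5 s⁻¹. Voltages are volts internally; millivolts appear only in
documentation.

## Curve families

`fit_hyperbola()`, `fit_boltzmann()`, `fit_line()` and `fit_monoexp()`
implement the four fit families with fixed, documented initializations
(hyperbola: Ymax = max(y), K_M at the half-maximum crossing;
mono-exponential: log-linear regression on the residual to the plateau),
so all fits are deterministic without seeds. `compare_lines_ftest()`
performs the nested F-test, slope equality first and full-line equality
second, matching how uptake–voltage relations under different
intracellular solutions are compared. Degenerate inputs (flat Boltzmann
data) are flagged, not fatal; all fit objects support `tidy()` and
`glance()`.

## Synthetic recordings

`generate_recording()` emulates two-channel patch-fluorometry data: the
current channel is the total membrane current plus additive Gaussian
noise (default SD 1 pA); the fluorescence channel is the
brightness-scaled cumulative uptake plus the bath wash-in/wash-out
artifact plus Gaussian noise (default SD 2% of the ramp). The bath
artifact — a square pulse convolved with the 10 ms exchange constant,
defaulting to 3× the ramp amplitude — reproduces the rapid
rise-and-decline component contributed by free dye across a field of
view much larger than the cell. Identical seeds give bit-identical
recordings, and the generator's state is restored afterwards so it never
perturbs the caller's random stream.

What the generator does **not** emulate: photobleaching, shot-noise
statistics of the photomultiplier, amplifier/capacitive artifacts,
cell-to-cell expression variability, and intracellular APP⁺ re-binding
(unless a finite cell volume is configured). Passing recovery tests on
synthetic data therefore demonstrates pipeline correctness under the
stated noise model, not robustness to every artifact of real recordings.
`recovery_harness()` quantifies recovery of known generating parameters
(bias/RMSE across seeds) and is the package's acceptance surface for the
analysis chain.

## Numerical choices

* Stiff adaptive integration (`deSolve::lsoda`) with atol 1e-10,
  rtol 1e-8, the exact generator supplied as the analytic Jacobian, and
  restarts at segment boundaries. The integrator or tolerances of the
  original simulations are not documented anywhere; these are this
  package's own choices, validated against the closed-form two-state
  solution (≤1e-6) and the algebraic steady state (≤1e-5).
* Occupancies are never renormalized inside the solver; conservation
  drift beyond 1e-6 raises an error.
* Output grids are 2 ms near application edges (peak resolution) and
  20 ms elsewhere.
* Steady states by SVD null-space solve; a degenerate null space
  (disconnected scheme) is an error, not a silent choice.

Problem sizes throughout tests and the acceptance script are the shipped
models themselves (10–12 states, 10–14 transitions) with protocol spans
of 15 s (uptake), up to ~65 s (two-pulse), chosen to match the
experimental protocols being emulated.

## Known limitations

* Na⁺ stoichiometry is collapsed to a single explicit Na⁺ per cycle (one
  released inside); the net charge per DAT/NET cycle is not independently
  constrained and the fixture's value (+1.7 equivalent charges over the
  substrate-translocating loop) is one admissible allocation among those
  consistent with the voltage-dependence benchmarks.
* Per-step loop free energies are fixture-dependent; only loop totals
  (sign and voltage decomposition) are anchored claims.
* The Li⁺ interaction of SERT is modelled as an inert dead-end complex,
  one of several mechanisms compatible with shallow peak-current IV
  relations.
* Temperature enters only as a fixed parameter; there is no
  enthalpy/entropy decomposition and no Gillespie-style stochastic mode.

## A short example

```{r example, eval = FALSE}
dat <- build_dat_model()
traj <- simulate_application(dat, 30e-6, V = -0.060, duration = 15)
autoplot(total_current(traj))
autoplot(substrate_uptake(traj))

iv <- run_iv(dat)
iv[, c("voltage", "uptake_slope_norm")]

rec <- run_two_pulse(build_dat_model("cognate"))
attr(rec, "recovery_rate")
```
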