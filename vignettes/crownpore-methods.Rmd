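---
title: "Models and methods behind crownpore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crownpore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crownpore)
```

`crownpore` analyses single-ion transport through sub-nanometre pores in
atomically thin membranes, with the crown-ether (18-crown-6) pore in
graphene as its reference system. This vignette states the models the
package implements, their assumptions, the tunable parameters, and the
numerical and design choices — in enough detail that a user can judge
what a passing test suite does and does not demonstrate about real data.

## Units and default conditions

Internally: lengths in nm, time in ns, energies in kBT at the configured
temperature, voltages in V, rates in ions/ns, concentrations in
ions/nm³ (1 mol/L = 0.6022 nm⁻³). Defaults (`conditions()`,
`ion_species()`, `pore_geometry()`): room temperature (298 K, chosen
because every thermal-unit quantity the analysis reports is consistent
with kBT/e ≈ 25.7 mV), 1 mol/L KCl with bulk resistivity
γ_b = 0.071 Ω·m (the value for rigid TIP3P water, since the reference
observables are MD-like), potassium mobility μ = 7.62×10⁻⁸ m²/(V·s)
with the diffusion coefficient tied to it by the Einstein relation, and
the crown-ether geometry: nominal radius 0.29 nm + 7.5 pm per percent
strain, oxygen van der Waals radius 0.152 nm (geometric radius
0.137 nm), effective radius a_p = 0.1 nm, effective membrane thickness
h_p = 1 nm, internal binding-site length Δ_p = 0.4 nm, staging spread
0.1 nm, crossing spread 0.02 nm, sampling-cylinder radius 0.28 nm.

## The free-energy landscape model

The single-ion energetics are approximated as a sum of per-shell
dehydration penalties and ion–rim Coulomb terms,

$$\Delta F(z) \approx \sum_i \eta_i f_i(z) E_i
  + \sum_{\nu'} \frac{q\,q_{\nu'} n_{\nu'}}{4\pi\epsilon_0\,\epsilon(r)\,r}.$$

* **Dehydration geometry.** The fraction $f_i(z)$ of shell $i$ stripped
  by the membrane is computed from a slab-plus-cylinder exclusion model:
  the membrane is a slab of thickness twice the carbon van der Waals
  radius (0.34 nm) perforated by a cylinder of the geometric pore
  radius. Because the shell is a thin sphere centred on the pore axis,
  the excluded fraction has a closed form (verified in the tests against
  a rejection-sampling volume oracle).
* **Hydration shells.** Published analyses of this pore only constrain the
  shell factors to be order one; the package defaults are
  literature-representative values for potassium — shell radii
  0.332/0.57 nm, energies 85/25 kBT, η = 1 — and are fully
  configurable. They affect only this landscape model, not the kinetics
  or estimators.
* **Permittivity switching.** Only the endpoints are physically
  constrained: ε ≈ 4 at contact (no intervening water) and the bulk
  value at full hydration. The package interpolates linearly in the
  ion–group distance between the first- and second-shell radii; the
  switching window is a parameter because the true form is unknown.

**Voltage tilt.** An applied bias is modelled as a linear potential ramp
over |z| < 0.5 nm (the observed drop region for an atomically thin
membrane with hydrated double layers), subtracting exactly qV across the
profile. **Discrete gradients** pair every local minimum with the next
maximum in the +z direction; profiles are smoothed with a 3-point moving
average and extrema with prominence below 0.5 kBT are pruned, because
sampled profiles carry half-kBT-scale standard errors and spurious
extrema would otherwise dominate. A feature is *irrelevant* when the
applied ideal field qV/(2·0.5 nm) should have reduced its gradient but
did not (within a 10% tolerance; matching tolerance 0.1 nm) — such
features are not rate limiting and build no self-consistent local
potential drop.

**Entropic penalties.** Confinement costs are reported as
−ln(πr²l/l³) for bulk → sampling cylinder (≈1.8 kBT with r = 0.28 nm,
l = 1.2 nm), −ln(r_c²/r_ABF²) for cylinder → crossing region (≈5 kBT),
and −ln(l_W/l) for axial localisation (1–2 kBT).

## The Brownian walker

`simulate_walkers()` integrates the overdamped Langevin equation
dz = −D F′(z) dt + √(2D dt) N(0,1) (F in kBT) with an Euler–Maruyama
step, the force from central differences with linear interpolation. The
default step obeys √(2D dt) ≤ 0.2 × grid spacing; a step beyond half the
grid spacing is rejected with an error naming the bound. The lower
boundary is absorbing (an ion returning to bulk) or reflecting (a
reservoir that always resupplies).

The **one-way incoming rate** J_in(z) counts each walker's first forward
crossing of each plane within a fixed observation window, per unit time.
A 1D walker fed from an absorbing plane cannot show a constant J_in even
on a flat landscape — free 1D diffusion itself produces the
1/(z−z_source) decay of a diffusive constriction — so the package uses a
reflecting source with a finite window: on a featureless profile the
curve is flat once the window exceeds the diffusion time, a barrier
produces a monotone drop up to its position, and the plateau equals the
net translocation rate exactly. Oracles shipped with the package:
the constant-drift splitting probability
(1−e^{−ux})/(1−e^{−u}) and the reflecting/absorbing mean first-passage
time (1/D)∫dy e^{F(y)}∫dx e^{−F(x)}, computed by trapezoidal quadrature
on a 6000-point grid (`integrate()` is avoided because the doubly
exponential integrand triggers spurious round-off failures).

## The three-site chain and its two notions of steady state

Sites: staging (association side), the pore binding site, and an exit
site, with one-way transitions through the pore
(backward rates are accepted but default to zero). The rate equations

$$\dot P_1 = k_b(1-P_1) - k_b' P_1 - k_a P_1 (1-P_2), \quad
  \dot P_2 = k_a P_1 (1-P_2) - k_d P_2 (1-P_3),$$
$$\dot P_3 = k_d P_2 (1-P_3) - k_\mathrm{out} P_3 + k_\mathrm{in}(1-P_3)$$

(the exit-side form printed in some statements of the model is
sign-inconsistent; the package uses the physically consistent form
above, and the elimination below makes the exit side inconsequential
anyway). Eliminating the staging site at steady state gives the
two-parameter current

$$I/q = \left[\frac{1}{k_b} + \frac{1}{\tilde k_a (1-P_2)}\right]^{-1},
\qquad \tilde k_a = k_a \frac{k_b}{k_b + k_b'},$$

which is the fitting surface: it needs only the bulk feed, the effective
association rate, and the *measured* pore occupancy.

**Mean-field versus exact.** The rate equations factorize pair terms
such as $P_1(1-P_2)$ — they are mean-field. The underlying occupancy
Markov chain on $\{0,1\}^3$ develops correlations between the staging
and pore sites when association is fast and dissociation slow
(blocking), and its stationary marginals then differ appreciably (the
package's own example: P₂ = 0.94 mean-field vs 0.74 exact at
k_b = k_b' = 0.72, k_a = 24, k_d = 0.378 ns⁻¹). `steady_state_chain()`
therefore has two methods: `"mean_field"` (the model; solved by reducing
the fixed point to one monotone scalar balance at the pore site, to
machine precision, so the closed-form identity above holds to ~1e−15)
and `"exact"` (the eight-state master equation solved by linear
algebra). The event-driven simulator `gillespie_chain()` is exact for
the microscopic chain and is validated against the `"exact"` solution;
it discards a 10% burn-in by default because replicas start from an
empty pore. This mean-field gap is a genuine property of site models
with blocking, worth knowing when interpreting fitted occupancies near
saturation.

## Rate estimators and regime criteria

All estimators return audit records (value plus echoed inputs). Capture
uses the circular-disc solid angle Θ = 4 by default (2π and 4π are the
named alternatives); the pore resistivity convention defaults to twice
the bulk KCl value (single-carrier transport: only the cation passes),
overridable. The diffusion-limited window
ΘkTc a_p h_p² ≪ qV ≪ ΘkT h_p/(πa_p) evaluates to about 6–330 mV for the
default pore; the lower bound is a prediction, untested even by the
reference simulations. "Much less than" is operationalised as a factor
of 3 (configurable) throughout the regime module. Per-point regime
labels use the kinetic balance: occupancy above ½ means a localized ion
blocks the pore (barrier/dissociation-limited); otherwise supply-limited
transport is split into diffusion- or drift-fed by comparing κ_bV with
k_b0. Conductance linearity (superlinear = activated/barrier-limited,
sublinear = diffusion-limited) is classified by the sign of the weighted
least-squares slope of G = I/V against V with a 95% interval, replacing
classification by eye.

## Fitting

`fit_bulk_model()` fits the two-parameter current (with
k_b = k_b0 + κ_bV, k_b0·e^{βV} — β in kBT per volt — or κ_bV) to
measured currents by weighted Levenberg–Marquardt, parameters in log
space (rates are positive). Weights are inverse variances from the
current SEs; because the measured P₂ enters the model nonlinearly, its
uncertainty is propagated into the weights by the delta method and the
fit re-run once — without this, occupancy noise at near-blocked points
attenuates the association-rate estimate. Parameter standard errors come
from the reduced-chi-square-scaled covariance, mapped back from log
scale. `extract_kd()` inverts the plateau balance k_dP₂ = I/q per point
(assuming a nearly empty exit site) and fits log-linear strain and
combined strain–voltage laws; when the table carries per-point SEs the
parameter covariance is computed from those known variances rather than
a residual variance estimated from a handful of points, which would make
nominal 2-SE intervals undercover. `compare_models()` ranks fits by
adjusted R² and the residual at the lowest voltage, where the drift-fed
and activated interpretations differ most.

## The synthetic generator

The generator's defaults are the study conditions: strains 0–10% in 2%
steps; voltages 0.1, 0.25, 0.5, 1 V; five replicas of 50 ns per design
point (a 250 ns campaign per point, the lower end of the reference
protocol); truth parameters k_b0 = 0.5 ns⁻¹, κ_b = 2.2 V⁻¹ns⁻¹,
k̃_a = 12 ns⁻¹ and the combined dissociation law
k_d = 3.2·V·e^{0.043 qV/kBT + 0.22 s} ns⁻¹. The deterministic truth at
each point solves the plateau balance k_dP₂ = I/q with an empty exit
site, so extraction and fitting are exact inverses on noise-free data.

Counting noise realises the model's pore site as a stationary two-state
dwell (telegraph) process — occupied intervals ending in a translocation
at rate k_d, empty intervals refilled at k_dP₂/(1−P₂) — so each replica
reports a translocation count over the run and a dwell-time occupancy,
and the per-point SE is √(var/n) across replicas. Starting each replica
from the stationary state makes the generator exactly unbiased for the
model truth; generating instead from the microscopic three-site chain
would bake the mean-field/exact gap (up to ~20%) into the data as model
misspecification. A Gaussian approximation and a noise-free mode are
provided. A concrete chain realization (for the stochastic-simulator
route) sets k_b' = k_b, k_a = 2k̃_a, and a fast exit at 500·k_d; the
fitting surface is invariant to these choices by the elimination
identity.

Synthetic profiles are Gaussian feature sums: a central electrostatic
well whose depth decays exponentially with strain (the well flattens and
vanishes under strain), a central dehydration barrier growing linearly
with strain, satellite features near ±0.35 nm, seeded Gaussian noise at
the 0.5 kBT SE level, and the standard voltage tilt.

**What passing tests show — and do not.** Parameter recovery and regime
classification are demonstrated on data whose noise structure (renewal
counting noise, independent replicas) and whose mean structure (the
two-parameter current with measured occupancy) match the model. Real MD
or experimental data add correlated noise, strain-dependent association,
backward currents at low voltage, and occupancies measured with
model-dependent site definitions; agreement there is a scientific
question, not a software guarantee. The kinetic model itself cannot be
used at very small voltages, where one-way transitions cannot reproduce
the approach to equilibrium.

## Numerical choices and limitations

* Chain steady state: scalar root solve (`uniroot`, machine-precision
  tolerance); stage-current residuals below 1e−12 × the rate scale.
* ODE integration via `deSolve::ode` (rtol 1e−10, atol 1e−12) with
  occupancy-bound checks.
* Walker step-size bound and the trapezoidal MFPT quadrature as above;
  all stochastic entry points take explicit seeds and are reproducible
  bit for bit.
* Problem sizes in the test suite (hundreds of walkers, hundreds of
  nanoseconds of chain time, 20 generator seeds) were chosen to resolve
  the tested effects at 3-sigma Monte-Carlo resolution on a laptop-class
  single core.
* The dehydration model ignores shell restructuring and treats the
  membrane as a rigid slab; the Coulomb term uses a scalar distance-
  dependent permittivity. These reproduce qualitative landscape shapes,
  not quantitative MD profiles — which is why the landscape module is
  analysis machinery, with the synthetic generator standing in for MD
  observables.
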