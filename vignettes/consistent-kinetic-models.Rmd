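---
title: "Thermodynamically consistent kinetic cycle models with kinconsist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamically consistent kinetic cycle models with kinconsist}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinconsist)
```

## The problem

Bottom-up models of molecular machines — transporters, polyprotic acids,
receptors — describe a system as a graph of discrete chemical microstates
connected by elementary processes (a conformational change, the binding of a
single ligand). Each process is parameterized by a free-energy difference or
by a forward/backward rate pair, and these parameters are measured in
*separate* experiments or simulations, each with its own error. Statistical
mechanics constrains them jointly: around any closed cycle the free-energy
differences must sum to zero (the Wegscheider condition), and equivalently
the product of intrinsic forward rates must equal the product of intrinsic
backward rates (kinetic cycle closure). Independently measured parameters
essentially never satisfy these identities, and a model assembled naively
from them contains spurious, unphysical driving forces: an "equilibrium"
model that runs in circles.

`kinconsist` repairs this in a statistically principled way. Rather than
adjusting parameters ad hoc, it treats the inputs as noisy observations and
finds the model that satisfies the constraints exactly while being maximally
likely given the data and their stated uncertainties.

## State free energies by weighted maximum likelihood

The central object is the **potential graph**: state free energies \(G_i\)
(in kT) assigned to nodes, so that every edge difference
\(\Delta G_{ij} = G_j - G_i\) closes around every cycle *by construction*.
Given measured edge differences \(\bar\Delta_{ij} \pm \bar\sigma_{ij}\)
(Gaussian errors assumed), the maximum-likelihood potentials minimize

\[
\sum_{(i,j)} \left( \frac{(G_j - G_i) - \bar\Delta_{ij}}{\bar\sigma_{ij}} \right)^2 ,
\]

a weighted least-squares problem on the graph incidence matrix
(`solve_potentials()`). The solution is unique up to an additive constant on
a connected graph; the package pins a user-chosen reference state to zero.
Small edge uncertainties act as strong springs — those edges barely move —
while poorly known edges absorb most of the inconsistency.

Uncertainties propagate through the Fisher information, which for this
likelihood is the \(1/\bar\sigma^2\)-weighted graph Laplacian (up to an
overall factor, below). Its Moore–Penrose pseudoinverse — computed by SVD
with a relative singular-value cutoff of `max(dim) * .Machine$double.eps *
s_max`, expecting exactly one zero (gauge) mode — is the covariance of the
\(G_i\) (`state_uncertainties()`); `edge_sigma()` reports the gauge-free
\(\sqrt{C_{ii} + C_{jj} - 2C_{ij}}\) for an edge.

**Factor-of-two convention.** The likelihood is sometimes written with the
exponent \(-((G_j-G_i)-\bar\Delta_{ij})^2/\bar\sigma_{ij}^2\), i.e. without
the Gaussian \(1/2\). The point estimate is unaffected, but the covariance
scale is not. `kinconsist` uses the standard Gaussian convention for the
covariance, chosen so that a graph with a single edge reports exactly the
input \(\bar\sigma\) for that edge — the behaviour a user would expect of
error propagation. `fisher_information()` itself returns the no-half
convention (twice the weighted Laplacian), documented as such.

## Thermodynamically consistent rates

Rate pairs \((\bar k_{ij}, \bar k_{ji})\) defined at a gradient-free
reference condition are first converted to differences
\(\beta\bar\Delta_{ij} = -\ln(\bar k_{ij}/\bar k_{ji})\) with first-order
error propagation, the potential graph is solved, and each pair is then
**projected** onto the detailed-balance line \(k_{ij} = K k_{ji}\),
\(K = e^{-\Delta G_{ij}}\), at the constrained Gaussian maximum-likelihood
point:

\[
k_{ji} = \frac{\bar k_{ji} + (\bar\sigma_{ji}^2/\bar\sigma_{ij}^2) K \bar k_{ij}}
              {1 + (\bar\sigma_{ji}^2/\bar\sigma_{ij}^2) K^2},
\qquad k_{ij} = K k_{ji}.
\]

Rates with larger relative errors move more; the rate sigmas are carried
through unchanged. The whole pipeline is `make_consistent()`, which also
recovers intrinsic (concentration-independent) rate constants by dividing
each pseudo-first-order binding rate by \([X]/c_0\) at the reference
condition. The Gaussian-in-rates approximation is only trustworthy for small
relative errors; if a projection would produce a non-positive rate the
package raises a hard error rather than return a meaningless value. A
log-normal rate model would respect positivity exactly but is deliberately
out of scope.

## Conditions, observables, and units

All free energies are in kT (\(\beta = 1\)); temperature enters only through
the thermal voltage when converting membrane potentials. Concentrations are
relative to the standard state \(c_0 = 1\) M; protons are always specified
as pH with \([\mathrm{H^+}]/c_0 = 10^{-\mathrm{pH}}\), so a protonation edge
obeys \(\beta\Delta G(\mathrm{pH}) = \ln 10 \, (\mathrm{pH} - pK_a)\).

A `condition_set` fixes concentrations, pH, voltage, and temperature;
`condition_potentials()` rebuilds the state free energies at a condition by
accumulating shifted edge differences along a spanning tree from the
reference state. Because consistent differences close exactly and
concentration shifts close on stoichiometrically balanced cycles, the result
is tree independent; a cycle with net ligand creation is detected and
reported as a modelling error. Notably, for a transporter model a
transmembrane gradient *legitimately* fails this check — there is no
equilibrium to condition to — and the error message says so; nonequilibrium
questions go through the master equation instead.

From conditioned potentials: Boltzmann microstate probabilities
(`state_probabilities()`, max-shifted, stable for spreads of hundreds of
kT), macrostate free energies via log-sum-exp (`macrostate_dg()`), and
titration scans (`titration_scan()`) with per-site and total occupancies.
The uptake derivative \(\partial\bar X/\partial \mathrm{pH}\) uses centered
finite differences on the user's grid (one-sided at the ends): observables
may be arbitrary macrostate aggregates, so no analytic derivative is
attempted, and grid spacing is the user's accuracy control.

## Nonequilibrium steady states

`build_rate_matrix()` assembles the master-equation generator \(Q\) (columns
sum to zero; \(Q_{ji}\) is the rate \(i \to j\)) from intrinsic rates,
side-specific concentration factors (edges in transporter models declare
whether they bind from the `in` or `out` bath), and membrane-voltage
factors. A transition moving charge \(q\) inward across potential
\(\Delta\Psi = \Psi_{in} - \Psi_{out}\) is modelled with an Eyring barrier a
fraction `split` (default one half) through the field: the forward rate
carries \(e^{-\beta q \Delta\Psi \cdot split}\) and the reverse
\(e^{+\beta q \Delta\Psi (1 - split)}\), so the pair ratio contributes
exactly \(e^{-\beta q \Delta\Psi}\) regardless of the barrier position.
Edges with zero charge (e.g. empty-carrier leak transitions) are unaffected.

`steady_state()` extracts the stationary distribution as the null vector of
\(Q\) by SVD — robust for stiff matrices — and errors if the null space is
not one-dimensional ("reducible kinetic network"). Edge net fluxes
\(J_{ij} = P_i k_{ij} - P_j k_{ji}\) and the net flux across a designated
reporter edge (the transporter turnover number) follow. The cycle driving
potential \(\beta\chi = \ln(\Pi_+/\Pi_-)\) (`cycle_drive()`) is zero in
equilibrium, equals the chemical-gradient term for electroneutral cycles
(voltage contributions cancel), and is linear in \(\Delta\Psi\) with slope
proportional to the net transported charge for electrogenic cycles.

Numerical note: the test suite checks `steady_state()` against an
independent long-time matrix-exponential propagation. For a moderately stiff
system the two agree to \(10^{-8}\) per component. For the antiporter model,
whose rates span \(10^2\) to \(3\times10^8\;s^{-1}\), the matrix-exponential
*oracle* itself carries rounding of order \(10^{-7}\) (its null-space
residual is an order of magnitude larger than the SVD solution's), so the
comparison there is made at \(10^{-6}\) while the steady-state residual
\(\lVert Q p \rVert\) is held to \(10^{-10} \times \max Q\).

## Inverse inference by zero-temperature Monte Carlo

`mc_infer()` infers microscopic edge parameters (pKa values or standard
free-energy differences) from macroscopic training curves. Per iteration,
one uniform perturbation \(\delta \sim U(-\Delta, \Delta)\) is drawn per
symmetry group — edges representing chemically equivalent processes share
one parameter and move together — and *all* groups move in the same
iteration; the potential graph is re-solved, so the model is
thermodynamically consistent at every step; the pooled RMSD against the
training curves (equal per-point weight across curves) is recomputed; and
the collective move is accepted only if the RMSD decreased (a
zero-temperature Metropolis rule; a finite temperature is available but off
by default). The trajectory is deterministic given the seed. Defaults:
\(\Delta = 2\) (pKa units), step cap \(10^5\) with a convergence flag rather
than an exception.

**Known limitation.** With a fixed step width and strict descent, the
probability of accepting a collective move decays like \((d/2\Delta)^m\)
near an optimum at parameter distance \(d\) with \(m\) groups. For the
three-site (7-group) model the walk therefore stalls: across seeds, final
RMSD values of 0.013–0.08 after \(10^5\) iterations are typical for
noiseless synthetic recovery, even though the fit is visually excellent.
Reaching arbitrarily small RMSD would require a decreasing step schedule,
which this deliberately simple algorithm does not include. Inferred
parameters are also not guaranteed unique — distinct microscopic parameter
sets can produce nearly identical macroscopic curves — so recovered curves,
not recovered parameters, are the meaningful output.

## Built-in systems and what the synthetic data does (not) establish

* `generate_two_site()` — a diprotic binding site: 4 states, one cycle.
  Independent (all pKa 7), cooperative and anticooperative variants; the
  symmetric split is ±1.5 pKa units by default (a round value chosen to make
  the qualitative regimes visible; the magnitude is a parameter, not a
  claim). Cooperativity suppresses the singly-protonated macrostate and
  steepens uptake; anticooperativity promotes it and flattens uptake into a
  double step.
* `dtpa_model_builder()` / `generate_dtpa()` — the three-site protonation
  cube (8 states, 12 edges, 7 symmetry groups under the terminal mirror) of
  the polyamine chelator DTPA, with a reference microscopic pKa table. The
  synthetic titration curves (central-site and mean-terminal occupancy on a
  pH 2–12 grid, step 0.25 — wide enough to cover both titration transitions)
  are computed through the forward model and stand in for digitized NMR
  data, which is not shipped. A green recovery test therefore establishes
  that the inverse machinery works on this graph family — not that the
  experimental data are fit, and not noise robustness, since the synthetic
  curves are noiseless.
* `generate_antiporter()` — a six-state alternating-access sodium/proton
  antiporter with competing binding, a small empty-carrier leak edge, and
  order-of-magnitude input rates with uncertainties, defined at 100 mM
  driving ion and pH 8. Variants: driving-ion valence +1 (electroneutral) or
  +2 (electrogenic), and leak none/small/large (the "large" leak rate pair,
  1000/1350 per s, is a synthetic stand-in at the stated order of
  magnitude). The fixture reproduces the reference consistent parameter
  block to its stated precision, which validates the numerical pipeline; it
  does not validate the biology of any real transporter, since the inputs
  are deliberate order-of-magnitude estimates.
* `generate_random_graph()` — seeded random connected graphs for oracle
  comparisons of the solver.

## Numerical choices, tie-breaks, degenerate inputs

* Potential solve: dense QR on the reduced (reference-column-dropped)
  weighted incidence system; no iterative solver (graphs here are small).
  No tie-breaking is needed — the reduced problem has full rank exactly when
  the graph is connected, which is validated at load time.
* Parallel edges between a state pair are rejected at load time; model one
  process per pair.
* Rate projection returning a non-positive rate (possible for extreme
  inconsistency) is a hard error, not a warning.
* `curve_rmsd()` requires exact x-grid agreement; no interpolation is ever
  performed silently.
* Binding direction of an order-2 edge is inferred from the `site:`
  occupancy columns of its two states (the bound state has one more ligand),
  so files may list either orientation.
* Writing graphs uses `%.17g`, so CSV round trips are bit exact.

## Limitations

* Gaussian likelihoods throughout; no log-normal rate model, no Bayesian
  posterior over the potentials.
* Deterministic steady states only; no stochastic trajectory simulation.
* The inverse MC is a proof-of-concept optimizer (see above), not a sampler
  of parameter uncertainty.
* Conditions are uniform baths; no spatial or time-dependent driving.
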