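# kinconsist

Thermodynamically consistent kinetic cycle models in R.

## Who this is for

Anyone assembling a state-resolved model of a molecular system — a membrane
transporter, a polyprotic acid, a ligand-gated receptor — from free-energy
differences or rate constants that were measured or simulated *separately*.
Independently obtained parameters essentially never satisfy the
thermodynamic identities that couple them, and a model built naively from
them embeds spurious driving forces: state populations become
path-dependent, "equilibrium" models run in circles, and transport
predictions are arbitrary.

## What it does

Every closed cycle in a kinetic graph must satisfy two equivalent
constraints: the free-energy differences sum to zero (Wegscheider
condition),

    sum over cycle of dG_ij = 0,

and the intrinsic forward/backward rate products balance (kinetic cycle
closure),

    ln( prod k°_ij / prod k°_ji ) = 0.

`kinconsist` enforces both exactly while staying maximally consistent with
the noisy inputs:

1. **Potential solve** — state free energies `G_i` (kT) are the weighted
   least-squares / maximum-likelihood solution of all measured edge
   differences `dG_ij ± sigma_ij`; uncertainties come from the
   pseudoinverse of the Fisher information (`solve_potentials()`,
   `state_uncertainties()`, `edge_sigma()`).
2. **Rate projection** — each rate pair is projected onto the detailed
   balance line `k_ij = exp(-dG_ij) * k_ji` at the constrained Gaussian
   maximum-likelihood point; rates with larger relative errors move more
   (`make_consistent()`, `project_rate_pair()`).
3. **Observables** — condition-dependent free energies, Boltzmann state and
   macrostate probabilities, titration curves and uptake derivatives over
   concentration/pH grids (`condition_potentials()`, `titration_scan()`,
   `macrostate_dg()`).
4. **Nonequilibrium kinetics** — master-equation generators with
   side-specific concentrations and membrane-voltage (Eyring half-barrier)
   factors, SVD steady states, edge fluxes and transporter turnover numbers
   (`build_rate_matrix()`, `steady_state()`, `turnover_scan()`,
   `cycle_drive()`).
5. **Inverse inference** — zero-temperature Metropolis Monte Carlo that
   adjusts microscopic edge parameters (e.g. site pKa values, with
   symmetry-related edges coupled) until model titration curves match
   macroscopic training data (`mc_infer()`).

Models are plain CSV (`states.csv` + `graph.csv`, see
`?load_state_graph`), conditions are YAML (`?load_conditions`), and three
reference systems ship as code: a two-proton binding site, the three-site
protonation cube of DTPA, and a six-state sodium/proton antiporter
(`?generate_two_site`, `?generate_dtpa`, `?generate_antiporter`).

## Worked example: the antiporter model

The built-in six-state alternating-access Na+/H+ antiporter carries
order-of-magnitude input rates with uncertainties, defined at 100 mM Na+ and
pH 8. The raw inputs violate cycle closure by 0.235 kT around the transport
cycle; `make_consistent()` repairs them:

```r
library(kinconsist)
g   <- generate_antiporter()
kin <- make_consistent(g)
kin
#> <consistent_kinetics> 7 edges
#>                 edge       k_fwd       k_rev  dG_kT
#> 1   IF(H+) -> OF(H+) 8.00621e+03 4.99004e+03 -0.473
#> 2    OF(H+) -> OF(0) 6.00796e+03 1.94467e+02 -3.431
#> 3   OF(0) -> OF(Na+) 3.20044e+08 1.67079e+08 -0.650
#> 4 OF(Na+) -> IF(Na+) 8.00624e+03 4.98998e+03 -0.473
#> 5   IF(Na+) -> IF(0) 7.67609e+07 3.19948e+08  1.427
#> 6    IF(0) -> IF(H+) 2.15845e+02 7.88902e+03  3.599
#> 7     OF(0) -> IF(0) 9.97039e+01 1.35218e+02  0.305
```

Every forward/backward pair now satisfies `k_fwd/k_rev = exp(-dG)` exactly
and every cycle closes to < 1e-10. The consistent binding free energies
convert to equilibrium constants of the two conformations:

```r
sol <- kin$solution
100 * exp(-sol$consistent_dg[5])   # Na+ KD, inward-facing:  24 mM
100 * exp(sol$consistent_dg[3])    # Na+ KD, outward-facing: 52 mM
8 - sol$consistent_dg[6] / log(10) # proton pKa, inward:  6.4
8 + sol$consistent_dg[2] / log(10) # proton pKa, outward: 6.5
```

Out of equilibrium, a 10-fold outward sodium gradient against an adverse pH
gradient drives proton export:

```r
cs <- condition_set(concentrations = list("Na+" = c("in" = 0.01, "out" = 0.1)),
                    pH = c("in" = 7.4, "out" = 7))
ss <- steady_state(build_rate_matrix(kin, cs))
reporter_flux(ss, c("IF(H+)", "OF(H+)"))
#> [1] 106.1435    # protons/s out of the cell
```

Positive turnover means proton transport out of the cell. Because the
Na+/H+ cycle is electroneutral, this sign cannot be flipped by a membrane
voltage — only by the chemical gradients; the divalent-cation variant
(`generate_antiporter(charge = 2)`) is electrogenic and reverses at zero
gradient.

## Command line

```sh
Rscript inst/cli/kinconsist.R fixtures --system antiporter --out model/
Rscript inst/cli/kinconsist.R solve    --states model/states.csv --graph model/graph.csv --out out/
Rscript inst/cli/kinconsist.R rates    --states model/states.csv --graph model/graph.csv --out out/
```

Subcommands: `solve`, `rates`, `scan`, `steadystate`, `fit`, `fixtures`;
each run writes a JSON manifest with input checksums. See `?run_cli`.

## More

The methods vignette (`vignettes/consistent-kinetic-models.Rmd`) documents
the model and its assumptions, parameter conventions and units, numerical
choices, what the synthetic systems do and do not establish, and known
limitations of the inverse Monte-Carlo optimizer.
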