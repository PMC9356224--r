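# groovePMF

Energetics of ion permeation through the hydrophilic groove of a membrane
protein (a TMEM16-scramblase-like system), computed from umbrella-sampling
data — with a built-in synthetic-data generator so the whole pipeline runs
and is testable without any molecular-dynamics input.

## Who this is for

Computational biophysicists who have (or want to emulate) per-window
reaction-coordinate series from harmonically biased sampling of an ion
moving along a membrane-normal coordinate Z, and who need the standard
downstream analyses in one tested place:

* **Umbrella bookkeeping** — window grids (e.g. 84 windows over
  Z = −10.25…10.5 Å at 0.25 Å spacing, k = 10 kcal/mol/Å²), harmonic bias
  energies, shared histograms, neighbor-overlap QC.
* **WHAM** — the self-consistent estimator
  `P(b) = Σᵢ nᵢ(b) / Σⱼ Nⱼ exp[(fⱼ − wⱼ(b))/kT]`,
  `fⱼ = −kT log Σ_b P(b) exp[−wⱼ(b)/kT]`, iterated to a 10⁻⁶ kcal/mol
  tolerance; PMF = −kT log P, minimum-anchored at zero; Monte Carlo
  bootstrap error bars with an effective sample size
  `N_eff = ⌈N·Δt/τ⌉` (τ = 20 ps by convention).
* **Contact analysis** — per-window frame counting of partners within 3 Å
  of the ion, the strict >50 %-of-frames "critical interaction" rule, and
  contiguous critical Z-ranges per partner; a permeation-event detector
  for unbiased runs.
* **Geometry** — the average permeation path (mean XY of sampled ion
  positions per Z bin) and a maximal-inscribed-sphere pore-radius profile
  with its geometric axis (a planar-per-Z HOLE-style description), plus
  their RMS deviation.
* **Electrostatics** — finite-difference linearized Poisson–Boltzmann on a
  membrane-slab dielectric model (ε_P = ε_core = 2, ε_head = 30,
  ε_water = 80; 26 Å core, 8 Å headgroup layers, an 18 Å water-filled
  cylindrical hole; 150 mM mobile monovalent ions excluded from the
  membrane and bead interiors), sampled along the average path.

The synthetic-data module generates overdamped Langevin (Brownian)
trajectories on designed groove potentials
`U(x,y,z) = Σ Gaussians(z) + ½ k_r(z) (x² + y²)` whose exact 1-D free
energy `F(z) = U_z(z) + kT log(k_r(z)/2πkT)` is known analytically, so
every recovery claim is checked against a closed form. Three presets
mirror the regimes of interest: an open groove with an anionic lipid
(≈2 kcal/mol barrier), an open groove with a bulky zwitterionic lipid
(≈7 kcal/mol), and a constricted mutant-like groove (≈8 kcal/mol, peak at
Z = +3.5 Å).

## Worked example

```r
library(groovePMF)

pot <- groove_potential("open_pg")                # designed 2 kcal/mol barrier
win <- generate_windows(-10.25, 10.5, 0.25)      # 84 windows, k = 10
smp <- sample_boltzmann_windows(pot, win, 1000, seed = 101)
res <- solve_wham(build_histograms(smp, 0.1), win)
barrier_height(res, c(-10.25, 10.5))
#> [1] 2.151982
designed_barrier(pot, c(-10.25, 10.5))
#> [1] 1.999807
```

The recovered barrier (2.15 kcal/mol) agrees with the analytic profile of
the generating potential (2.00 kcal/mol) to within the sampling noise of
1000 frames per window; the full profile matches to 0.08 kcal/mol RMS.

A complete scenario — sampling, QC, WHAM + bootstrap, contact annotation,
path/pore geometry and the electrostatic potential along the path — runs
from one config:

```r
cfg <- scenario_config("open_pg", profile = "ci", seed = 11, outdir = "out")
s <- run_scenario(cfg)
s$barrier_kcal_mol      # 2.242  (designed 1.932 over the reduced ci grid)
s$path_axis_rms_A       # 0.161  (sampled path vs geometric pore axis)
s$ep_range_kcal_mol_e   # -5.83 .. -2.00  (anionic lipid + gate in groove)
```

or from the shell:

```sh
Rscript inst/cli/groovepmf.R --preset open_pg --profile ci --seed 11 --outdir out
```

## Layout

```
R/                 implementation (constants/types, potentials, Langevin
                   sampling, umbrella, WHAM, contacts, geometry,
                   electrostatics, pipeline)
tests/testthat/    unit + property tests; test-acceptance.R
scripts/           acceptance.R
inst/cli/          groovepmf.R command-line entry point
vignettes/         methods vignette (model, parameters, limitations)
```
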