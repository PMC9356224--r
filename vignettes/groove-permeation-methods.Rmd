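---
title: "Methods: ion-permeation energetics in a membrane-protein groove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ion-permeation energetics in a membrane-protein groove}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes, which
numerical choices it makes where the design was genuinely open, and what a
green test does and does not establish.

## The physical problem and the model

A monovalent cation (potassium-like) permeates the hydrophilic groove of a
membrane protein. The reaction coordinate is the signed Z distance between
the ion and a fixed reference bead in the middle of the transmembrane
region (`value = ion_z − ref_z`; +Z is extracellular). All lengths are in
Å, energies in kcal/mol, times in ps, charges in e; the Boltzmann constant
(1.9872041×10⁻³ kcal/(mol·K)) and Coulomb prefactor (332.0636
kcal·Å/(mol·e²)) are frozen literals so results reproduce bit for bit.
The working temperature is 310 K throughout (kT = 0.6160 kcal/mol).

Because microsecond-scale all-atom trajectories are out of reach at desk
scale, the package ships a synthetic stand-in whose ground truth is exact:

$$U(x,y,z) = \sum_i A_i e^{-(z-c_i)^2/2w_i^2} \;+\; \tfrac12 k_r(z)\,(x^2+y^2)$$

Gaussian terms shape the free-energy landscape along the membrane normal;
the harmonic in-plane term is the groove wall. Since the XY part is
Gaussian at every z, it integrates analytically and the exact 1-D profile
is

$$F(z) = U_z(z) + kT \log\!\big(k_r(z)/2\pi kT\big),$$

so every recovery test compares against a closed form, never against
another numerical estimate.

### Presets

| preset | barrier (design) | realization |
|---|---|---|
| `open_pg` | 2.0 kcal/mol | single Gaussian, A = 2.0, c = 0.5 Å, w = 2.5 Å; k_r ≡ 0.5 |
| `open_pc` | 7.0 kcal/mol | single Gaussian, A = 7.0, c = 2.7 Å, w = 2.5 Å; k_r ≡ 0.5 |
| `l302a` | 8.0 kcal/mol | A = 8 − kT·log 10 = 6.582 at c = 3.5 Å plus a 10-fold tightening of k_r (0.5 → 5.0) at the same center, so the entropic neck contributes kT·log 10 = 1.418 kcal/mol exactly |

The barrier is defined as max − min of F over the umbrella-covered range;
the `l302a` amplitude is chosen so the analytic barrier is exactly 8.0 at
310 K, with the peak at Z = +3.5 Å where the constricted scaffold is
narrowest. These three regimes (≈2, ≈7, ≈8 kcal/mol) are design targets
emulating an open groove with an anionic lipid, an open groove obstructed
by a bulky zwitterionic headgroup, and a constricted mutant-like groove.
The presets do **not** reproduce secondary features of real profiles
(e.g. a local minimum mid-groove); they are deliberately minimal so that
the designed barrier is unambiguous.

## Synthetic dynamics

Sampling uses overdamped (Brownian) dynamics — only equilibrium sampling
matters for free-energy recovery, so inertia is omitted:

$$x \leftarrow x - \frac{D\,\Delta t}{kT}\nabla(U + U_\text{bias}) + \sqrt{2D\,\Delta t}\,\xi,\qquad \xi \sim N(0,1).$$

Defaults: D = 0.2 Å²/ps (a typical aqueous cation diffusivity), dt = 0.01
ps, one stored frame per 2 ps (mirroring 4500 kept frames per window for
9 ns of production sampling). One RNG stream per window, seeded
`master + window_index`, makes every generator a pure function of
(config, seed). A single-step displacement above 5 Å aborts with advice to
reduce dt.

**Known numerical bias.** The plain Euler–Maruyama update has an O(dt)
configurational sampling bias. It is negligible for second moments (the
stationary variance in a k = 10 window is inflated by ~1.7 % at dt = 0.01)
but accumulates across WHAM windows into a profile tilt: at dt = 0.01 the
recovered barrier on a reduced 25-window grid sits ~0.5 kcal/mol above the
analytic value, at dt = 0.002 ~0.2. The update formula itself is part of
the generator's contract, so the scheme is kept and the pipeline profiles
run at dt = 0.005, where the bias is below the statistical error of a
reduced run. Exact-sampling checks (below) bypass dynamics entirely.

**Exact biased sampling.** `sample_boltzmann_windows()` draws directly
from p(z) ∝ exp(−(F(z) + ½k(z−z₀)²)/kT) by inverse-CDF on a 0.005 Å grid
with in-bin jitter. This is the input for the parameter-recovery
acceptance tests: it isolates the estimator from the sampler.

**Partner beads.** Intermittent ion–partner proximity (gate residue,
in-groove lipid headgroup) is emulated by placement rules: inside the
rule's Z window, with probability p the partner is placed uniformly at
2.0–2.9 Å from the ion (inside the 3 Å contact shell), otherwise at
4–8 Å. This makes contact counting exactly controllable — the emulation
reproduces contact *statistics*, not lipid dynamics; there is no water,
no scrambling, and the "lipid" exists only as a bead and a charge.

## Umbrella bookkeeping and WHAM

Window grids are exact arithmetic on a rational grid (the production
grids are 84 windows over −10.25…10.5 Å and 96 over −12.25…11.5 Å at
0.25 Å spacing; a non-commensurate range errors rather than truncating).
The protocol defaults are k = 10 kcal/mol/Å², five 2.4-ns runs per window
with 0.6 ns discarded; supplemental stiffer windows (k = 20) can be
appended. Histograms share one 0.1 Å grid spanning the observed data
padded by one bin; neighbor overlap below 0.05 is flagged as QC advice
(the published protocol shows overlaps only qualitatively, so the
threshold is ours and is not a hard failure).

WHAM is solved by direct iteration of the standard coupled equations to a
tolerance of 10⁻⁶ kcal/mol on the window free-energy increments (no
acceleration — adequate at this problem size and simplest to verify;
~2000–8000 iterations on the production grids). Choices worth recording:

* **Gaps.** Bins with zero total count are reported as `NA`; downstream
  annotation refuses to cross a gap rather than interpolate. Two blocks
  of windows sharing no occupied bin make the relative offsets
  undetermined; this errors naming the gap.
* **Offset anchor.** The PMF minimum-equals-zero convention is applied
  over bins holding ≥ 10 counts. Taken literally over *all* occupied
  bins, one or two stray far-tail counts (bins where every window's bias
  weight is ~e⁻¹²) anchor the offset with kcal-scale downward noise; we
  observed this freezing the bootstrap error at a floor that broke the
  expected √N shrinkage. All bins are still reported.
* **Insensitivity guards.** The result is insensitive (≤ 0.05 kcal/mol
  RMS on well-covered bins) to halving the bin width and to quarter-bin
  shifts of the grid origin; both are tested, since the production bin
  width is not published.

**Bootstrap errors.** Effective sample size
`N_eff = ⌈N·Δt/τ⌉` with the stated correlation time τ = 20 ps (τ is an
input by convention, never estimated from data); each of n_trials = 200
trials resamples N_eff values per window i.i.d. from the empirical
distribution, rebuilds histograms on the original grid and re-solves
WHAM; the error bar is the per-bin SD of the min-shifted PMF across
trials. The reduced CI pipeline profile sets τ equal to the 2 ps frame
interval because the Brownian sampler's frames are effectively
uncorrelated there (harmonic-well relaxation time kT/(Dk) ≈ 0.3 ps).

## Contacts, critical ranges, events

A partner "interacts" in a frame iff the *minimum* distance from the ion
to any bead of that partner is < 3 Å (partners are counted as whole
units). Percentages are counts/total rounded to one decimal and are never
renormalized — one frame can host several interactions, so columns may
sum past 100 %. "Critical" is strict: frames > 50 % of the window total
(the worked-example rule "> 2250 of 4500"); 50.0 % exactly is not
critical. Critical ranges are maximal contiguous runs of critical windows
with endpoints reported at window centers — no sub-window interpolation,
matching the double-arrow annotation convention of PMF figures.

Permeation events in unbiased runs are defined by gate contact plus
departure, not fixed Z cuts alone: an EC→IC event opens at the first
in-groove frame with gate contact after EC bulk and closes when the ion
exits below the groove; IC→EC mirrors it (closing requires the gate to be
disengaged). The groove boundaries default to ±10 Å, the umbrella-covered
span, and are declared configuration.

## Geometry

The average permeation path is the per-Z-bin mean XY of all equilibrated
ion positions (0.25 Å bins aligned with window centers; bins with < 50
samples are flagged undefined). The pore profile is a maximal-inscribed-
sphere search restricted to each Z plane: Nelder–Mead from the previous
plane's optimum plus four jittered restarts, radius capped at 15 Å
("escaped to bulk"), non-positive optimum flagged "blocked". This is a
planar-per-Z description, sufficient for a Z-aligned groove; it does not
reimplement full 3-D channel tracing of curved pores.

## Electrostatics

The linearized Poisson–Boltzmann equation
∇·(ε∇φ) − ε_w κ²(r) φ = −4πC ρ is discretized with harmonic-mean face
dielectrics and solved by red–black SOR (ω = 1.8) to a 10⁻⁶ relative
tolerance; Dirichlet boundary values are the Debye–Hückel superposition
of the source charges. The membrane-slab model: bead interiors and a
26 Å hydrophobic core at ε = 2, 8 Å headgroup layers at ε = 30, water at
ε = 80 with an 18 Å water-filled cylinder through the slab; mobile ions
(150 mM, 1:1) screen only the ion-accessible water — the hole is
accessible, the membrane and bead interiors are not. The screening
parameter is κ² = 8π·l_B·N_A·I·10⁻²⁷ with Bjerrum length
l_B = C/(ε kT); at 150 mM, ε = 80, 310 K the Debye length is 8.09 Å,
verified in the tests against an independent SI-units computation.

Grid spacing defaults to 1.0 Å with 20 Å padding; a point charge
reproduces the Coulomb and Debye–Hückel closed forms within 5 % for
r ≥ 3 grid spacings, and superposition holds to the solver tolerance.
Fields are solved for single static configurations only (no trajectory
averaging). The production solver's grid spacing, box and boundary
condition are not published; ours are declared here and guarded by the
analytic-limit and convergence tests, with no claim of matching any
particular production code.

## Pipeline profiles

`scenario_config()` validates everything before any compute (a schema
violation raises `config_error`). The `full` profile mirrors the
production protocol (0.25 Å spacing, 5×2.4 ns windows, 200 bootstrap
trials); the `ci` profile runs 25 windows at 0.5 Å spacing over −6…6 Å
with 3×0.4 ns runs at dt = 0.005 — sized so that the end-to-end barrier
recovery error (statistical + discretization) stays within the
0.5 kcal/mol design-recovery check while the whole scenario completes in
about a minute on one CPU. Configs are JSON (no YAML parser is available
in the dependency budget; the nested-map semantics are identical). Every
output carries a config hash that excludes only the output directory.

## What a green test establishes — and what it does not

The suite establishes that the estimators recover *designed* ground
truths from *synthetic* data: exact-sampling WHAM recovery to
≤ 0.3 kcal/mol RMS, barrier recovery within 0.5–0.7 kcal/mol, √N error
scaling, analytic electrostatic limits, exact geometric lumens. It does
not establish anything about real scramblase energetics: the synthetic
world has no explicit lipids or water, its partner beads follow scripted
contact probabilities, and its potentials are smooth Gaussians. Numbers
printed by the real study (microsecond trajectories, Table-style contact
counts) enter only as *protocol constants and worked-example arithmetic*
(grid counts, 4500-frame percentages, the > 50 % rule), which the
package reproduces exactly.

## Known limitations

* Euler–Maruyama sampling bias (documented above) makes dynamics-based
  recovery accurate only to ~0.2–0.5 kcal/mol unless dt is reduced;
  exact-sampling tests carry the precision claims.
* The pore search is planar-per-Z; strongly tilted or curved channels
  would need 3-D tracing.
* The LPB solver is single-grid SOR without focusing; fine grids
  (< 0.5 Å) on large boxes get slow in pure R.
* Chloride or multi-ion permeation, lipid scrambling, and nonlinear PB
  are out of scope.
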