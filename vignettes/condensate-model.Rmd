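---
title: "A coarse-grained model for charge- and hydrophobicity-driven condensates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained model for charge- and hydrophobicity-driven condensates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(condensim)
```

## The scientific question

Intrinsically disordered proteins drive liquid-liquid phase separation
(LLPS), and the interactions holding a condensate together come in two
flavours with very different reach: electrostatic attractions between
charged residues, screened over a Debye length of ~20 A at physiological
salt, and dispersion ("hydrophobic") contacts that act only within a few
Angstrom of bead contact. `condensim` implements a one-bead-per-residue
polymer model in which these two channels can be traded against each other
residue by residue, and the analysis stack needed to quantify what the
trade does to a condensate's **stability** (critical temperature),
**structure** (coexistence densities, droplet shape, chain dimensions) and
**liquid character** (diffusion, neighbour-exchange and conformational
relaxation times).

The sequence family at the centre of the package is a 40-residue,
zero-net-charge polyampholyte whose charge pattern is tuned to a
charge-mixing score kappa = 0.55, progressively mutated so that a fraction
phi = 0 ... 0.8 of its residues become neutral hydrophobic beads (equal
numbers of + and - are always removed together, so net charge stays zero).

## The model

Each residue is one bead. Four energy terms act:

* **Bonds**: harmonic, `U = k_b (r - r0)^2` with `r0 = 3.8` A (the
  Calpha-Calpha spacing) and `k_b = 20` kcal/mol/A^2.
* **Angles**: harmonic, `U = k_a (theta - theta0)^2` with `theta0 = 120`
  degrees and a deliberately soft `k_a = 2` kcal/mol/rad^2; chains carry no
  dihedral term, so they are conformationally unrestricted beyond local
  stiffness. A switch (`angles_on = FALSE`) removes the angle term for the
  fully flexible reading. The bond/angle constants are the package's own
  choices: the model family this implements states harmonic bonded terms
  without printing constants, and these values keep the chain locally
  protein-like while leaving it disordered.
* **Screened electrostatics** between charged beads (Debye-Hueckel):
  `U = K_coul B(kappa_D) q_i q_j exp(-kappa_D r) / (eps_r r)` with
  `K_coul = 332` kcal A/mol, dielectric `eps_r = 80`, and ionic strength
  0.02 M. `B = exp(kappa_D a)/(1 + kappa_D a)` is the finite-ion-size
  correction with ion radius `a = 5.24` A (the standard form; the exact
  expression and `a` used by the original study are not printed in its
  text). Internally the prefactor is evaluated as `exp(kappa_D (a - r))`,
  which stays finite under arbitrarily strong screening.
* **Short-range dispersion** between hydrophobic beads: a 12-10
  Lennard-Jones well, `U = eps [5 (sigma/r)^12 - 6 (sigma/r)^10]` with
  `sigma = 7` A — depth exactly `-eps` at `r = sigma`, zero crossing at
  `sigma sqrt(5/6) ~ 6.39` A. The default strength `eps = 0.2` kcal/mol;
  sweeps over `eps` in 0-0.5 emulate mutations to residues of different
  hydrophobic strength.
* **Excluded volume** between all other nonbonded pairs:
  `U = eps_rep (sigma_rep/r)^12`, `sigma_rep = 4` A, `eps_rep = 0.2`
  kcal/mol (prefactor unstated in the source model; this choice makes the
  core comparable to kBT at ~3.5 A). Hydrophobic-hydrophobic pairs are
  excluded from this term by default because their 12-10 well already
  carries a repulsive core; `repulsion_on_all_pairs = TRUE` restores the
  literal "all beads repel" reading. The two readings differ only in a
  slightly harder HH core, since at the 12-10 minimum (7 A) the r^-12 term
  at 4 A scale contributes ~0.2*(4/7)^12 ~ 0.0002 kcal/mol.

Nonbonded terms exclude 1-2 and 1-3 neighbours along a chain.

### Cutoffs and tabulated evaluation

Dispersion and excluded volume are cut at 25 A. Electrostatics are cut at
1.6 Debye lengths (~35 A at 300 K, capped at 45 A at high temperature
where the Debye length grows as sqrt(T)): beyond that range the pair
energy is a few percent of kBT, and — because the system is net-neutral —
the omitted tail largely cancels between attractive and repulsive pairs.
Truncation is plain by default; `shift_at_cutoff = TRUE` shifts each term
to zero at its cutoff, which removes the energy discontinuity and is used
for the microcanonical (energy-conservation) checks.

Pair energies and forces are evaluated from cubic Hermite tables with
knots every 0.02 A and analytic derivatives at the knots. The force is the
exact derivative of the tabulated energy, so force/energy consistency
holds to machine precision by construction (verified against central
finite differences at 1e-6 relative tolerance in the test suite), and the
table error relative to the analytic forms is below 1e-6 for r > 2 A.
Below 1 A the tables continue as a linear barrier.

### Units

Lengths in Angstrom, energies in kcal/mol, temperatures in Kelvin with
`kB = 0.0019872` kcal/mol/K, bead mass 100 g/mol (one residue); the time
unit is `sqrt(mass A^2 / (kcal/mol))` ~ 489 fs. All dynamical quantities
are reported in these reduced time units, and all cross-condition
comparisons are made at matched T/Tc, so absolute time and temperature
scales never enter a comparison.

## Simulation engine

`run_langevin()` integrates the Langevin equation with the BAOAB
splitting; the OU (friction + noise) substep is exact, so the scheme
samples the target temperature for any friction. Defaults: `dt = 0.2`
time units (the stiffest term, bonds, has angular frequency 0.63 per time
unit, so omega dt < 0.13; droplet production runs use dt = 0.3, still a
factor ~5 below instability), `gamma = 0.05` per time unit (low friction
mixes configurations quickly while BAOAB keeps the ensemble exact).
Periodic boundaries use the minimum image; nonbonded forces run over a
Verlet list (cutoff + 4 A skin, rebuilt when any bead moves half the
skin) built from a cell decomposition when the box supports one.
Randomness comes from R's RNG, so a `sim_config(seed = )` makes whole
trajectories bit-reproducible.

Initial states are either dispersed self-avoiding walks
(`initialize_random`, the study-scale protocol) or a pre-assembled
droplet (`initialize_droplet`), which shortens dense-phase equilibration
at desk scale. Placement cannot avoid the 12-10 core region entirely
(its zero crossing at 6.4 A exceeds liquid packing distances), so
`minimize_frame()` — displacement-capped steepest descent — relaxes any
start before dynamics; production protocols call it routinely.

## Condensate detection and structure

Two chains are nearest neighbours when at least 5 residues of each lie
within 10 A of some residue of the other; the criterion sentence can also
be read as "at least 5 residue pairs", and `symmetric = FALSE` implements
that laxer reading. Condensates are connected components of the resulting
chain graph; the largest component is the droplet.

The dense-phase density divides the largest cluster's bead count by the
volume of its convex hull after periodic unwrapping (chains are unwrapped
bond-by-bond, then whole chains are shifted by box vectors along a BFS of
the contact graph). The hull is computed by an incremental
(beneath-beyond) algorithm implemented in the package — no qhull binding
is assumed — with a bounding-box fallback for degenerate clusters. Note
the finite-sample property of hulls: for a droplet sampled by n beads the
hull sits strictly inside the bead cloud, so absolute densities carry a
deficit that shrinks with n (~16% at n = 600, ~9% at n = 2000 for uniform
balls); it largely cancels in the temperature *differences* the Tc fit
consumes when bead counts are comparable across temperatures. Chains in
components smaller than `min_cluster_chains = 3` count as dilute;
intermediate oligomers are tracked separately so bead bookkeeping is
exact.

Droplet shape is summarized by the cyclic ratio sum
`d_x/d_y + d_y/d_z + d_z/d_x` of the three axis-aligned largest diameters
of the unwrapped largest cluster — 3 for a sphere (by AM-GM it is the
minimum, attained iff all diameters are equal), larger for elongated or
fragmented shapes. The original study's formula is only shown as an
image; this form is adopted because it reproduces both stated anchors
(sphere = 3, elongation > 3).

## Thermodynamics

`fit_critical_temperature()` fits the order-parameter branch
`rho_dense - rho_dilute = A (1 - T/Tc)^beta` with `beta = 0.325` (3D
Ising) held fixed. The model is linear in A, so A is profiled out
analytically and Tc is found by 1D minimization (coarse log grid +
`optimize`), which recovers noise-free synthetic curves to 1e-6 relative
and is scale-equivariant in the densities. Points failing a Kendall trend
test on the final half of their density series are flagged unconverged
and excluded by default; weights are inverse block-averaged variances.
`detect_reentrance()` flags curves whose dense branch rises, peaks at an
interior temperature, and falls again on cooling (the signature of highly
hydrophobic sequences).

`estimate_tc_quickscan()` is the desk-scale protocol: short
droplet-seeded runs at a coarse temperature grid feed the fit. Two
honest caveats, stated here because they shape every scaled-down result:
the dilute branch of a 20-30-chain droplet run is far from converged
(evaporation is slow), so the fit leans on the dense branch's decay; and
with the package's own bonded constants the absolute Tc of the phi = 0.2
sequence lands near 1000 K — an effective model temperature, not a
physical one. Both are why all downstream protocols use T/Tc ratios, as
the original study also does.

## Dynamics

`msd_chains()` averages squared chain-COM displacements over time origins
and chains. In the droplet context a chain contributes to a window only
if it stays in the largest cluster for the whole window, and the average
MSD of the droplet COM over the same windows is subtracted (removing the
collective droplet drift exactly as stated: MSD minus MSD, not
displacement-by-displacement; the latter is available as a sensitivity
alternative via `com_correction`). `diffusion_coefficient()` takes the
least-squares slope over lags in 5-25% of the usable range (avoiding the
short-lag ballistic and long-lag noisy ends) and divides by 6.

`correlation_time()` is the shared correlation machine: normalized
autocorrelation on a geometric lag grid, pooled over chains or pairs,
with the relaxation time read off at the 1/e crossing by linear
interpolation. A correlation that never reaches 1/e returns a `"no-decay"`
sentinel rather than a number. The interchain estimator correlates the
raw neighbour indicator h(t) (so C(t) is the probability that a contact
alive at the origin is alive at lag t), restricted to pairs in contact at
the origin; the intrachain estimator uses mean-subtracted end-to-end
distance fluctuations. The raw-vs-fluctuation choice matters: for a
symmetric two-state process the raw correlation decays to 1/2 and never
crosses 1/e, so the telegraph-recovery oracle in the tests exercises the
fluctuation form, while real contact series decay to zero as pairs
separate permanently.

## Synthetic data with known ground truth

Every analysis stage has a seeded generator whose ground truth travels
with the object (`attr(x, "ground_truth")`): droplet+gas bead
configurations with planted densities and axis ratios
(`gen_droplet_config`), Brownian walkers with known D and optional drift
(`gen_brownian`), Ornstein-Uhlenbeck series via the exact discretization
(`gen_ou_series`; autocorrelation exp(-t/tau) at every lag by
construction), symmetric telegraph contact series with exact flip
probability (`gen_telegraph`; centred autocorrelation exp(-2kt)) and
scaling-law coexistence curves with optional re-entrant deformation
(`gen_coexistence_curve`). Exact discretizations mean the recovery
tolerances in the tests measure the estimators, not generator bias.

What these fixtures do **not** emulate: interacting-polymer statistics —
correlated bead positions, chain connectivity effects on contacts,
density fluctuations near criticality. Tests passing on synthetic data
therefore validate the analysis stack, and only the scaled-down MD
protocols probe the model's actual phase behaviour.

## Scaled-down protocols and problem sizes

The documented full protocol is 100 chains of 40 residues in a 300 A
box, 1e7 steps, multiple seeds per temperature — the scale the
`"paper"` preset of `experiment_plan()` records. The package's own
measurements (tests, acceptance script, analysis drivers) run the desk
scale: 20-30 chains, 1e4-1e5 steps, droplet initialization, 1-3 seeds —
sizes chosen so a full pipeline pass completes on one CPU within minutes
while leaving the measured ratios (Rg droplet/bulk, density decay with
temperature) interpretable. At this scale the dilute branch and the
slowest relaxation times are not converged; the methods above flag
exactly which quantities inherit that limitation.

## Known limitations

* The droplet/bulk mean-Rg ratio at T = 0.5 Tc comes out near 1.15-1.25 at
  desk scale under the default parameterization: the dense-phase chains
  are reliably the more expanded ones (and their Rg distribution the
  broader one), but the magnitude of the ratio is governed by how strongly
  the isolated bulk chain collapses, which in turn depends on the bonded
  stiffness constants this model family leaves unstated. With the
  package's defaults the bulk chain stays a mildly swollen coil down to
  ~0.35 Tc rather than collapsing into a globule.

* Absolute temperature and time scales are effective; only ratios are
  comparable across parameterizations (bonded constants and the
  excluded-volume prefactor are package choices the source model leaves
  unstated).
* The nominal 0.02 M salt acts as a higher effective concentration
  because charges sit directly on the backbone; no remapping is
  attempted.
* Convex-hull densities carry the finite-sample deficit described above.
* Desk-scale Tc values are placement devices for T/Tc ratios, with fit
  uncertainty dominated by the unconverged dilute branch.
* High-phi sequences at low T/Tc can kinetically arrest (fragmented
  droplets); the shape-anisotropy and re-entrance machinery detects this,
  but converged low-T coexistence at desk scale is out of reach.
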