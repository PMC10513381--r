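---
title: "slabsim: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{slabsim: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slabsim)
```

slabsim is a desk-scale toolkit for residue-level coarse-grained (CG)
simulations of biomolecular condensates: one bead per amino acid for
proteins and RNA, one bead per nucleotide for double-stranded DNA.  It
covers the full workflow — building topologies, assigning force fields,
running reference molecular dynamics with enhanced-sampling protocols, and
analysing slab simulations for phase behaviour.  This vignette documents
the models as implemented, the tunable parameters, and the design choices
made where the problem was genuinely open.

## Unit system

Everything internal is nm, ps, amu, kJ/mol, elementary charge and Kelvin.
Coefficient tables printed in kcal are converted by the exact factor 4.184
once, at load time.  Mass densities are reported in mg/mL via the exact
conversion 1 amu/nm^3 = 1.66053906660 mg/mL, the unit condensate
coexistence curves are conventionally quoted in.  `slabsim_constants()`
exposes the constants.

## Topologies

A `cg_topology` is a bead table (mass, charge, residue code, chain) plus a
bonded-term table (bonds, angles, fan bonds).  Key constructors:

* `chain_topology()` — linear protein/RNA chains, one bead per residue.
* `parse_cg_pdb()` — reads CG or atomistic PDB files.  Proteins are
  reduced to the C-alpha position of each residue (an error names any
  residue lacking a CA record); nucleotides are reduced to the residue
  centroid.  The reduction rule is a package decision — the choice barely
  matters for CG beads but is stated here so it is not silent.
* `build_straight_chain()` — collinear starting coordinates with 0.38 nm
  spacing, the typical C-alpha virtual bond length; disordered chains are
  conventionally initialized this way before equilibration.
* `build_dsdna_topology()` — two antiparallel strands with intra-strand
  bonds/angles and inter-strand *fan bonds*: bead *i* is connected to the
  beads at tabulated offsets Delta from its Watson-Crick partner,
  wherever the partner exists.
* `replicate_into_box()` — seeded rigid random insertion (uniform
  quaternion rotation + uniform translation) with a minimum-image
  inter-copy distance constraint and a 10,000-attempt cap per copy.

Bead and molecule indices are 1-based throughout, following the host
language convention; PDB serials coincide with bead indices on write.
Charges are assigned uniformly from the registry, including terminal
residues.

## Force fields

All nonbonded forms use **energy-shifted truncation**: the value at the
cutoff is subtracted so the potential is continuous there.  Cross-engine
comparisons are sensitive to exactly this convention (tabulated potentials
in other engines cause small deviations), so the convention is locked by
tests rather than left implicit.  Default cutoffs: 2.0 nm for the pair
forms, 3.5 nm for electrostatics; both configurable.

**HPS (Ashbaugh–Hatch)** — `load_hps()`.  With the Lennard-Jones well
$\phi(r) = 4\varepsilon[(\sigma/r)^{12} - (\sigma/r)^6]$,

$$U(r) = \begin{cases}\phi(r) + (1-\lambda)\varepsilon & r \le 2^{1/6}\sigma\\
\lambda\,\phi(r) & r > 2^{1/6}\sigma\end{cases}$$

where $\lambda = \mu\,(\lambda_i+\lambda_j)/2 - \Delta$ is the pair
hydropathy under a global scale $\mu$ and shift $\Delta$, and
$\sigma_{ij}$ is the arithmetic mean of the residue van der Waals
diameters.  $\varepsilon = 0.8368$ kJ/mol (0.2 kcal/mol).  Two normalized
hydropathy scales ship with the package: KR (Kapcha–Rossky) and Urry;
`scale = "Urry"` with $\mu = 1, \Delta = 0.08$ is the optimal parameter
set for condensate work and the default.

**Wang–Frenkel (Mpipi-style)** — `load_mpipi()`.  Pair potential

$$U(r) = \varepsilon_{ij}\,\alpha
\left[\left(\frac{\sigma_{ij}}{r}\right)^{2\mu}-1\right]
\left[\left(\frac{R_{ij}}{r}\right)^{2\mu}-1\right]^{2\nu},\quad
R_{ij} = 3\sigma_{ij}$$

with $\alpha$ fixed so the minimum is exactly $-\varepsilon_{ij}$ (a
property the tests verify numerically).  $\nu = 1$, $\mu = 2$.  Charges
are scaled by 0.75 (His +0.375, RNA nucleotides -0.75), the convention of
this model family.

**Contact-matrix (MOFF-style)** — `load_moff()`.  A $1/r^{12}$
excluded-volume core plus a tanh-switched contact well,

$$U(r) = \frac{\varepsilon_{\mathrm{rep}}\sigma_{ij}^{12}}{r^{12}}
+ \frac{\epsilon_{ij}}{2}\left[1 + \tanh\!\big(\eta(r_0 - r)\big)\right]$$

with switching steepness $\eta = 7$ nm$^{-1}$ and midpoint $r_0 = 0.8$
nm; $\epsilon_{ij}$ is the 20x20 residue-pair contact matrix (negative =
attractive).

**MRG-CG DNA** — `load_mrg_dna()`.  Quartic polynomial bonded terms
$U(x) = k_2x^2 + k_3x^3 + k_4x^4$ in the deviation from the rest
geometry, for intra-strand bonds ($x = r - r_0$, nm), angles ($x =
\theta - \theta_0$, *degrees*, as the tables are degree-tabulated), and
the inter-strand fan bonds (per-Delta rest lengths).  Nonbonded
nucleotide pairs interact by excluded volume, and every phosphate carries
-1 e in the Debye–Hückel term.  `rescaled = TRUE` (default) multiplies
all bonded coefficients by `bond_scale` (default 0.9), the package's
implicit-ion recalibration knob for matching double-stranded DNA
stiffness at physiological salt; electrostatics is deliberately
untouched by it, which a field-by-field test pins down.

**Cross combinations** — `combine_cross()` merges a protein and a
nucleic-acid assignment; cross-kind pairs get excluded volume plus
Debye–Hückel only.  Both assignments must agree on the electrostatics
spec.

**Electrostatics.**  Screened Coulomb
$U(r) = \frac{q_iq_j}{4\pi\varepsilon_0\varepsilon_r}\,
\frac{e^{-r/\lambda_D}}{r}$ with the 1:1-electrolyte Debye length
computed in closed form from (salt, T, dielectric); defaults 100 mM,
300 K, $\varepsilon_r = 80$.  As salt $\to$ 0 the term converges to
unscreened Coulomb, which is a test.  Bonded 1-2 and 1-3 pairs are
excluded from all nonbonded terms; fan-bonded pairs are *not* excluded
(they are inter-strand contacts, not covalent neighbours) — this is
configurable in principle and flagged here because conventions differ.

### Parameter provenance

Parameter tables are shipped as checksummed plain-text files under
`inst/extdata/` and verified at load time.  The amino-acid registry
(masses, diameters, charges, KR and Urry scales) is standard published
data.  The MOFF contact matrix, the Mpipi epsilon/sigma matrices and the
MRG-CG polynomial coefficients are **synthetic stand-ins**, generated by
the documented deterministic recipes in the file headers (hydropathy
products with cation-pi/pi-pi bonuses; B-DNA-geometry rest lengths with
persistence-length-scale stiffness).  They have the right structure,
symmetry, units and magnitudes, and every energy/force/sampling test is
calibration-independent, but quantitative phase behaviour from these
tables should not be compared against published condensate simulations.
The HIS charge differs by convention: +0.5 e (HPS), +0.25 e (MOFF),
+0.375 e (Mpipi).

## Dynamics

**Langevin middle (BAOAB).**  Half kick, half drift, full
Ornstein–Uhlenbeck velocity refresh ($c_1 = e^{-\gamma\Delta t}$,
$c_2 = \sqrt{(1-c_1^2)k_BT/m}$), half drift, half kick.  With
$\gamma = 0$ the O-step is the identity and the integrator reduces
*exactly* to velocity Verlet — that limit is the NVE conservation test
(relative drift < 1e-4 over 1e4 steps at 1 fs on a Lennard-Jones
cluster).  Defaults follow condensate practice: friction 1 ps$^{-1}$,
timestep 10 fs.

**Nosé–Hoover.**  Single-chain thermostat in a velocity-Verlet scheme
with quarter-step chain updates.  The coupling is specified as a
"collision frequency" mapped to the inverse relaxation time $\tau$ of
the chain variable, $Q = N_f k_B T \tau^2$.  Equipartition on harmonic
systems locks the discretization for both thermostats.

**Annealing.**  `run_md()` accepts a per-step target-temperature
schedule, supporting the compress-at-150 K-then-heat slab protocol.

**MC barostat** (`npt_compress()`).  Isotropic volume moves on a cubic
box every `move_interval` steps; molecule *centroids* are rescaled
(intramolecular geometry untouched) and the move is accepted with
Metropolis weight $\exp[-(\Delta E + P\Delta V - N_{mol}k_BT\ln
(V'/V))/k_BT]$.  The proposal is uniform in $V$ with a *fixed*
half-width, making it symmetric — a volume-scaled proposal width would
need a Hastings correction and is a classic silent bias.  The
ideal-gas average $\langle V\rangle = (N+1)k_BT/P$ is recovered in a
test.  Moves that create overlaps are rejected, not fatal.

**Replica exchange** (`run_remd()`).  Neighbour swaps with
$\Delta = (\beta_i-\beta_j)(E_j-E_i)$, attempted every
`exchange_interval` steps on alternating even/odd neighbour pairs (the
standard DEEM-style sweep; the alternation choice is a package decision).
Velocities are rescaled by $\sqrt{T_{new}/T_{old}}$ on acceptance rather
than redrawn, preserving the instantaneous kinetic state.  The long-run
acceptance on a harmonic dimer is validated against dense numerical
quadrature over the two Boltzmann distributions, and equal temperatures
give acceptance exactly 1.

**Minimization.**  Adaptive steepest descent with monotone
non-increasing energy, terminating at a max-|force| tolerance.
Deliberately simple: it only prepares desk-scale states.

## Analysis

* `radius_of_gyration()` — mass-weighted, over whole (bond-walk
  unwrapped) molecules.
* `identify_largest_cluster()` — molecules are nodes, edges join
  molecule pairs with centre-of-mass minimum-image distance below the
  cutoff (default 5 nm); the largest connected component is returned,
  ties broken toward the lowest molecule index.  "Molecule" means one
  replicated copy (a pre-assembled dimer is one molecule).  The graph
  route (igraph) is cross-checked against brute-force union-find in
  tests.
* `density_profile()` — frame-averaged mass histogram along z (the
  elongated slab axis), each frame optionally translated so the largest
  cluster's COM sits at z = 0.  Bin width defaults to 1 nm (not dictated
  by anything physical; it divides the standard window edges evenly).
  Profiles conserve mass exactly and centering is idempotent.
* `coexistence_densities()` — dense phase = mean density over |z| <
  5 nm (HPS-style slabs) or 10 nm (MOFF-style), dilute phase over |z| >
  50 nm, averaged over the second half of the trajectory by default.
* `fit_critical_point()` — nonlinear least squares of
  $\rho_H - \rho_L = A(T_c - T)^\beta$ with $\beta = 0.325$ (3D Ising)
  frozen.  Initialization: $T_c = \max T + 20$ K, $A$ from the coldest
  point; $T_c$ is bounded below by the warmest fitted temperature.  The
  fit object is a classed model with `coef`/`predict`/`plot`/`residuals`
  methods.  Noiseless synthetic curves are recovered to 1e-8.
* `persistence_length()` — $C(n) = \langle \hat u_i\cdot\hat
  u_{i+n}\rangle$ over positions and frames; linear fit of $\log C(n)$
  over $n \in [2, 20]$ by default (n = 0, 1 are skipped as they carry
  rigid-constraint artefacts), $l_p = -\bar b/\mathrm{slope}$.
  Non-positive correlations inside the range shrink it with a warning; a
  perfectly straight chain reports $l_p = \infty$.  The freely rotating
  chain with fixed bend angle $\theta$ is the closed-form oracle:
  $l_p = -b/\ln\cos\theta$, matched within 2% at over 1e5 synthetic
  samples.

## The synthetic-data generator

`generate_fixture()` produces the study systems: the harmonic dimer
(thermostat calibration; analytic minimum), a 30-residue mixed-charge
disordered chain under HPS-Urry (energy/force surface with every protein
term active), a 20-bp MRG dsDNA (polynomial bonded terms and fan bonds),
a Lennard-Jones cluster (hydropathy-1 beads, i.e. plain LJ — the NVE
system), an ideal gas (NPT closed form), and the step-profile slab.  The
step-profile generator places beads *exactly at bin centers with equal
counts per bin*, so the constructed density is recovered bit-exactly by
the analysis path — a construct-then-measure oracle, not a statistical
one.  What these fixtures do **not** emulate: real condensate
configurations (equilibrated interfaces, capillary waves, finite-size
effects), long-range correlation in dense phases, or calibrated
sequence-specific phase behaviour.  Passing tests therefore demonstrate
correctness of the machinery, not accuracy of any particular published
force field.

## Numerical choices

* Minimum-image convention, orthorhombic boxes only.
* Separations below 1e-4 nm in divergent terms raise an explicit error
  rather than propagating NaN.
* Verlet neighbor list with 0.3 nm skin, rebuilt when any bead has moved
  more than skin/2 since the last build; listed energies equal brute
  force exactly because the candidate set is a superset of the cutoff
  sphere.  Brute force is used below ~60 beads where the list costs more
  than it saves.
* Straight-chain angles (180 degrees) make the angle force formally
  0/0; the implementation returns the correct limit (zero transverse
  force) below sin(theta) = 1e-8.
* The dsDNA builder uses a planar ladder at 0.34 nm/bp rise and 1.0 nm
  strand separation; the shipped rest lengths are consistent with that
  geometry, so a freshly built duplex starts at its bonded-energy
  minimum.
* One user-facing seed per stochastic operation, fanned out internally
  (replica k, segment s gets a deterministic function of the master
  seed); all RNG runs on a private stream that restores the caller's
  RNG state.

## Problem sizes

The shipped tests and the acceptance script run at desk scale by design:
systems up to a few hundred beads, 1e4–1e6 MD steps, 2e4-chain polymer
ensembles.  The engine refuses systems above 3000 beads — production
condensate simulations (hundreds of chains, 1e8 steps) belong in
GPU-accelerated engines; this package's value is that every algorithmic
ingredient of that workflow is small enough here to be verified against
independent oracles.

## Known limitations

* No Ewald/PME electrostatics (Debye–Hückel only, as in the implicit-ion
  models themselves).
* No pressure virial; the barostat uses energy differences, which is all
  a Monte Carlo barostat needs.
* Orthorhombic periodicity only; no domain decomposition or GPU path.
* The calibrated interaction matrices of the published force fields are
  not included (see Parameter provenance above).
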