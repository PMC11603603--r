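---
title: "Heavy-atom coarse graining by variational force matching"
author: "nohcg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heavy-atom coarse graining by variational force matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nohcg)
```

## The model

`nohcg` implements bottom-up coarse graining (CG) of proteins at
heavy-atom resolution. The map is deliberately simple: every hydrogen is
deleted and absorbed into the heavy atom it is bonded to, and water is
never represented (solvation is implicit in the learned potential). One
bead per heavy atom keeps the representation close to atomistic detail —
roughly half the degrees of freedom — while avoiding the excessively
smooth energy surfaces of coarser mappings.

Three ingredients define the method.

**The noh map and force aggregation.** For an all-atom configuration
$r$ with forces $f$, the CG configuration $R$ is the selection of the
heavy-atom coordinates, and each bead's force label is the *aggregated*
force
$$ F_i = f_{i_h} + \sum_{h \in H_i} f_h, $$
where $H_i$ is the set of hydrogens bonded to heavy atom $i$. Summing a
bead's internal forces cancels the stiff intra-bead terms exactly, so
the label is a far less noisy estimator of the CG mean force than the
bare heavy-atom force. Aggregation conserves the total force identically
— `aggregateForces()` is tested against a brute-force per-bead loop and
against component-wise conservation at machine precision.

**The bead embedding.** Each bead is typed by the pair (element,
number of bonded hydrogens), which is a crude but effective proxy for
hybridization and local chemistry. Enumerating the 20 standard amino
acids at standard protonation (`enumerateBeadTypes()`) realizes exactly
12 classes — C0–C3, N0–N3, O0, O1, S0, S1 — with ids assigned by sorting
on element and hydrogen count. Unusual groups (terminal variants,
nonstandard protonation) either extend the table (`strict = FALSE`) or
raise a typing error naming the offending pair (`strict = TRUE`).
Bead masses aggregate the same way as forces: element mass plus bonded
hydrogen masses, so a CH3 bead weighs 15.035 a.m.u.

**Variational force matching.** The CG potential
$\tilde U(R, z; \theta)$ is fitted by minimizing the mean squared
deviation between its negative gradient and the aggregated force labels,
$$ L(\theta) = \frac{1}{K} \sum_{k=1}^{K} \frac{1}{3 N_k}
  \bigl\lVert -\nabla_R \tilde U(R_k, z_k; \theta) - F_k
  \bigr\rVert^2 . $$
At CG resolution, energies are unavailable by construction (the free
energy of the fine system is not a per-frame observable), so forces are
the only training signal. No prior energy terms are added: the predicted
force is purely the gradient of the learned potential, and a test
verifies that a model trained to zero labels predicts zero force.

The per-component normalization ($3 N_k$ rather than $N_k$) is a
documented package choice; the two conventions differ by a constant
factor 3 that only rescales the objective.

## The potential

The potential is a strictly invariant radial-basis pair model:
$$ \tilde U(R, z) = \sum_{i<j,\; r_{ij} < r_c} \sum_m
   \theta_{p(z_i, z_j), m}\;
   e^{-(r_{ij}-\mu_m)^2/2w^2}\;
   \tfrac12\bigl(1 + \cos(\pi r_{ij}/r_c)\bigr), $$
with one coefficient vector per unordered pair of bead types, Gaussian
centers $\mu_m$, shared width $w$, and a cosine envelope that takes the
energy and its gradient smoothly to zero at the receptive field $r_c$
(10 Å by default). Because the energy depends on coordinates only
through distances, invariance under rotations, reflections and
translations — and hence force equivariance — holds by construction;
both are nevertheless asserted on random frames in the test suite, along
with agreement between the analytic forces and central finite
differences. Scalar-energy prediction only needs invariance, so nothing
is lost by not carrying directional features.

Linearity in $\theta$ has a practical payoff: the force-matching loss is
an exact quadratic, and one pass over the data accumulates its
sufficient statistics. The default trainer is conjugate gradient on that
quadratic — from a zero start it converges to the minimum-norm
least-squares solution, leaving basis functions that see no data at
exactly zero — with full-batch Adam available as an alternative.
Training is deterministic; a validation set, when given, selects the
retained checkpoint. Basis centers are best placed across the sampled
distance range (`rmin`/`rmax`); centers far outside the data create
null directions that the minimum-norm solution leaves untouched.

Pair enumeration is exact all-pairs with a cutoff test. Every system in
the package's scope (toy systems, fixtures, fast-folder-scale CG
systems of a few hundred beads) is small enough that a cell list would
not pay for its complexity.

## Dynamics

`runDynamics()` propagates beads with the BAOAB splitting of Langevin
dynamics, chosen for its configurational accuracy at large timesteps;
with zero friction it reduces to velocity Verlet, and the test suite
checks both the harmonic equipartition value $\langle x^2 \rangle =
k_B T / k$ and energy conservation in the frictionless limit. Defaults
follow the simulation protocol the method targets: 4 fs timestep,
1 ps$^{-1}$ friction, with bead masses aggregated over constituent
atoms (heavier beads are part of what makes the large timestep stable).
Units are Å, fs, a.m.u., and kcal/mol throughout; velocities are
Å/fs and $k_B = 1.9872 \times 10^{-3}$ kcal/(mol K). Thermostat noise
comes from R's RNG, so seeded runs are exactly reproducible and the
compiled engine matches the R-level `langevinStep()` draw for draw.
The integrator runs in vacuum with no constraints, no electrostatics
and no long-range corrections: all interactions are the learned
potential within its receptive field.

## Dataset curation

The curation module mirrors the filters used to assemble heavy-atom
training sets from an mdCATH-like corpus: keep domains with at most 150
residues, at most 1000 heavy atoms, and at least 50% combined
helix + sheet fraction. All bounds are inclusive for retention — a
literal reading of "more than 150 residues" as the exclusion criterion —
and secondary-structure fractions are read from dataset metadata rather
than recomputed (mdCATH ships DSSP labels). The complementary band-pass
(150–250 residues) selects a scale-up evaluation set. Trajectories at
320/348/379/413/450 K are pooled flat with temperature kept as per-frame
metadata: multiple temperatures broaden the sampled configurations, not
the model inputs.

Subsampling applies the stride within each (domain, temperature)
trajectory before pooling; splitting is by frame with a fixed seed, with
a domain-level option (`byDomain = TRUE`) for stricter held-out
evaluation. Default fractions are 0.90/0.05/0.05 and must sum to 1.
Serialization uses R-native single-file containers with a versioned,
hierarchical mdCATH-like layout (per-domain groups; per-temperature
coordinate/force arrays; metadata attributes); round trips are bitwise
and malformed files fail with the offending group named.

## Thermodynamic-consistency analysis

Trajectories are validated thermodynamically, not kinetically: featurize
with all pairwise Cα distances; reduce with time-lagged independent
component analysis (TICA, symmetrized estimation, so eigenvalues are
real and at most 1); discretize with seeded k-means++; estimate a
reversible Markov state model by iterative maximum likelihood on the
transition counts (detailed balance then holds exactly and the
stationary distribution is available in closed form); and convert
stationary weights into a free-energy surface over the first two TICA
coordinates on an 80 × 80 grid, $F = -k_B T \ln p$, min-shifted to
zero. CG trajectories are projected with the *all-atom* TICA means and
vectors (`projectCG()`), never refitted, so both resolutions share one
reduced space. Conventions follow the analysis protocol the package
targets: 4 components for fitting, 2 for surfaces, 3 for CG projection,
10% of initial frames discarded per trajectory (5% is the documented
choice for very long runs); all are arguments. Macrostates are obtained
by spectral lumping (k-means on leading eigenvectors of the transition
matrix), and `macrostateStats()` reports per-macrostate equilibrium
probability and mean/min Kabsch RMSD to a reference, defining the
native macrostate as the one containing the minimum-RMSD conformation;
a residue-range selection supports references that exclude floppy
termini.

## The synthetic systems, and what they do (not) show

The generator builds toy molecules — chains of heavy sites with
explicitly bonded hydrogens — governed by a closed-form force field
(harmonic bonds, optional angles and Lennard-Jones terms, optional
harmonic tethers). Hydrogens are light satellites on stiff bonds that
interact only within their bead, which makes the aggregated force label
an *exact* evaluation of the CG mean force for the two-site dimer: the
flagship benchmark is therefore sharp, not statistical.

The CG-solvable dimer (`dimerSpec()`) joins two CH3-like beads by a
double-well bond $h(u^2-1)^2 + t\,u$, $u = (r - r_0)/w$, with defaults
$h = 2$ kcal/mol, $w = 0.7$ Å, $r_0 = 4$ Å — a barrier of about
$3\,k_BT$ at 300 K, low enough to cross many times in a few
nanoseconds, high enough for two distinct basins. The tilt $t$ is
calibrated at construction by quadrature so the basin free-energy
difference of the exact PMF equals a designed value (1 kcal/mol by
default) at the reference temperature. The exact PMF is the pair
potential plus the radial entropy term $-2 k_B T \ln r$ that a
bond-length histogram measures in three dimensions; `analyticCgPmf()`
can omit the Jacobian term to expose the bare closed form.

`runDimerBenchmark()` runs the full loop: sample all-atom
coordinate–force pairs (50,000 frames by default, pooled over
320–450 K — pooling broadens coverage of the reaction coordinate while
the labels remain exact analytic forces), map and aggregate, train the
radial-basis potential, simulate the two-bead system for $10^6$ BAOAB
steps at 4 fs and 1 ps$^{-1}$, and compare the simulated bond-length
free energy against the analytic PMF over populated bins (≥ 50
counts within the window where the analytic PMF is below 4.5 kcal/mol).
The acceptance gate is a maximum deviation of 0.5 kcal/mol; typical
runs land near 0.15.

These toys validate the machinery — mapping, aggregation, training,
integration, analysis — under conditions where the truth is known
exactly. They do not emulate protein energetics: no secondary
structure, no many-body frustration, no solvent-mediated interactions.
Passing them shows the pipeline is correct, not that a radial pair
basis suffices for real proteins (it does not; proteins need the
many-body expressiveness of a network potential, which is exactly why
the force-matching interface is architecture-agnostic).

## Numerical and design choices

* **Indexing.** All atom and bead indices are 1-based, as everywhere in
  R. File writers convert where a format requires otherwise.
* **Serialization.** Dataset, fixture and trajectory files are R-native
  serialized objects with `format` version markers and hierarchical
  layouts, read and written only through the package's functions.
* **Bond inference.** PDB input without bond records falls back on
  element-dependent distance cutoffs (H–X < 1.2 Å, heavy–heavy
  < 1.9 Å, 2.2 Å when sulfur is involved), overridable by an explicit
  bond list.
* **Degenerate inputs.** Hydrogens not bonded to exactly one heavy atom,
  unknown (element, nH) pairs in strict mode, shape mismatches, empty
  batches, overlapping atoms (r < 10⁻⁶ Å), all-zero weights and
  non-finite forces are errors that name the offender; near-singular
  TICA covariances are regularized with a message (or rejected with
  `strict = TRUE`); k-means with no more distinct points than clusters
  degenerates to exact assignment.
* **Problem sizes.** The shipped tests and the acceptance script use
  50,000 training frames and $10^6$ dynamics steps for the flagship
  benchmark, 150,000-step chains for MSM oracles, and 500,000-point
  samples for surface checks — sizes at which the stochastic tolerances
  (3 standard errors; 0.5 kcal/mol) are comfortably resolved on a
  single CPU in well under a minute each.
* **Known limitations.** The radial pair potential cannot represent
  many-body CG physics; the engine is vacuum-only and serial; curation
  reads metadata rather than recomputing secondary structure; the
  native mdCATH HDF5 dialect is not parsed directly — fixtures follow
  the package's own documented container.
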