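---
title: "Methods: conformational-ensemble analysis for lid-gated esterases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational-ensemble analysis for lid-gated esterases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esterdyn)
```

## The problem this package addresses

Many alpha/beta-hydrolases gate their active site with a mobile lid.
Whether the lid sits open or closed, how stiff it is, and how strongly it
communicates with the rest of the protein together control substrate
access and catalytic competence.  Comparing a wild-type enzyme against a
mutant therefore comes down to a standard battery of ensemble statistics:
per-residue fluctuations, residue-residue cross-correlations, principal
components and their free-energy surfaces, persistent-contact networks
and their community structure, plus a handful of bespoke geometric
coordinates (a lid-displacement frame, catalytic-triad distances, a
restraint-compliance classifier, and a disulfide design screen for
stabilizing variants).

`esterdyn` implements that battery as reusable, tested functions.
Because real production trajectories are rarely shareable, the package
ships a synthetic-ensemble generator with *known* statistical structure,
so that every analysis stage is validated by parameter recovery against
closed forms rather than by eyeballing plots.

## The synthetic ensemble model

`build_enm()` constructs an anisotropic elastic network (ANM) on the
Calpha atoms: every pair within a `cutoff` (default 10 Angstrom, the
standard ANM choice at Calpha resolution) is joined by a Hookean spring of
uniform stiffness `gamma` (default 1 kcal/mol/Angstrom^2).  The 3N x 3N
Hessian is assembled from the usual rank-one super-elements; modes with
eigenvalue below 1e-8 times the largest are dropped, which removes the six
rigid-body modes of any connected network and, uniformly, any small-N
degeneracies (a collinear dimer keeps exactly its bond-stretch mode).  The
thermal covariance is `kT H^+` over the remaining modes, with
`k_B = 0.0019872041` kcal/mol/K and `T = 300` K by default, so energies
and the restraint force constants share one unit system.

`sample_ensemble()` draws i.i.d. Gaussian frames in the vibrational-mode
subspace with per-mode variance `kT / lambda`.  Three optional layers sit
on top:

* a **planted Gaussian mode** (`plant_gaussian_mode()`), a unit 3N vector
  with Gaussian amplitude, used to give PCA a known dominant direction;
* a **planted two-state lid** (`plant_two_state_lid()`), a mode supported
  only on the lid atoms, pointing outward along the protein-to-lid
  centroid axis, with amplitude 0 (closed) or a chosen displacement
  (open) at a chosen occupancy -- the stand-in for an open/close
  equilibrium;
* **rigid-body frame noise** (random bounded rotation plus translation),
  which downstream superposition must remove.

All randomness flows through R's Mersenne-Twister with inversion normals;
the seed is a required argument and identical calls are bit-identical.
`write_truth()` records the generation parameters and per-frame state
labels as a JSON sidecar, which is what the parameter-recovery tests read.

What the generator deliberately does **not** emulate: frames are
statistically independent (no kinetics, no autocorrelation), solvent and
side chains are absent, and fluctuations are Gaussian around one basin
(plus the planted two-state mode).  Passing the recovery tests therefore
demonstrates the correctness of the *estimators*, not their behaviour on
rugged, time-correlated real data.

## Superposition statistics

`kabsch()` is the SVD least-squares superposition with reflections
excluded (determinant +1 enforced via the sign of the smallest singular
value); collinear atom sets are refused because the rotation is
undetermined.  RMSF and the covariance-based analyses use an **iterative
average-structure reference**: fit all frames to the running mean,
recompute the mean, and repeat until the mean moves less than 1e-6
Angstrom (at most 10 iterations).  A plain first-frame reference would
bias the profile toward whatever conformation happened to come first.

`pairwise_rmsd()` computes the all-pairs best-fit RMSD matrix in closed
form: per-pair 3x3 cross-covariances are assembled from nine F x F
component products, their singular values from the trigonometric solution
of the symmetric 3x3 eigenproblem, and the reflection case handled by the
sign of the determinant.  The vectorized matrix is tested against the
looped Kabsch computation.  `cluster_frames()` runs average-linkage
hierarchical clustering on that matrix (cut at `k = 2` by default, the
usual two-major-state readout), relabels clusters by decreasing
population, and picks medoids with lowest-index tie-breaks so reruns are
identical.

Radius of gyration is mass-weighted with element masses from `bio3d`'s
periodic table; a Calpha-only mask therefore uses the carbon mass, which
is stated here because it changes nothing for equal-mass selections but
matters for mixed ones.

## Correlations, PCA, free-energy surfaces

`dccm()` uses the scalar-product convention
`C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)` on displacements from the
iterative average after superposition, giving the familiar [-1, 1] maps.
A zero-variance atom is an error naming the residue rather than a silent
NaN.  `pca_ensemble()` eigendecomposes the 3N x 3N covariance (sample
denominator F - 1); eigenvector signs are fixed by making the
largest-magnitude coordinate positive, so component orientation is
platform-independent.  Eigenvalue sums are checked against the total
variance in the tests (conservation of variance).

`fes_2d()` converts a 2D histogram to free energies,
`F = -kT ln(P / P_max)`, with empty bins masked (`NA`), the occupied
minimum exactly zero, and 60 x 60 bins by default.  For validating the
Gaussian closed form the package provides `fes_radial_profile()`, which
shell-averages occupied bins; the validation fit is restricted to radii
below 2.5 sigma because beyond that the finite-count censoring of empty
bins (a bin with zero samples carries no energy estimate) biases the
profile flat -- a property of histogram free energies generally, not of
this implementation.

One validation choice deserves a note: the planted-mode PCA recovery runs
without re-superposition (`fit = FALSE`).  The generator samples in the
vibrational subspace around a fixed mean, so there is no rigid motion to
remove, and a planted amplitude large enough to dominate the spectrum by
a factor of 100 would push a re-fit into its nonlinear regime on a
20-node fixture.  The superposition contract itself is tested separately
(rigid-noise ensembles reproduce the noise-free DCCM).

## Contacts, networks, communities

A residue pair is "in contact" in a frame if its minimum inter-atom
distance is at or below the cutoff (4.5 Angstrom heavy-atom by default;
Calpha-only models use a wider 7.5 Angstrom cutoff since Calpha atoms
stand ~3.8-7 Angstrom apart even in packed cores).  `build_network()`
keeps edges between non-covalent neighbours (|i - j| > 1) persistent in at
least 75% of frames, weighted `-log|C_ij|` with |C| clamped to
[1e-6, 1 - 1e-6] so weights stay finite.

`girvan_newman_communities()` is authored rather than delegated: the
classic loop removes the edge of maximal weighted betweenness (weights as
distances), with ties broken on the lexicographically smallest endpoint
pair for determinism.  The stopping partition maximizes Newman weighted
modularity evaluated on the *original* graph with **affinity** weights
(|C|), not the -log|C| distances: modularity treats weights as connection
strengths, and feeding it distances would invert its meaning.  (This is
exactly the pitfall in `igraph::cluster_edge_betweenness`, which applies
one weight vector in both roles; `igraph` primitives are still used for
betweenness, components and the modularity formula.)
`intercommunity_flow()` sums full-graph edge betweenness over
cross-community edges; diagonal entries hold intra-community sums so the
table conserves the total.

## Lid frame, triad distances, restraints

The lid coordinate frame puts its origin at the catalytic serine's Calpha
(residue 146), points x at the Calpha of residue 244, Gram-Schmidt
orthogonalizes y toward residue 284, and takes z = x cross y
(right-handed).  The frame is rebuilt in every frame, which makes the
lid-centroid trace invariant under global rigid motion -- a fixed frame
from the average structure would not be.  The tracked subset defaults to
the Calpha atoms of residues 192-196, the lid tip.

Triad side-chain distances default to the hydrogen-bond topology of the
Ser-His-Glu charge relay: d1 = Ser Ogamma to His Nepsilon2, d2 = Glu
carboxylate (minimum over Oepsilon1/Oepsilon2, since the two oxygens are
chemically equivalent) to His Ndelta1.  The atom names are configurable
because crystallographic conventions vary.  Coincident atoms return 0
with a warning rather than an error: a distance of zero is a statement
about the input, not a failure of the estimator.

The restraint operator is flat-bottom harmonic: zero at or below the
bound (5.5 Angstrom default) and `E = k (d - bound)^2` above it with
`k = 32` kcal/mol/Angstrom^2.  The convention is `k`, not `k/2` -- the
AMBER restraint convention -- and is stated prominently because it scales
all energies by two.  A frame is "catalytic" iff every restraint is at
zero energy; `catalytic_state_fraction()` is just that count over frames.

## The disulfide screen

`model_cystine()` places Sgamma on each residue at the ideal
Cbeta-Sgamma bond (1.81 Angstrom) and ideal Calpha-Cbeta-Sgamma angle
(114.6 degrees), scanning chi1 on a 5-degree grid, and keeps the pair
minimizing |d(S-S) - 2.04|.  Glycine gets an ideal tetrahedral Cbeta
(bond 1.53, angles 110.5 degrees).  The criteria are the native-cystine
windows: chi3 within +/-30 degrees (circular) of -87 or +97, both bond
angles within 114.6 +/- 10 degrees.  The screened angle is
Calpha-Cbeta-Sgamma -- cysteine has no Cgamma, so the occasionally quoted
"Calpha-Cbeta-Cgamma" can only mean this angle.  Geometric impossibility
(distant residues) is a recorded feasibility flag (|d - 2.04| <= 0.5
Angstrom), never an exception, so screens over all pairs always return a
complete table.  Functional-site filters then reject pairs within 10
Angstrom of any triad atom, within 5 Angstrom of any important region
(lid, pocket; any-atom distances), or on a conservation blacklist, each
with recorded reasons.  `scan_all_pairs()` prefilters at Cbeta-Cbeta <= 8
Angstrom (generous for any disulfide) and sequence separation >= 2, and
sorts by S-S deviation then chi3 deviation, so output order is
deterministic.

## The benchmark and the demo pipeline

`benchmark_structure()` builds a fixed 297-residue, three-lobe Calpha
protein by a seeded confined self-avoiding walk (bond 3.8 Angstrom,
clash distance 3.4, lobe radius 13); the geometry is inverted at build
time if needed so that the lid frame's +z axis points outward from the
protein -- "open" means +z.  The benchmark is a fixed study object
(structure seed 42); the sampling seed varies the trajectories drawn on
it.

`make_demo()` instantiates the two roles on this structure:

* **wild type** -- springs across two subdomain interfaces (residues
  1-50 | 51-99 and 199-248 | 249-297) scaled by 0.002, so those
  subdomains float semi-independently and their interface contacts drop
  below the persistence cutoff; lid two-state occupancy 1/4 at 4
  Angstrom.
* **mutant** -- cohesive subdomains, all inter-lobe springs stiffened
  6-fold (strengthened internal coupling), and a wider-opening lid
  (occupancy 2/3 at 5 Angstrom).

These conditions were designed so each planted contrast is expressed
through the mechanism the analyses actually measure: the lid contrast
through RMSF/PCA/the lid trace, and the coupling contrast through the
persistent-contact network (weakly coupled subdomains fragment into extra
communities; the stiffened mutant stays at the three-lobe count plus the
lid group).  Both lids use displacements of 4-5 Angstrom because the
two-state classifier thresholds the lid-frame z coordinate, and the
planted separation must clear the ~0.5 Angstrom thermal width of the
centroid coordinate for occupancy recovery to be a meaningful test.
600 frames per role keeps binomial occupancy noise near 0.02 while the
whole demo (generation plus full pipeline) runs in a few minutes on one
CPU; 5000-frame ensembles are used where closed-form covariance recovery
is asserted, and a 20-node ring (puckered out of plane to keep the
network in generic position) serves as the small exactly-solvable model.

`run_pipeline()` executes the stages in dependency order on a YAML or
list config, writes per-stage TSV artifacts plus a JSON report with
cross-system deltas, and stamps every report with the seed, package
version and config checksum.  Reports contain no timestamps, so a rerun
with the same config is byte-identical; timestamps go to the log file
only.  The pipeline recomputes all requested stages on each run --
incremental regeneration of individual stage artifacts is not
implemented, which costs little here because a full rerun is minutes.

## Known limitations

* Frames are treated as exchangeable; nothing here estimates
  autocorrelation times or statistical inefficiency, which a
  time-correlated trajectory would require before error bars are quoted.
* Multi-chain selection support is minimal (one chain per region), and
  insertion codes are rejected outright.
* The community layer's default contact definition at Calpha resolution
  (7.5 Angstrom) is a coarse surrogate for the heavy-atom 4.5 Angstrom
  definition used on all-atom models; counts depend on it, which is why
  it is a recorded, configurable parameter rather than a constant.
* The disulfide screen is purely geometric: no rotamer library, no
  energy term, no repacking.  It reproduces the window logic sharply (the
  tests flip each criterion by one degree), which is its job; ranking
  beyond the geometric windows is out of scope.
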