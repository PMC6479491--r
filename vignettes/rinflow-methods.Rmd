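---
title: "Ensemble analysis and residue-interaction-network centralities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble analysis and residue-interaction-network centralities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rinflow)
```

rinflow turns an ensemble of protein conformations — frames of a molecular
dynamics trajectory, or any multi-model PDB — into stability profiles,
hydrogen-bond statistics, collective-motion decompositions, a representative
structure, and a residue interaction network whose centralities nominate
residues that mediate intramolecular signalling. This vignette documents the
models, the tunable parameters, the numerical choices, and what the
synthetic-data generator does and does not emulate.

## Containers and units

A structure is a tibble of atoms (coordinates in ångström, author residue
numbering preserved alongside a 0-based sequential index); an ensemble is a
light S3 object holding the topology, an `n_frames x n_atoms x 3` coordinate
array, and strictly increasing frame times in picoseconds. All analysis
functions return tibbles, so results compose with dplyr/ggplot2 directly.
Eigenvalues and projections are reported in nm (nm²) because collective
motions of proteins are conventionally quoted on that scale; everything
else stays in ångström.

## Rigid-body superposition

All deviation-based metrics first remove global translation and rotation by
a least-squares rigid fit (singular value decomposition of the 3×3
cross-covariance, with the determinant sign guarded so only proper
rotations are returned). Fits need at least three non-collinear atoms;
collinear selections are rejected rather than silently resolved. RMSF and
covariance analysis fit frames to their *mean* structure, iterating
fit → new mean → refit. The RMSF default is 3 rounds (a
`reference = "first"` mode is available); the covariance fit iterates to a
fixed point (tolerance 1e-10 Å RMS, cap 50 rounds) so that the stored mean
is self-consistent and projecting the mean structure yields the zero
vector.

## Stability metrics

- **RMSD**: per-frame post-fit deviation over a selection (default
  `"backbone"` = N, CA, C, O), against a reference frame (default frame 1,
  standing in for the equilibrated starting structure; configurable).
- **RMSF**: per-atom RMS deviation from the time-averaged position,
  reported per residue at its Cα.
- **SASA**: Shrake–Rupley point counting on a deterministic golden-spiral
  lattice (default 960 points/atom, probe 0.14 nm, built-in vdW radii
  C 0.17, N 0.155, O 0.152, S 0.18, H 0.12 nm). The default selection is
  the backbone, matching the workflow this package supports; whole-protein
  SASA is one selection string away. Points landing exactly on a coincident
  neighbour sphere are assigned to the lower-indexed atom so degenerate
  overlaps behave like a single sphere.

## Hydrogen bonds

The detector is purely geometric: donors are N/O/S atoms with a covalently
attached hydrogen (same residue, D–H < 1.25 Å), acceptors are N/O/S, and a
triple is bonded iff the D–A distance is ≤ 3.5 Å **and** the angle at the
donor between D→H and D→A is ≤ 30°. Both cutoffs are inclusive (a 1e-9
numerical pad keeps exact boundary constructions stable), because the
occupancy bookkeeping must be exact for designed fixtures. The donor-angle
convention is the one the 3.5 Å / 30° pairing originates from; a
`"dha"` mode instead bounds the deviation from D–H···A linearity for users
who prefer that convention. Occupancy is per residue ("any bond to the
partner group in this frame"), which matches how per-residue occupancy bars
are usually presented; residues with zero occupancy are omitted from the
report. No protonation, salt-bridge or π-interaction logic is attempted.

## Essential dynamics and free-energy landscapes

The covariance of the 3M-dimensional fitted coordinate vector is
diagonalised with the population divisor (1/n_frames), the convention of
trajectory covariance tools; the projection variance along mode *i* then
equals eigenvalue *i* identically, which the tests assert at 1e-8 relative
tolerance. Covariance is unweighted (no mass weighting) by default.

Whether a 2-D landscape over two principal components is meaningful depends
on sampling: projections that resemble a half-cosine indicate
random-diffusion-like exploration. The cosine content
`(2/T)(∫ cos(iπt/T) p_i dt)² / ∫ p_i² dt` is evaluated by trapezoidal
quadrature on the actual frame-time grid, and `free_energy_surface()`
refuses to build a landscape when either chosen component exceeds 0.2
unless forced. The surface itself is a raw-count 2-D histogram (default
32×32 over the data range with a half-bin margin; 16 bins in small
examples) converted by ΔG = −k_B T ln(n/n_max), k_B = 0.0083145
kJ mol⁻¹ K⁻¹, T = 300 K by default. Empty bins are masked (`NA`), not
assigned a ceiling, so plots show them blank; kernel smoothing is
deliberately not applied, keeping the estimator unbiased and auditable. The
minimum basin is the most populated bin (ties: first in column-major
order), and its member frames are returned in time order.

## Representative selection

The total conformational energy is an *input* series (two-column time/energy
text, `#`/`@` comments tolerated): re-deriving a forcefield energy is out of
scope, and keeping it an input makes the contract explicit. The k = 20
lowest-energy frames (energy ties broken by earlier time) are clustered by
pairwise superposed RMSD with single linkage cut at 2.0 Å — chosen over
k-medoids or average linkage because single linkage at a fixed cut is
deterministic, order-independent, and auditable by hand on 20 frames. The
representative is the lowest-energy member of the largest cluster; size
ties go to the cluster containing the global minimum.

## Residue interaction networks and centralities

Nodes are amino-acid residues with two coarse-grained centers: the Cα, and
the side-chain heavy atom farthest from the Cα in the given structure
(glycine has none; alanine's is Cβ). An edge exists iff any of the ≤ 4
center-pair distances is **strictly** below 7 Å, recording which center
pairs touched, and carries the number of distinct hydrogen bonds between
the two residues as its weight (0 allowed; 0 throughout for models without
explicit hydrogens). Ligands are excluded by default
(`include_ligand = TRUE` adds each HETATM group as one node); sequence
neighbours are connected like any other pair, with an
`exclude_neighbors` option since many RIN tools drop |i−j| ≤ 1.

Shortest paths use **unit edge length** by default, so d(i,k) is the
minimum number of edges — this honours the closeness definition verbatim,
and most contact edges carry zero hydrogen bonds, which would be unusable
as path lengths. The H-bond weights remain on the edges, and a
`weights = "inverse-hbond"` mode (length 1/(1+count)) is provided for
sensitivity analysis. Degree is reported raw and as deg/(N−1); closeness is
`((Σ d)/(N−1))⁻¹`, computed per connected component and scaled by
(reachable−1)/(N−1) on disconnected graphs (the exact textbook value on
connected ones), isolated nodes reporting 0 with a warning; betweenness
uses Brandes' dependency accumulation with the 2/((N−1)(N−2))
normalisation and endpoints excluded, so a star hub scores exactly 1. The
implementation is validated against an independent exhaustive
path-enumeration oracle and against igraph on random graphs.

Reports follow the analysis conventions of this workflow: residues with
C_B ≥ 0.05 (with the threshold's empirical percentile), and between-state
|ΔC_B| tables flagged at 0.02 (reporting) and 0.03 (structure mapping),
matched by author residue label across states.

## The synthetic-data generator

`generate_ensemble()` builds an idealised extended chain (N–CA 1.46,
CA–C 1.52, C–O 1.23, C–N 1.33 Å; an amide hydrogen and a Cβ per residue;
a 0.7 Å z zig-zag so Cα selections are never collinear) and layers three
controllable signals:

1. **Fluctuations** — i.i.d. Gaussian displacement per atom and frame with
   per-residue σ per coordinate, so the expected RMSF is σ√3.
2. **Designed hydrogen bonds** — the donor N/H and acceptor O of chosen
   residue pairs are placed at absolute anchor positions: on-axis at 2.9 Å
   in exactly `round(q · n_frames)` frames (sampled reproducibly from the
   seed) and at 5.5 Å otherwise, so recovery of occupancy q is exact, not
   statistical.
3. **A collective mode** — one shared direction (default: a
   Gaussian-enveloped z-displacement with zero net translation) scaled by
   i.i.d. Gaussian per-frame coefficients. Coefficients are deliberately
   *not* sinusoidal, keeping cosine content low so the mode is admissible
   for landscape analysis. Given a `variance_fraction` target f, the
   amplitude is set to √(f/(1−f) · Σ 3σ²).

`generate_hub_structure()` places two compact residue clusters (pairwise
within contact range) whose centers are far apart, joined through a central
hub residue; each cluster faces the hub with two bridge members so the hub
is the *unique* cut vertex, making "the designed hub attains maximal
betweenness" a provable property rather than a tendency. Note a geometric
constraint here: if the hub is within 7 Å of a member of each cluster, the
triangle inequality caps the closest cross-cluster approach below 14 Å, so
the guarantee enforced is graph-level (no direct cross-cluster contact,
centers > 14 Å apart) rather than a uniform 14 Å margin on all pairs.

What the generator does **not** emulate: bonded-geometry constraints across
frames, realistic Ramachandran statistics, correlated side-chain dynamics,
solvent, or forcefield energetics (the energy series generator is an
independent noisy series with a designed minimum). Passing tests therefore
demonstrate correctness of the *analysis operators* on data with known
ground truth — not that any biological conclusion transfers to a particular
real trajectory.

## Numerical choices and degenerate inputs

- Boundary conventions: H-bond cutoffs inclusive (ties are bonds); RIN
  contact strictly `< 7 Å`; both fixed so exactness tests are well-posed.
- Alternate locations resolve to highest occupancy, ties to the first
  listed; waters are excluded on reading by default.
- Zero-variance centralities make Pearson correlations undefined; they are
  reported as `NA`, never 0.
- All-zero projections have cosine content defined as 0 with a warning.
- Reruns are bit-identical: the pipeline manifest stores content hashes and
  no timestamps, and every stochastic stage derives from an explicit seed.

## Problem sizes

The shipped tests and the acceptance script run on peptides of 5–20
residues, ensembles of 4–400 frames, and graphs of up to 12 nodes (where
exhaustive shortest-path enumeration is the oracle), with 200 random graphs
in the oracle-equivalence sweep — sizes chosen so every expected value can
be computed independently, by brute force or closed form, while the full
suite stays fast enough to run on every change.

## Known limitations

- mmCIF input, bond-order perception and protonation are out of scope; the
  H-bond detector requires explicit hydrogens.
- Closeness on disconnected graphs uses the component-scaled variant; other
  tools may report unscaled per-component values.
- SASA is quadrature-based; values carry ~1% error at 960 points
  (the isolated-sphere closed form is reproduced to that tolerance).
- The FEL is a raw-count estimator; sparse sampling shows as rugged
  landscapes rather than being smoothed away.
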