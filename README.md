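# rinflow

Post-simulation analysis of protein conformational ensembles in R:
stability metrics, hydrogen-bond occupancy, essential dynamics with
free-energy landscapes, minimum-energy representative selection, and
weighted residue-interaction-network (RIN) centrality analysis with
between-state difference maps.

The package is aimed at structural bioinformaticians who have a set of
conformations of a protein — typically frames sampled from a molecular
dynamics trajectory, stored as a multi-model PDB — and want to go from raw
coordinates to a ranked list of residues that mediate intramolecular signal
flow, comparing e.g. an apo state against ligand-bound states. A
synthetic-ensemble generator with known, parameterised properties makes
every stage testable without external data.

## The methods at the core

**Stability.** Per-frame backbone RMSD against a reference frame after
optimal rigid-body superposition (SVD-based least-squares fit with a
reflection guard), per-residue RMSF of Cα atoms about the iteratively
fitted mean structure, and Shrake–Rupley solvent-accessible surface area
(probe 0.14 nm, 960 deterministic sphere points).

**Hydrogen bonds.** Geometric detection per frame: a donor–hydrogen–acceptor
triple counts as bonded iff the donor–acceptor distance is ≤ 3.5 Å and the
angle at the donor between D→H and D→A is ≤ 30° (both boundaries
inclusive). Occupancy is the fraction of frames in which a residue forms at
least one bond with the partner group.

**Essential dynamics.** After removal of rigid-body motion, the 3M-dimensional
coordinate covariance matrix is diagonalised; eigenvalues (nm²) rank the
collective modes. Projections whose cosine content

c_i = (2/T) (∫ cos(iπt/T) p_i(t) dt)² / ∫ p_i(t)² dt

is ≤ 0.2 define a free-energy landscape by Boltzmann inversion of the 2-D
projection histogram, ΔG(bin) = −k_B T ln(n_bin / n_max), so the most
populated bin sits at ΔG = 0 and empty bins are masked.

**Representative selection.** Frames are ranked by a supplied total
conformational energy series; the 20 lowest-energy frames are clustered by
pairwise superposed RMSD (single linkage, 2.0 Å), and the lowest-energy
member of the largest cluster becomes the representative structure.

**RIN centralities.** Each amino acid contributes two coarse-grained centers
(Cα, and the side-chain heavy atom farthest from Cα); two residues are in
contact iff any center pair is closer than 7 Å, and the edge weight is the
number of hydrogen bonds between the residues. On this graph the package
computes

- degree C_D(k) = deg(k) (and deg/(N−1)),
- closeness C_C(k) = ((Σ_i d(i,k)) / (N−1))⁻¹ with Dijkstra/BFS
  shortest-path distances,
- betweenness C_B(k) = [2/((N−1)(N−2))] Σ_{s<t} σ_st(k)/σ_st via Brandes'
  algorithm,

plus reports of residues with C_B ≥ 0.05 and per-residue |ΔC_B| between two
states flagged at 0.02 / 0.03 — the quantities used to nominate residues
that mediate allosteric signal flow.

## Worked example

```r
library(rinflow)

spec <- ensemble_spec(
  n_residues = 15, n_frames = 100, fluctuation = 0.25,
  hbond_pairs = list(list(donor = 3, acceptor = 12, occupancy = 0.8)),
  collective_mode = list(variance_fraction = 0.9), seed = 42
)
ens <- generate_ensemble(spec)

occupancy_table(ens, "resid 3", "resid 12")
#> # A tibble: 1 × 4
#>   residue_index label occupancy n_frames
#> 1             2 A3          0.8      100
```

The designed donor (residue 3) recovers exactly the 0.8 target occupancy.
Essential dynamics finds the designed collective mode as PC1:

```r
ed <- fit_essential_dynamics(ens, "backbone")
ed
#> <essential_dynamics> 180 modes from 100 frames ('backbone')
#>   total variance 1.073 nm^2; PC1 89.3%, PC1-2 90.4%

proj <- project_ensemble(ens, ed, k = 2)
c(pc1 = cosine_content(proj, 1), pc2 = cosine_content(proj, 2))
#>          pc1          pc2
#> 8.324592e-05 1.290407e-02

fel <- free_energy_surface(proj, n_bins = 16, temperature = 300)
fel
#> <free_energy_surface> PC1 x PC2, 16 x 16 bins, 100 frames, T = 300 K
#>   deltaG range 0..5.981 kJ/mol over 39 populated bins
```

Both cosine contents are far below the 0.2 admissibility bound, so the
landscape is meaningful; its deepest basin sits at ΔG = 0 by construction.
A designed energy minimum at frame 37 is recovered as the representative:

```r
energy <- generate_energy_series(100, minimum_at = 37, seed = 43)
select_representative(ens, energy, "backbone", k = 20)
#> <representative_set> 20 low-energy frames, 1 cluster(s) at 2.00 A
#>   lowest-energy frame 37; representative frame 37 (t = 36 ps)
```

On a two-cluster structure bridged by a single hub residue, the hub tops the
betweenness ranking, exactly as its construction guarantees:

```r
hub <- generate_hub_structure(n_per_cluster = 5, seed = 7)
cent <- centrality_table(build_rin(hub, cutoff = 7.0))
threshold_report(cent, cb_min = 0.05)
#> # A tibble: 6 × 7
#>    node label chain degree degree_norm closeness betweenness
#> 1     1 G1    A          5         0.5     0.667      0.556
#> 2     7 G7    A          5         0.5     0.588      0.2
#> ...
```

`autoplot()` methods produce ggplot figures for each result type
(RMSD/RMSF/SASA series, occupancy bars, eigenvalue spectra, PC1/PC2
projections, free-energy surfaces, centrality profiles and difference
maps), and `run_pipeline()`/`compare_states()` orchestrate the whole chain
into TSV/JSON outputs with a reproducibility manifest.

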