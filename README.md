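# vasculotopo

Geometric and topological quantification of 3D vascular networks from
binary vessel volumes, as acquired by light-sheet microscopy of optically
cleared brain tissue.

Glioblastoma remodels brain vasculature in ways that individual-vessel
measurements (radius, length, density) capture only partially; the
*connectivity* of the network changes more dramatically. This package
implements the full analysis chain needed to see both:

1. **Volume conditioning** — Gaussian smoothing with re-binarization, hole
   filling, speck removal (6 µm sphere rule), skeleton-preserving
   circumferential thinning, region masking.
2. **Skeleton → graph** — topology-preserving 3D thinning (26/6 digital
   topology, Rcpp), endpoint/junction/slab tagging, and conversion to an
   undirected spatial multigraph: 26-adjacent junction voxels merge into
   single branch nodes, slab paths become edges carrying their centerlines;
   multi-edges, self-loops and degree-2 nodes are retained.
3. **Vessel geometry** — per-segment length *l*, endpoint separation *d*,
   tortuosity τ = *l*/*d*, distance-transform radius profiles, lateral
   surface area; tiling-box fVV and MVD (500 µm boxes); global densities
   ρ_L (mm/mm³) and ρ_A (mm²/mm³); clearing-shrinkage rescaling
   (lengths × (1−s)^(−1/3)).
4. **Network topology** — degree distribution P(k) with power-law exponent
   γ (least squares on log–log frequencies, k ≥ 5), local clustering
   C_i = 2E_i/k_i(k_i−1) with the hierarchical exponent β from robust fits
   of C_i(k_i) ~ k_i^(−β), characteristic path length L and diameter D,
   and matched Erdős–Rényi baselines.
5. **Community analysis** — Louvain unfolding with exact weighted
   modularity Q = (1/2m) Σ_ij [A_ij − k_i k_j/2m] δ(c_i, c_j); per-community
   structure (n, e, perimeter P, centroid, extent R, degree k_c = 2e + P);
   the weighted community meta-network with C_c, L_c, D_c; isolation
   exponent ξ (P ~ e^ξ), assortativity exponent κ (⟨k_c1⟩ ~ k_c^κ), and
   path length versus physical separation L_c(Δ).
6. **Cohort statistics** — Kruskal–Wallis tests on per-specimen summaries.

A synthetic phantom generator (`phantom_spec()`, `generate_network()`,
`voxelize()`, `corrupt()`) produces vascular networks with known
ground-truth topology — healthy-like capillary meshes fed by bifurcating
arterio-venous trees, fragmented endpoint-rich tumor-like variants, and
deterministic tree phantoms — so every stage of the chain is validated
against an exact oracle. Pure-graph generators (G(n,m), a deterministic
hierarchical model, configuration-model power laws) serve as estimator
oracles.

## Worked example

```r
library(vasculotopo)

spec <- phantom_spec(domain_size_um = c(800, 800, 400), mode = "custom",
                     tree_levels = 3, radius_range_um = c(7, 10), seed = 5)
gt  <- generate_network(spec)         # known truth: 16 nodes, 15 edges
vol <- corrupt(voxelize(gt),
               noise_spec(speck_count = 10, hole_count = 5,
                          boundary_fuzz_prob = 0.03, seed = 105))
vol <- remove_specks(fill_holes(smooth_and_rebinarize(vol, 1)), 6)
sk  <- skeletonize(vol)
vg  <- build_graph(sk)
vg
#> vascular_graph: 16 nodes, 15 edges
seg <- segment_geometry(vol, vg, sk)
summarize_geometry(seg)[4, c("median", "q95")]
#>     median      q95
#> 4 1.102897 1.372924
```

The corrupted, re-conditioned volume yields back exactly the ground-truth
topology (16 nodes, 15 edges, identical degree multiset), and the tortuosity
summary reflects the straight tree segments plus lattice-path overshoot.

The numbered scripts under `analysis/` run the full study-style workflow —
phantom cohorts, the image pipeline, geometry/topology/community tables —
and write their outputs under `results/`:

```sh
Rscript analysis/01_simulate_phantoms.R
Rscript analysis/02_image_pipeline.R
Rscript analysis/03_geometry_cohorts.R
Rscript analysis/04_topology.R
Rscript analysis/05_communities.R
```

## Limitations

Radii below ~3 µm appear with single-voxel thickness at the default
anisotropic grid and are not measured accurately (by design — the topology
is unaffected). The phantom generator emulates the topological and
density signatures of healthy and tumor vasculature, not radius
heterogeneity, core–periphery gradients, or assortative community mixing;
see the methods vignette for the full validation envelope.
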