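# taugraph

Band-specific amplitude-envelope-correlation connectomes and Tau-associated
graph metrics for E/MEG resting-state studies.

In early Alzheimer's disease, Tau aggregation disrupts synaptic function
before overt atrophy, and the disruption is visible in the organisation of
neurophysiological networks. `taugraph` implements the analysis chain that
links the two measurements: parcel-level E/MEG time series on one side,
regional Tau burden from PET (the nondisplaceable binding potential,
BP<sub>ND</sub>) on the other. It is written for neurophysiologists and
methods researchers who want a tested, scriptable version of this pipeline —
and, because no raw patient data are publicly deposited for studies of this
design, it ships a synthetic-cohort generator with known ground truth so
every stage can be validated end to end.

## The method

Starting from parcel (or vertex) time series at sampling rate *f*<sub>s</sub>:

1. **Spectral decomposition.** Zero-phase fifth-order Butterworth band-pass
   filters (realised as second-order sections, stable down to the 0.1 Hz
   delta edge) split the signal into delta (0.1–4), theta (4–8), alpha
   (8–12), beta (12–30) and gamma (30–95 at a 200 Hz analysis rate) bands;
   gamma is notch-filtered at mains. Data are cut into 4 s epochs and
   decimated to 200 Hz. Parcels are summarised by their first eigenvariate.
2. **Leakage correction.** Source leakage mixes parcel signals with zero
   lag. `symmetric_orthogonalize()` replaces the parcel set with the
   *closest* (least-squares, Frobenius) set of mutually orthogonal time
   courses, iterating a polar-decomposition step with per-parcel rescaling,
   removing all shared zero-lag signal at once.
3. **Connectivity.** The Hilbert envelope of each band-limited parcel is
   correlated with every other parcel's envelope: the amplitude envelope
   correlation (AEC) matrix. Proportional thresholding keeps the strongest
   25% of connections as a weighted graph, so every subject has the same
   edge count.
4. **Nodal graph metrics.** Four per-node measures: eigenvector centrality
   (leading eigenvector of the weight matrix), weighted clustering
   (geometric-mean triangle formulation), closeness centrality (inverse
   summed shortest path length, lengths = 1/weight) and participation
   coefficient over a Louvain community partition. Each is normalized
   against 500 degree-preserving null graphs (edge-swap rewiring with the
   original weight multiset reassigned): the reported value is
   raw / null-mean, with the z-score kept alongside.
5. **Statistics.** General linear models relate unit-level metrics (whole
   brain, five lobes, or the high-Tau ROI set) to group, regional Tau and
   visit, adjusting for age, site and regional gray-matter atrophy.
   Familywise error across each metric's units × bands family is controlled
   by max-|t| permutation (500 permutations): Freedman–Lane residual
   permutation for continuous predictors, group-label permutation within
   site strata for group contrasts, sign-flipping for paired longitudinal
   contrasts. Results are reported at corrected α = 0.01.

The ROI set is defined from the group-mean Tau map: bilateral regions whose
burden exceeds the cortical mean — on the packaged group table, 21
temporo-parietal-occipital regions.

## Worked example

Simulate twelve alpha-band parcels in three coupled modules with 30% source
leakage, correct the leakage, and estimate the connectome:

```r
library(taugraph)

band     <- canonical_bands()$alpha
coupling <- generate_envelope_coupling(modules = rep(1:3, each = 4),
                                       within_r = 0.5, between_r = 0.1)
series   <- generate_band_series(coupling, band, duration = 300,
                                 leakage_strength = 0.3, seed = 42)

A <- series |>
  symmetric_orthogonalize() |>
  epoch(4) |>
  hilbert_envelope() |>
  aec()
A
#> <association_matrix> 12 parcels (alpha), mean r = 0.222, range [0.023, 0.762]

G <- proportional_threshold(A, density = 0.25)
G
#> <weighted_graph> 12 nodes, 16 edges (density 0.25)

tbl <- compute_all_metrics(G, n_nulls = 100, seed = 1)
dplyr::filter(tbl, metric == "clustering_coefficient")
#> # A tibble: 12 x 7
#>    node metric                   raw null_mean null_sd ratio zscore
#>   <int> <chr>                  <dbl>     <dbl>   <dbl> <dbl>  <dbl>
#> 1     0 clustering_coefficient 0.704    0.0875   0.129  8.05   4.79
#> 2     1 clustering_coefficient 0.694    0.0599   0.107 11.6    5.94
#> ...
```

The modular structure survives leakage correction: within-module envelope
correlations (~0.5 by construction) dominate the retained edges, and
clustering sits far above its degree-preserving null (ratio ≫ 1). A full
study — synthetic cohort, all bands, metrics, and the three statistical
suites — runs through one call:

```r
cfg <- pipeline_config(parc = load_parcellation(taugraph_example("atlas_toy24.tsv")),
                       duration = 60, bands = c("alpha", "beta"),
                       n_nulls = 50, n_permutations = 200, seed = 1)
res <- run_pipeline(cfg, out_dir = "run1")   # CSV tables, t-map grids, manifest
```

or from a shell via the thin CLI: `Rscript inst/cli/taugraph run-all --toy
--seed 1 --out run1`.

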