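---
title: "Envelope connectomes, null-normalized graph metrics, and Tau association: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Envelope connectomes, null-normalized graph metrics, and Tau association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taugraph)
```

## Scope and model

`taugraph` estimates band-specific functional connectomes from parcel-level
E/MEG time series and tests their graph-theoretic organisation against
regional Tau burden (PET BP~ND~), group membership and six-month change.
The pipeline starts at the parcel (or vertex) level: sensor cleaning,
forward modelling and source inversion are upstream physics and out of
scope, as are PET kinetic modelling and MRI segmentation — the package
consumes finished BP~ND~ and gray-matter tables.

The statistical object at the centre is the **amplitude envelope
correlation (AEC)**: the Pearson correlation between the Hilbert-transform
magnitude envelopes of two band-limited parcel signals. AEC is attractive
in this setting because it is robust to the residual phase structure of
source-projected data once zero-lag leakage has been removed, and because
it is among the most repeatable connectivity estimates at the single-subject
level after leakage correction. Its key assumptions: the band-limited
signal is well described as a slowly modulated oscillation (the envelope
varies much more slowly than the carrier), and linear zero-lag mixing is
the dominant artifact to remove.

## The signal chain and its numerical choices

**Band-pass filtering.** Fifth-order Butterworth designs for delta
(0.1–4 Hz), theta (4–8), alpha (8–12), beta (12–30) and gamma bands. Two
choices matter numerically:

* Filters are applied **forward-backward** (zero net phase). Envelopes are
  lag-sensitive, so any phase distortion would bias AEC; zero phase is the
  defensible default and is asserted by a cross-correlation test (peak at
  lag 0).
* Designs are realised as **cascaded second-order sections** (biquads)
  rather than a single transfer function. A 10th-order band-pass polynomial
  with a normalized edge of 0.001 (0.1 Hz at 200 Hz) is numerically
  singular — the transfer-function form produces overflow — while the
  biquad cascade keeps every factor well conditioned. The designer works in
  the analog domain (Butterworth prototype poles, band transform, bilinear
  map) and pairs conjugate poles into sections; gain is normalized at the
  warped centre frequency and distributed evenly across sections.

**Gamma band and sampling rate.** The analysis rate is 200 Hz, so the
nominal 30–100 Hz gamma band touches Nyquist; it is truncated to
30–95 Hz (`0.475 * fs`) and the truncation is recorded in the band spec.
Gamma additionally receives a zero-phase IIR notch (default 50 Hz mains,
quality factor 35, configurable).

**Epoching and decimation.** Continuous data are cut into consecutive 4 s
epochs (a 300 s recording gives 75), the trailing partial epoch discarded.
Decimation applies an 8th-order low-pass at 80% of the target Nyquist and
keeps every k-th sample; only integer factors are supported (1000→200 Hz
is factor 5) and anything else errors rather than silently resampling.

**Eigenvariate.** A parcel's vertex-by-time matrix is summarised by its
leading right singular vector scaled by the singular value. The SVD sign is
arbitrary, so determinism requires a rule: the time course is flipped to
correlate nonnegatively with the vertex mean. Downstream results are
sign-blind (envelopes are magnitudes), but reproducibility is not.

**Hilbert envelopes and epoch edges.** The analytic signal is computed per
epoch by the frequency-domain mask; epochs are then concatenated. Because
the in-epoch transform is circular, the first and last 10% of each epoch's
envelope samples are flagged invalid and excluded from correlation. The
exclusion window is a package choice (the transform's edge bias is real but
its extent is not standardised); it is switchable (`edge_frac = 0`), and a
single global valid-sample mask is applied to **all** parcels — no
pairwise-complete handling — so the correlation matrix stays positive
semidefinite in expectation.

## Leakage correction

Source leakage adds zero-lag linear cross-talk between parcels.
`symmetric_orthogonalize()` removes it multivariately: find the set of
mutually orthogonal time courses closest, in the least-squares sense, to
the originals. The iteration alternates (a) the orthonormal Procrustes
(polar-decomposition) solution for the best orthonormal frame with (b)
per-parcel least-squares rescaling, and stops when the relative distortion
change falls below 1e-12 or at 100 iterations — strict constants chosen for
desk-scale inputs, not taken from any reference. Rows are demeaned first so
that zero inner products coincide with zero Pearson correlations; a test
asserts residual pairwise |r| < 1e-8 and idempotence to 1e-10.

Degenerate inputs are rejected explicitly: fewer samples than parcels, or
numerical rank below the parcel count (tolerance `1e-10 * largest singular
value`), with the closest near-duplicate row pair named in the error. The
correction is applied to the band-limited series **before** envelope
computation, over concatenated epochs as one matrix; per-epoch
orthogonalization would cap the parcel count at the epoch length (800
samples) and is not the default.

## Graphs, metrics, nulls

The AEC matrix is proportionally thresholded at density 0.25: exactly
`floor(0.25 * n(n-1)/2)` strongest edges are retained with their weights
(1188 edges at 98 parcels). Three conventions make this deterministic and
well defined:

* `floor`, not `round`, so edge sets are nested across densities;
* ties broken by (i, j) lexicographic order;
* negative correlations are never retained — the metric definitions
  (paths, triangles) require nonnegative weights; if fewer positive edges
  exist than requested, only the positives are kept, with a warning.

The four nodal metrics follow the weighted-undirected conventions of the
standard brain-connectivity toolboxes: eigenvector centrality is the
leading eigenvector of the weight matrix (unit Euclidean norm, computed on
the largest connected component with zeros and a flag elsewhere); weighted
clustering is the geometric-mean (Onnela-type) triangle formulation on
weights rescaled by the graph maximum; closeness uses reciprocal weights as
lengths with a `(r-1)/(n-1)` reachability penalty so fragmented null graphs
keep finite, comparable values; participation uses a Louvain partition,
taking the best of 100 seeded restarts (run-to-run variability of Louvain
is real; best-of-restarts with a fixed seed makes it reproducible).

Null normalization: 500 graphs with the observed graph's **binary degree
sequence** (edge-swap rewiring, 10 attempted swaps per edge) and its exact
weight multiset reassigned at random. "Equivalent degree" could also mean
strength-preserving nulls; that alternative is noted but not implemented.
The primary normalized value is the ratio raw/null-mean — the convention
for small-world-type indices — with the z-score stored alongside; nodes
whose null mean is below 1e-12 are set missing with a flag. Complete graphs
admit no degree-preserving swap; nulls then keep the topology and permute
weights only, with a warning.

## Statistics

Analysis units are the whole cortex, five lobes (parcel means) and the
high-Tau ROI set: bilateral regions whose group-mean BP~ND~ strictly
exceeds the cortical mean (ties excluded — the literal reading, and
deterministic). On the packaged group table this yields 21
temporo-parietal-occipital regions.

Each suite fits one OLS GLM per (unit, band, metric):

* **Group**: metric ~ group + age + site; group labels permuted within site
  strata (controls come from a single site, so strata keep the permutation
  honest).
* **Tau**: patients only, metric ~ local BP~ND~ + age + site + local
  atrophy; Freedman–Lane residual permutation (permute reduced-model
  residuals, refit the full model).
* **Longitudinal**: within-subject month-6 minus baseline differences
  tested against zero with age and site covariates, permuted by
  sign-flipping the reduced-model residuals. Covariates are centred so the
  intercept is the covariate-adjusted mean change; an uncentred,
  near-constant age column would absorb the shift being tested.

The familywise correction is the max-|t| distribution over each metric's
units × bands family with shared permutations, and
`p = (1 + #exceedances) / (n_perm + 1)`, so no p value is ever zero.
Group and Tau tests are two-sided at corrected α = 0.01; the
Tau-cognition partial correlations are one-tailed. Residual degrees of
freedom are `n - p` with the package's own bookkeeping. Missing values are
handled by family-wise listwise deletion — tests with no data are dropped
first, then subjects missing any remaining value, both logged — because
shared max-|t| permutation requires every test in a family to share its
subjects.

## The synthetic cohort: what it emulates, and what it does not

The generator produces a full study with recorded ground truth:

* **Signals**: independent white-noise carriers band-passed with the
  package's own filters, amplitude-modulated by positive envelopes
  `exp(sigma * g)` where `g` are slow latent Gaussians (low-passed at
  `min(1, band_low/2)` Hz) with a prescribed correlation matrix, then mixed
  by `I + a M` (`M` random sparse symmetric, unit spectral radius,
  `a < 1` so the mixing is invertible). Latent noise is synthesized with
  burn-in padding trimmed after filtering; without it, filter edge
  transients dominate the standardized modulators and explode through the
  exponential.
* **Calibration**: the observable AEC of this model is a distorted version
  of the latent correlation — lognormal envelopes and the carrier's own
  Rayleigh envelope attenuate it, with closed form
  `r_obs = pi (v^rho - 1) / (4v - pi)`, `v = exp(sigma^2)`. The generator
  inverts this to pick the latent correlation, and the achievable ceiling
  (π/4 as modulation depth grows; ≈0.74 at the default `sigma = 1.25`) is
  stored with the ground truth. Recovery tests therefore compare against
  the *achievable* target and use generous tolerances.
* **Cohort structure**: 12 patients and 12 controls by default, three
  sites, 9 patients with a month-6 visit, five-minute recordings at 200 Hz
  (signals are generated directly at the analysis rate; the 1000 Hz
  acquisition is exercised by a dedicated decimation test instead of every
  simulation). Patient global uptake is drawn from 0.12–0.31 and Tau maps
  carry a posterior (temporo-parietal-occipital) loading; controls get
  near-zero Tau. Patients' couplings are scaled by `1 + beta * tau_i`
  (default `beta = -1` at the coupling level), and month-6 visits apply a
  global coupling change. Small additive site offsets give the site
  covariate something real to remove.
* **Metric-level fast path**: `simulate_metric_study()` generates
  unit-level metric tables directly from the GLM the suites assume. It is
  the null simulator for type-I-error calibration and the effect injector
  for power checks. The default Tau slope (−4.5 in normalized-metric units
  per unit BP~ND~) was calibrated by simulation to give roughly 80%
  corrected detection power at n = 12 — the design's one free parameter,
  fixed once.

What the generator does **not** emulate: sensor arrays, head models and
inversion error; non-stationarity, artifacts and bad channels; 1/f spectra
and cross-frequency structure; PET counts or kinetic-model noise;
spatially graded (distance-dependent) leakage. Passing recovery tests
therefore shows the pipeline is correct and calibrated under its own
assumptions — not that those assumptions exhaust real MEG data.

## Problem sizes in the standing tests

The test battery runs at desk scale by design: oracle equivalence on 200
random weighted graphs of up to 8 nodes against brute-force
implementations (dense eigen-decomposition, Floyd–Warshall, explicit
triple loops); leakage-contrast checks over 50 seeds at 6 parcels × 60 s;
familywise-error calibration over 200 simulated studies with a 48-test
family and 500 permutations each; power and sign-recovery over 50 seeds;
and an end-to-end smoke run of the full pipeline on a 24-parcel toy cohort
(12 + 12 subjects, 60 s recordings, alpha and beta bands, reduced null and
permutation counts recorded as manifest overrides), run twice to assert
bit-identical outputs. The canonical defaults (4 s, 200 Hz, density 0.25,
500 nulls, 500 permutations, α = 0.01) are asserted separately and are
never altered by the reduced-scale runs.

## Known limitations

* Closeness centrality scales with the weights (lengths are 1/w); the
  null-ratio normalization removes the common scale, but raw closeness
  values are comparable only within a subject-band.
* Eigenvector centrality on badly fragmented graphs concentrates on the
  giant component; at very low densities (or tiny toy graphs) many nodes
  get missing normalized values, and the suites' listwise deletion will
  shrink the sample. The packaged densities avoid this regime.
* The permutation schemes assume exchangeability within strata
  (group), of reduced-model residuals (Tau), and sign-symmetry of paired
  differences (longitudinal). Strong heteroscedasticity across sites would
  violate the first; none of the generators produce it.
* Strength-preserving nulls, pairwise-orthogonalized AEC variants,
  phase-based connectivity and dynamic (sliding-window) connectivity are
  out of scope.
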