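---
title: "Methods: volume scaling of connectome modularity and communication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: volume scaling of connectome modularity and communication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(connscale)
```

## The question and the model

Mammalian brains span more than four orders of magnitude in volume, yet
every connectome must fit its wiring inside a skull and pay the metabolic
price of its axonal tracts. `connscale` operationalizes one question: *how
do modular organization and communication efficiency of a weighted,
spatially embedded brain network change with brain volume?* Each animal
contributes one connectome bundle — a symmetric non-negative weight matrix
(streamline-count-derived), node centroid coordinates, hemisphere labels,
sparse tract lengths, and volumetric metadata — and the pipeline reduces it
to a row of scalar features whose rank correlation with volume across
animals is the result.

## Modular organization

Modules are found by maximizing modularity under the configuration null,

$$Q(\gamma) = \frac{1}{2m} \sum_{ij}\Big[W_{ij} - \gamma \frac{k_i k_j}{2m}\Big]\,\delta(\sigma_i, \sigma_j),$$

with the resolution parameter $\gamma$ controlling granularity. We report
$Q$ normalized by total weight $2m$: this does not change the argmax at
fixed $\gamma$ and makes values comparable across networks. Louvain
optimization is delegated to `igraph::cluster_louvain` with seeded R
random state, so every run is reproducible; `optimize_partition()`
additionally evaluates the all-singleton and one-module baselines and never
returns a worse partition than either.

Because no single resolution is privileged, the pipeline sweeps many. The
two-step multiresolution procedure first runs one Louvain optimization at
each of `n_gamma` logarithmically spaced resolutions over $[0.01, 10]$ and
brackets the informative range: $\gamma_L$, the smallest resolution with at
least 2 modules, and $\gamma_H$, the largest with at most $N/2$. It then
re-sweeps `n_gamma` log-spaced resolutions inside $[\gamma_L, \gamma_H]$,
dropping any partition whose module count leaves $[2, N/2]$. The retained
ensemble gives the co-classification matrix `CC` (pairwise co-assignment
frequency) and, by clustering `CC` itself (Louvain at $\gamma = 1$, 100
restarts, best $Q$), the consensus partition.

**Joint versus per-animal bracketing.** In a cohort, the bracket can be
found per animal or jointly — a single $[\gamma_L, \gamma_H]$ that yields
2 to $N/2$ modules for *every* animal (the intersection of the per-animal
brackets). The cohort pipeline defaults to joint bracketing
(`gamma_mode = "joint"`), for a substantive reason: per-animal brackets let
strongly spatial networks spend most of the sweep in their long
two-module (hemisphere-split) regime, flooding `CC` with coarse structure
and making consensus granularity bistable across animals. The joint
bracket anchors the lower end at the most-integrated animal's splitting
point, so the ensemble concentrates on scales that are informative for
everyone and module-level features (notably intramodule density) become
comparable across the cohort. Per-animal mode remains available for
single-network use.

Features derived from the consensus and `CC`: **IMD** (mean within-module
realized edge density, singleton modules excluded as their density is
undefined), the **long-distance fraction** (count of the top-5%-longest
existing edges, by Euclidean distance, that bridge modules, normalized by
module count; ties in length broken by ascending node index, count
= ceil(0.05·E)), and the **interhemispheric index** (mean `CC` over
inter-hemisphere pairs / mean over intra-hemisphere pairs).

## Communication models

Three models span the routing-to-diffusion spectrum.

- **SPE.** Edge lengths are inverse weights; $\Pi_{ij}$ is the shortest
  path length and $\mathrm{SPE} = 1/\Pi$. Unreachable pairs get 0.
- **NSI.** The search information $SI_{ij} = -\log_2 P(\pi_{i \to j})$ is
  the surprisal of a random walker following the shortest path, with step
  probabilities $W_{uv}/s_u$. We report the symmetric negative form
  $\mathrm{NSI}_{ij} = -(SI_{ij} + SI_{ji})/2$: the defining sources print
  an ambiguous (as-written antisymmetric) formula while requiring a
  symmetric measure, and the symmetric average is the reading consistent
  with both; rank-based downstream statistics are insensitive to the 1/2.
  When several shortest paths tie exactly, the lexicographically smallest
  node sequence is followed — a documented deterministic tie-break that
  only matters on contrived toys.
- **CMY.** Communicability is the matrix exponential of the
  strength-normalized weights, $\exp(S^{-1/2} W S^{-1/2})$. The square-root
  normalization is the standard form; a literal $W_{ij}/(s_i s_j)$ variant
  is available (`strength_norm = "literal"`). The exponential is computed
  by symmetric eigendecomposition (exact for symmetric matrices; verified
  in tests against a truncated power series and `Matrix::expm`). Isolated
  nodes are masked `NA`; the empty graph returns the identity.

**Morphospace.** To compare routing and diffusion on a common scale, mean
SPE and mean CMY are standardized against two reference ensembles matched
in size and edge count — one-dimensional ring lattices (neighbor rings
filled in increasing radius until the edge count is met) and uniform random
graphs — each realization carrying a random permutation of the empirical
weight multiset (10 realizations by default; the references' weighting is a
design choice, made so that only topology differs):
$\mathrm{SPE}_{scaled} = (E - \langle E_{latt}\rangle) / (\langle E_{rand}\rangle - \langle E_{latt}\rangle)$,
and analogously for CMY. A lattice-like network scores near 0, a
random-like one near 1; the scaling is invariant to uniform weight
rescaling. Note the standardization fixes the *expectation* of the random
reference at 1; an individual random draw scatters around it with sd ≈ 0.06
at $N = 100$, which is why calibration checks target the mean.

## Portraits, representatives and outliers

A network portrait counts, for each binned shortest-path distance $l$, how
many nodes have $k$ nodes at that distance. Continuous distances are
discretized into 25 quantile bins; when networks are compared, bin edges
are pooled from the whole comparison set so portraits remain commensurable
(a per-network binning would make divergences incomparable). Unreachable
pairs land in a dedicated overflow bin, keeping disconnected graphs
comparable. Portrait divergence is the base-2 Jensen–Shannon divergence of
the joint $(l, k)$ distributions, with row $l$ weighted by the fraction of
node pairs at that distance (mass $\propto k\,B_{l,k}$) — bounded in
$[0, 1]$, symmetric, zero for identical portraits.

Among repeated reconstructions of one animal, the representative is the
instance with minimal mean divergence to the others, after removing
instances whose mean divergence exceeds the median by more than 3 scaled
MADs (constant 1.4826). Cohort-level screening adds a second rule: animals
whose within-taxonomic-order divergence strength has z-score above 3 are
flagged; single-member orders are exempt (z undefined) and noted.

## Null models

Three nulls certify that observed couplings reflect empirical topology:

1. **Mantel permutation** — a random node permutation applied jointly to
   rows and columns of `CC`; value multiset, symmetry and diagonal exactly
   preserved (1,000 draws by default).
2. **Module-allegiance permutation** — node labels shuffled, module-size
   multiset exactly preserved.
3. **Distance-binned rewiring** — edges split into 10 equal-count
   Euclidean-distance bins (count a design default; the construction only
   requires equal counts), then degree-preserving double-edge swaps within
   bins (10 attempted swaps per edge). Weights travel with their edge, so
   weight–length coupling is broken only at bin resolution; degree
   sequence and per-bin counts are exact invariants.

## Cross-animal statistics

Per-animal couplings are Spearman correlations over upper-triangle node
pairs: `CC` against weight, cost (weight × tract length; non-edges
contribute weight 0 and cost 0) and Euclidean distance, and distance /
`CC` against each communication matrix (masks for undefined pairs
propagate). Couplings are Fisher-z-transformed ($\mathrm{atanh}$, clipped
at $|\rho| \le 1 - 10^{-12}$ so degenerate toys stay finite) before being
correlated with volume; rank correlations are invariant to this monotone
transform, which matters only for parametric follow-ups. P-values are
reported raw, mirroring the single-panel design; a Benjamini–Hochberg
adjustment can be applied downstream if many panels are compared.

Allometric volume laws are fitted as `log10 y ~ log10 x` by OLS inside a
bootstrap: draws of `floor(0.9 n)` animals *with replacement*, 10,000
iterations, reporting mean ± sd of slope and intercept. The with-replacement
choice is deliberate: the spread of 90% *subsamples without* replacement
underestimates the slope's standard error by roughly $\sqrt{(n-d)/d} \approx 3$
(delete-d jackknife scaling), so its "±sd" would not be a usable
uncertainty; the bootstrap sd is a consistent one, and the noiseless-law
recovery (sd exactly 0) is unaffected.

Partial rank correlations residualize rank-transformed variables on a
covariate design (numeric covariates rank-transformed, categorical ones
one-hot via treatment contrasts) and correlate residuals, with a
$t$-approximate p-value on $n - 2 - k$ degrees of freedom. Collinear
covariates are an error; a variable numerically fully explained by the
covariates yields $\rho = 0$ rather than a correlation of float noise.

## The synthetic cohort generator

The generator exists so that every stage is testable without data
downloads. Its defaults are fixed study conditions, chosen to emulate the
structure of the empirical mammalian cohort the method targets:

| parameter | default | meaning |
|---|---|---|
| `n_animals` | 200 | cohort size |
| `n_nodes` | 200 | nodes (100 per hemisphere); tests use 100 for speed |
| `volume_range` | [0.0842, 1597.3] cm³ | brain-volume span, sampled log-uniformly |
| `gm_slope`, `gm_intercept` | 0.98, 0.013 | log10 GM on log10 BV (mm³) |
| `wm_slope`, `wm_intercept` | 1.16, −1.45 | log10 WM on log10 GM (mm³) |
| `noise_sd` | 0.05 | lognormal noise on the volume laws (log10 space) |
| `n_modules` | 4 | planted spatial modules per hemisphere |
| `spatial_decay_base` | 0.4 | distance-penalty scale λ at mid-volume (normalized units) |
| `spatial_decay_volume_coupling` | 0.2 | λ(V) = base · (V/V_mid)^(−coupling) |
| `within_module_boost` | 3 | same-module edge-probability multiplier (1 + boost) |
| `weight_noise_sd` | 1.0 | lognormal edge-weight jitter (natural-log space) |
| `target_density` | 0.2 | fraction of node pairs connected |
| `fiber_length_factor` | 1.2 | tract length = 1.2 × Euclidean distance on edges |

The volume laws are applied in mm³: the printed GM/BV intercept is only
dimensionally sensible there (in cm³ it would imply GM > BV at 1 cm³).
Nodes sit in two mirrored hemispheric clouds scaled by $V^{1/3}$; node
scatter around module centers is $0.55\,\lambda(V)$, so larger brains have
geometrically tighter modules — spatial compactness varying with volume is
the planted effect the cross-animal analysis is meant to detect. Edges are
sampled without replacement with probability
$\propto e^{-d/\lambda(V)}(1 + \text{boost}\cdot[\text{same module}])$,
hitting the target density exactly; weights are $e^{-d/\lambda}$ times
lognormal noise. The weight jitter sd of 1.0 reproduces the
orders-of-magnitude spread of streamline-count weights; with much less
noise, distance couplings saturate near −1 for every animal and no volume
trend can express itself. Disconnected draws are regenerated (bounded
retries). All per-animal seeds derive from (cohort seed, animal index), so
cohorts are reproducible and animals regenerable independently.

**What the generator does and does not emulate.** It reproduces the
tabular statistical structure the cross-animal analysis consumes:
volume-law tables, spatial modularity, distance-dependent connectivity and
weights, hemispheric mirroring, and volume-coupled spatial compactness. It
does **not** emulate tractography biases, true streamline-count
distributions, inter-species parcellation variability (replicates are
weight-jittered, not re-parcellated), gyrification, or the empirical
balance of inter- vs. intrahemispheric connectivity. Consequently, passing
end-to-end tests shows the pipeline *recovers planted effects of realistic
shape and size*; it does not show that real mammalian data exhibit those
effects. Two cohort-level observables come out with signs opposite to the
empirical phenomenon (the long-distance bridge fraction falls rather than
rises with volume, and the synthetic morphospace favors routing rather
than diffusion in larger brains); these reflect generator simplifications,
not pipeline defects, and neither is used as a planted-trend check.

## Numerical choices and problem sizes

- Maximum-weight spanning backbone: Kruskal on descending weight, ties by
  ascending (i, j) — deterministic; density thresholding keeps the
  backbone and adds edges by descending weight to ceil(d·N(N−1)/2).
- Shortest-path tie detection uses a relative tolerance of 1e−12; portrait
  quantile edges collapse duplicates under heavy ties.
- Default test problem sizes: 100-node networks, sweeps of 25–100
  resolutions per step, 10-realization reference ensembles, cohorts of
  4–40 animals; the acceptance script uses 200 animals for the volume
  table (10,000 bootstrap iterations) and 40 animals × 100 nodes × (100 +
  100) resolutions for the end-to-end run. These sizes were chosen so that
  the full validation remains a desk-scale computation while every
  statistical property under test is comfortably detectable.
- Per-animal artifacts are recomputed rather than cached on disk: at these
  sizes a content-addressed cache would add state and invalidation risk
  for negligible savings, and determinism under fixed seeds makes re-runs
  exact.

## Known limitations

Undirected networks only (no directed communication variants); no
multilayer community detection (node correspondence across animals is not
assumed anywhere); no statistical backboning beyond the MST-plus-density
scheme; the optional deposited-dataset loader adapts to the archive layout
at hand and is not exercised by tests. Interpretation of synthetic results
is bounded by the generator's scope described above.
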