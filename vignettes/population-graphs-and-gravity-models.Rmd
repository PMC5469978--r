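---
title: "Population graphs and gravity models for landscape genetic connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population graphs and gravity models for landscape genetic connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Species that persist as small, discrete populations in fragmented
landscapes — ground squirrels in montane meadows are the motivating
system — depend on *functional connectivity*: the degree to which the
landscape permits gene flow among occupied patches. `popgravity`
implements two complementary network views of connectivity from
codominant microsatellite genotypes, site coordinates, and gridded
landscape layers:

1. **Population graphs.** Sampling locations are nodes; an edge is drawn
   only where two populations remain genetically associated *after
   conditioning on all other populations*. The pruned graph supports
   community detection, core–periphery analysis, centrality metrics, and
   a local-extinction (node-removal) simulation.
2. **Gravity models.** Pairwise gene flow (1 − D~PS~) is modelled as a
   function of geographic distance, at-site covariates (production or
   attraction of migrants), and between-site covariates (landscape
   resistance), in a singly constrained mixed-effects form with AICc
   multimodel inference.

A seeded synthetic-data generator produces genotypes, landscapes, and
flows with known ground truth, so every stage is testable without field
data.

# Genetic distances

For populations $i, j$ and loci $\ell = 1..L$ with allele-frequency
vectors $f_{i\ell}$:

* **Shared-allele distance**
  $D_{PS}(i,j) = 1 - \frac{1}{L'} \sum_{\ell} \sum_a \min(f_{i\ell a}, f_{j\ell a})$,
  where $L'$ counts loci scored in both populations. This is the
  *population-frequency* dialect (the population-level statistic of
  Microsatellite Analyzer), not a mean over individual pairs; the two
  dialects differ by a within-population heterozygosity term.
* **Weir–Cockerham $\theta$** (pairwise, multilocus): per-allele variance
  components $a$ (among populations), $b$ (among individuals), $c$
  (within individuals) are summed over alleles and loci and
  $\theta = \sum a / \sum (a+b+c)$. Negative estimates are reported
  as-is — truncation would bias averages of weakly differentiated pairs.
  A pair monomorphic at every locus has no defined $\theta$ and is
  returned as `NA` with a warning.
* **Geographic distance** is planar Euclidean in metres; lon/lat input is
  rejected rather than silently treated as planar
  (`equirectangular()` is provided for small study extents).

Mantel tests permute rows/columns of one matrix jointly with
$p = (1 + \#\{r_{perm} \ge r_{obs}\})/(n_{perm}+1)$, one-tailed for a
positive association by default — the isolation-by-distance convention.
The two-tailed variant is available via `alternative = "two.sided"`;
whether published Mantel probabilities in this literature are one- or
two-tailed is usually unstated, so the default is documented rather than
assumed universal.

# The population graph

The construction runs:

1. **Centroids.** Each population becomes a stacked allele-frequency
   vector over a common allele namespace (dimension = total allele count
   over loci). This approximates the published individual-level
   multivariate coding at population level; the approximation is isolated
   in `population_centroids()` so an alternative coding can be swapped in.
2. **Distances → covariance.** Squared Euclidean distances between
   centroids are Gower double-centred,
   $C = -\tfrac12 J D^{(2)} J$, $J = I - \frac1n \mathbf{1}\mathbf{1}'$,
   giving the centred inner-product (genetic covariance) matrix.
3. **Partial correlations.** $C$ is rank-deficient by construction (the
   centring removes one dimension), so the precision matrix is computed
   on the retained eigenspace: components with eigenvalue
   $> 10^{-10} \lambda_{max}$, plus a relative ridge ($10^{-8}
   \lambda_{max}$) for numerical safety. Then
   $\rho_{ij} = -\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}$. On
   well-conditioned full-rank input (e.g. an ordinary sample covariance)
   the cutoff keeps everything, so the function doubles as a standard
   Gaussian-graphical-model partial-correlation routine.
4. **Pruning.** Edge $(i,j)$ is kept iff the edge-exclusion deviance
   $EED_{ij} = -N \ln(1-\rho_{ij}^2)$ exceeds the $\chi^2_1$ critical
   value at $\alpha$ (default 0.05, configurable; the source literature
   does not print its level). $N$ is the total number of genotyped
   individuals, following the original population-graph formulation; it
   is exposed as `n_total` because the effective sample size of a
   centroid-level covariance is debatable — see *Limitations*.
5. **cGD.** Conditional genetic distance is the shortest-path length over
   retained edges, using the same pairwise genetic distances as edge
   weights that built $C$. Disconnected pairs are `Inf` with component
   labels attached — disconnection is a reported state, not an error.

Edge `flow` weights ($1 - D_{PS}$) are carried separately for the
topology metrics; the published "association indices" are not defined
precisely, so this choice is explicit and logged.

# Topology

Community detection and the core–periphery fit run on the **binary**
pruned topology. Degree and betweenness are binary by default;
betweenness uses fractional credit across tied shortest paths (published
per-node values are fractional, e.g. 15.08, which implies this
convention). Strength and optional weighted betweenness use the flow
weights.

*Modularity* is $Q = \sum_c (e_{cc} - a_c^2)$. Two detection methods are
provided: recursive leading-eigenvector splits of the modularity matrix,
and Walktrap (random-walk agglomeration, walk length 4 by default). Both
report $Q$ per candidate community count (2..`k_max`) where the merge
structure supports the cut, and the best partition by $Q$ with ties
broken toward fewer clusters. The per-`k` table only contains the counts
the underlying merge tree can express — the leading-eigenvector recursion
stops splitting when no split raises $Q$, so some `k` may be absent.

*Core–periphery.* The idealised model ties core nodes to everyone and
periphery nodes only to the core (core–periphery ties count as 1 — the
idealised pattern has the core connected "to the periphery"). For each
core size $k$ the core set maximising the Pearson correlation between the
off-diagonal adjacency and the ideal pattern is found exhaustively for
$n \le 20$ (the correlation reduces to a count of periphery-internal
edges, so all $\binom{n}{k}$ sets are scored cheaply) and by greedy
swapping with restarts above. *Concentration* is the maximal correlation;
it is undefined (error) for complete or empty graphs, where the ideal
pattern is constant. Continuous *coreness* is the leading eigenvector of
the adjacency matrix — the least-squares rank-one $c_i c_j$ fit of the
Borgatti–Everett continuous model — rescaled to $[0,1]$. The published
analyses do not define their continuous estimator, so exact
comparability of coreness values is unknown; rankings are the robust
output.

# Node-removal simulation

For each removal intensity $k = 1..n-2$: if $\binom{n}{k} \le$
`max_reps` (default 100) *all* removal subsets are enumerated, which is
deterministic and seed-independent; otherwise `max_reps` *distinct*
subsets are sampled uniformly (the source describes "up to 100" graphs
per scenario; enumeration removes Monte-Carlo noise exactly where
possible, and whether the original resampled with replacement is
unstated — distinct subsets are used here). Two metrics per scenario: the
proportion of induced subgraphs that remain fully connected, and the
largest-component size as a fraction of surviving nodes, with a normal
95% CI (mean ± 1.96 SE; degenerate when all replicates agree). A single
surviving node counts as connected of size 1.

# Landscape covariates

Rasters are plain matrices with grid geometry (row 1 = north, cell
centres, projected metres); I/O is headered ASCII grid. Implemented
surfaces:

* `percent_cover(mask, window)` — percent of non-missing window cells
  equal to 1, truncated windows at edges (summed-area tables, exact).
* `surface_relief_ratio(dem, window)` — $(\text{mean}-\min)/(\max-\min)$
  per neighborhood, 0 on flat neighborhoods; 3×3 and 27×27 are the usual
  fine/broad scales.
* `heat_load_index(dem, latitude)` — McCune & Keon (2002): slope/aspect
  by Horn's 8-neighbour method, aspect folded about the southwest axis,
  $\exp(-1.467 + 1.582\cos L\cos S - 1.500\cos A\sin S\sin L
  - 0.262\sin L\sin S + 0.607\sin A\sin S)$. Positive everywhere; flat
  cells are aspect-neutral because the aspect terms carry $\sin S = 0$.

At-site covariates average each layer over a disc around the site point;
the default radius 370 m gives ≈0.43 km², matching a typical occupied
site footprint where true site polygons are unavailable. Between-site
covariates sample straight-line transects with perpendicular offsets
filling a 30 m corridor by default; wider buffers (150/300 m) are
available but corridor means at these widths are strongly correlated on
smooth layers, which is why the narrow straight-line values are the
default. Climate summaries (frost-free period, growing-season
precipitation) and non-raster inputs enter as pre-computed per-site
scalars in the site table; deriving them from climate-spline surfaces is
out of scope.

# Gravity models

The design table has one row per *ordered* pair: response
$\ln T_{ij} = \ln(1 - D_{PS}(i,j))$, $\ln w_{ij}$ the log Euclidean
distance, z-standardised covariates (several candidates, e.g. heat-load
residuals, can be ≤ 0, so covariates are standardised rather than
logged). Rows with $D_{PS} = 1$ (zero flow) are dropped with a warning.
The model is

$$\ln T_{ij} = \beta_0 + \beta_w \ln w_{ij} + X\beta + u_i +
\varepsilon_{ij}, \quad u_i \sim N(0, \sigma_u^2),$$

fitted by maximum likelihood (`lme4`). The random intercept on the
*origin* node realises the single constraint; at-site covariates attach
to the *destination* (production/attraction read at the receiving end).
Neither the attachment side nor whether pairs enter once or twice is
stated in the source literature; both orientations are included here,
and the alternatives (origin attachment, random intercepts on both
endpoints) sit behind arguments. AICc uses
$k = $ fixed effects (incl. intercept) $+\,2$ variance parameters; the
counting rule is also unstated in the sources and is therefore fixed and
documented here. Candidate sets exclude any model containing a covariate
pair with $|r| \ge 0.7$. Ranking reports ΔAICc, Akaike weights
$w_m = e^{-\Delta_m/2}/\sum e^{-\Delta/2}$, and conditional
$R^2 = (\sigma_f^2 + \sigma_u^2)/(\sigma_f^2 + \sigma_u^2 +
\sigma_\varepsilon^2)$ (Nakagawa–Schielzeth), with $\sigma_f^2$ the
variance of the fixed-effect predictor. Cumulative variable weights sum
$w_m$ over models containing each variable.

# The synthetic generator

`simulate_genotypes()` uses the Balding–Nichols construction: ancestral
frequencies per locus from a symmetric Dirichlet, population frequencies
from $\mathrm{Dir}(p(1-F)/F)$ — which has exactly the $F p (1-p)$
allele-frequency variance that makes $F$ the expected differentiation —
and Hardy–Weinberg genotypes within populations. A two-level hierarchy
(clusters at $F_{between}$, populations at $F_{within}$) plants genetic
clusters. Defaults mirror the study conditions: 13 populations × 24
individuals × 8 loci × 10 alleles, divergence around $\theta = 0.2$ with
pairwise values spanning roughly 0.03–0.48 under the default hierarchy.
This was chosen over forward-time simulation because it parameterises
$F_{ST}$ directly and runs in seconds; mutation models and coalescent
history are out of scope.

`simulate_landscape()` builds the DEM from smoothed Gaussian random
fields (broad + fine scale) and class masks by thresholding independent
fields; sites are placed by rejection sampling with minimum spacing.
`simulate_flows()` draws directional flows from the gravity equation
with known $\beta$, $\sigma_u$, $\sigma_\varepsilon$ (defaults
$\beta_w = -0.8$, $\sigma_u = 0.3$, $\sigma_\varepsilon = 0.2$), clipping
into $(0,1]$ with the clip count reported. All randomness derives from
one root seed through named child streams, so stages regenerate
independently.

**What the generator does *not* emulate.** Genotypes are not spatially
structured: planted clusters are genetic, not geographic, so Mantel
correlations with distance on synthetic data are near zero by
construction, and synthetic gravity fits on genotype-derived flows
correctly prefer the distance-only null. Passing tests therefore
demonstrate statistical machinery and parameter recovery, not that real
squirrel landscapes behave this way. Real-data features absent from the
generator: isolation by distance, null alleles and genotyping error,
uneven sample sizes, and spatially autocorrelated covariate–flow
coupling (the latter is exercised separately by planting effects through
`simulate_flows()` on extracted covariates).

# Numerical choices and edge cases

* Eigen cutoff $10^{-10}\lambda_{max}$ and relative ridge
  $10^{-8}\lambda_{max}$ in the precision computation; inversion failure
  reports the condition number.
* $|\rho| = 1$ gives infinite deviance: the edge is retained with a
  warning rather than propagating `Inf` silently.
* Argmax-$Q$ ties break toward fewer clusters; best-core ties resolve to
  the smaller concentration index found first (deterministic given the
  enumeration order).
* Missing genotype entries: an entry is missing iff either allele is
  missing; missing entries are excluded locus-wise from frequencies and
  $\theta$.
* Temporal pooling uses a permutation G-test (999 label permutations,
  seeded) instead of an asymptotic χ² because microsatellite count
  tables are sparse; per-locus p-values combine by Fisher's method and
  pooling is recommended at combined $p \ge 0.05$. Merging decisions
  remain explicit configuration — where published node counts imply
  sites were pooled, the rule is not recoverable from the sources.

# Limitations

* **Graph density and the resolution limit.** The edge-exclusion test
  with $N$ = total individuals is liberal: its critical partial
  correlation shrinks as $1/\sqrt{N}$, while between-cluster partial
  correlations of clustered populations contain a *systematic* component
  (the conditional-dependence structure of a clumped centroid
  configuration) of roughly 0.1 that does not shrink with sample size.
  Pruned graphs of strongly clustered data therefore retain an
  appreciable fraction of between-cluster edges, and small planted
  clusters (say 4 nodes) can sit below the modularity resolution limit —
  the best-$Q$ partition may genuinely merge them even when the planted
  partition is visible by eye. The test suite consequently checks that
  detected communities agree with planted structure far above chance
  (mean adjusted Rand index), not that label recovery is exact.
* The centroid-level coding approximates the individual-level
  multivariate coding of the published population-graph procedure; the
  exact matrix conventions of the original software may differ, which is
  why the construction is exposed as composable steps.
* Continuous coreness values are estimator-dependent; only the discrete
  core set and concentration have a closed definition here.
* Conditional $R^2$ compares models on the same response; it is not an
  absolute goodness measure for ln-flow data.

# Problem sizes

The test suite and the acceptance script run at deliberately modest
sizes chosen to exercise every code path while completing quickly on one
CPU: genotype simulations up to 20 populations × 50 individuals × 20
loci for the $\theta$-recovery check, 50 replicate mixed-model fits over
15 nodes for the distance-decay recovery, 100-seed planted-partition
sweeps for community detection, exhaustive enumeration for all graph
oracles at $n \le 8$, and a 13-population study-scale synthetic dataset
for the end-to-end workflow.
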