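# popgravity

Network-based analysis of functional connectivity among patchily
distributed populations — built for landscape-genetics studies where
species persist as small, discrete colonies (the motivating system is a
pair of endemic ground squirrels) and the questions are *which sites hold
the network together* and *which landscape features drive gene flow*.

Two complementary analyses share one toolkit:

**Population graphs.** From multilocus microsatellite genotypes the
package computes population-pairwise genetic distances — the
shared-allele distance
*D*<sub>PS</sub>(i,j) = 1 − (1/L′) Σ<sub>ℓ</sub> Σ<sub>a</sub> min(f<sub>iℓa</sub>, f<sub>jℓa</sub>)
and pairwise multilocus Weir–Cockerham θ — then builds a graph whose
edges survive a conditional-independence test: population centroids →
Gower-centred genetic covariance → partial correlations ρ<sub>ij</sub> →
keep edge (i,j) iff the edge-exclusion deviance −N ln(1 − ρ²) exceeds
the χ²₁ critical value at α. On the pruned graph it computes conditional
genetic distance (shortest paths), community structure (leading
eigenvector and Walktrap, with modularity Q), centrality (degree,
strength, betweenness), a Borgatti–Everett core–periphery fit with a
concentration score, and a local-extinction simulation (random node
removal; proportion of connected graphs and largest-component size with
95% CIs).

**Gravity models.** Gene flow T<sub>ij</sub> = 1 − D<sub>PS</sub> over
ordered site pairs is modelled as
ln T<sub>ij</sub> = β₀ + β<sub>w</sub> ln w<sub>ij</sub> + Xβ + u<sub>i</sub> + ε<sub>ij</sub>,
with Euclidean distance w, z-standardised at-site and between-site
covariates, and a random intercept on the origin node (the single
constraint), fitted by maximum likelihood. Candidate models are screened
for collinearity (|r| ≥ 0.7), ranked by AICc, and summarised with Akaike
weights, conditional R², and cumulative per-variable weights. Covariates
come from matrix-backed rasters: moving-window percent cover, surface
relief ratio, McCune–Keon heat load index, disc-averaged at-site values,
and straight-line edge transects.

A seeded synthetic-data generator (Balding–Nichols genotypes with
optional planted clusters, Gaussian-random-field landscapes, gravity
flows with known coefficients) makes the whole pipeline testable without
field data. See `vignettes/population-graphs-and-gravity-models.Rmd` for
the methods account.

## Worked example

```r
library(popgravity)

cfg <- sim_config(n_pops = 10, n_ind_per_pop = 24, n_loci = 8,
                  cluster_map = rep(1:2, each = 5), seed = 42)
tab <- simulate_genotypes(cfg)
tab
#> genotype_table: 240 individuals, 10 populations, 8 loci

dps <- dps_matrix(tab)
fst <- fst_matrix(tab)
sprintf("mean D_PS = %.2f, mean theta = %.2f, cor = %.2f",
        mean(dps[lower.tri(dps)]), mean(fst[lower.tri(fst)]),
        matrix_correlation(dps, fst))
#> "mean D_PS = 0.50, mean theta = 0.20, cor = 0.99"

pg <- build_population_graph(tab, alpha = 0.05)
pg
#> population_graph: 10 nodes, 28/45 edges (62% of saturated), alpha = 0.05

tp <- topology_report(pg)
sprintf("communities: k = %d (Q = %.2f); core of %d nodes, concentration %.2f",
        tp$eigen$best$k, tp$eigen$best$Q,
        tp$core$best_size, tp$core$concentration)
#> "communities: k = 2 (Q = 0.05); core of 5 nodes, concentration 0.58"

prof <- removal_profile(pg, max_reps = 100, seed = 1)
prof[3, c("prop_connected", "mean_lcp")]
#>   prop_connected mean_lcp
#> 3           0.99        1
```

Reading the output: the two planted genetic clusters give a mean
pairwise θ of 0.20; conditional-independence pruning keeps 28 of 45
possible edges; the best modularity partition finds the two clusters
(weakly — Q is low because the pruned graph stays dense); the best
core–periphery model puts 5 nodes in the core with concentration 0.58;
and with 3 of 10 sites removed at random, 99% of simulated graphs remain
fully connected — a robust network.

## The analysis workflow

Numbered drivers under `analysis/` run the full study pipeline on the
bundled synthetic study-scale dataset and write tables under `results/`:

| script | writes |
|---|---|
| `01_simulate.R` | genotypes, sites, ASCII-grid rasters, truth JSON |
| `02_distances.R` | D_PS / θ / geographic matrices, Mantel tests |
| `03_population_graph.R` | pruned graph (GraphML + CSV), cGD, topology report |
| `04_robustness.R` | node-removal profile with CIs |
| `05_gravity.R` | covariates, AICc model ranking, variable weights |

Run them in order with `Rscript analysis/01_simulate.R` etc. Because the
synthetic genotypes are independent of the synthetic landscape, the
distance-only null correctly tops the gravity ranking on genotype-derived
flows; `05_gravity.R` then re-runs the selection on flows simulated with
planted covariate effects to demonstrate sign and structure recovery.

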