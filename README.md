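# scsclust — soft cross-species clustering of gene-expression profiles

`scsclust` clusters gene-expression profiles from **two species jointly**.
Orthologous gene pairs share a joint cluster label drawn from a
multinomial-logit prior that *encourages* — but does not *force* —
orthologs into correspondent clusters; given the label, each species'
profile is an independent diagonal Gaussian. The strength of the coupling,
γ, is estimated from the data, so conserved co-expression modules and
species-specific rewiring both remain visible. Genes without orthologs
participate through their own species' mixture, and a broad background
component (plus a posterior threshold) flags "scattered" genes that belong
to no coherent cluster.

The model, for pair *(i, i′)* with joint label *(k, k′)*:

- prior: π<sub>k,k′</sub> ∝ exp{α<sub>k</sub> + β<sub>k′</sub> + γ·I(k′ = σ(k))}, γ ≥ 0
- likelihood: N(g<sub>i</sub>; μ<sub>k</sub><sup>(1)</sup>, Σ<sub>k</sub><sup>(1)</sup>) · N(g<sub>i′</sub>; μ<sub>k′</sub><sup>(2)</sup>, Σ<sub>k′</sub><sup>(2)</sup>)

fitted by an EM-style iterative maximization with multiple restarts, then
cluster indices of the two species are aligned so that the clusters sharing
the largest intersection of orthologous genes get the same label.

Intended users: computational biologists comparing bulk or single-cell
expression across two species (e.g., mouse vs human stem-cell
differentiation time courses) who want model-based, threshold-free
conserved/diverged module calls.

The package also ships the full evaluation stack used to validate the
method: a synthetic two-species benchmark generator with known truth, an
orthology-map error-injection protocol, the global-scatter /
center-scatter / misassignment / BHI metrics, per-species K-means and
random-centroid baselines, a benchmark harness, and a command-line
interface.

## Worked example

Simulate a two-species dataset with 5 conserved clusters and 40 scattered
ortholog pairs, fit the model with the true K, and score the result:

```r
library(scsclust)

spec <- synthetic_spec(n_clusters = 5, d1 = 12, d2 = 12,
                       genes_per_cluster = 25, n_scatter = 40,
                       mean_range = c(0, 10), sd1 = 1, sd2 = 1)
sim  <- generate_paired_dataset(spec, seed = 42)
data <- build_paired_dataset(sim$expr1, sim$expr2, sim$map)

fit  <- fit_scsc(data, K = 5, scsc_config(seed = 42))
fit
#> scsc_fit: K = 5 | final loglik = -6774.765 | gamma = 27.4642
#>   | iterations = 5 | converged = TRUE | restart = 9

hard <- harden_assignment(fit$soft, scatter_threshold = 0.5)
misassignment_proportion(sim$truth, hard)
#> [1] 0
average_center_scatter(
  list(centers1 = sim$truth$centers1, centers2 = sim$truth$centers2),
  list(centers1 = fit$params$mu1,     centers2 = fit$params$mu2))
#> [1] 0.7111709
table(scatter = hard$scatter)
#> scatter
#> FALSE  TRUE
#>   250    80
```

Reading the output: γ ≈ 27 means the data support essentially hard
co-clustering of orthologs (the generator's clusters are perfectly
conserved); misassignment 0 means every gene of both species, including
all 80 scattered genes, was recovered exactly; the center scatter of about
0.71 is the statistical floor for estimating 12-coordinate cluster means
from 25 members with SD-1 noise (≈ 1·√(12/25) = 0.69), i.e., centers are
recovered up to sampling noise.

Rewire 30% of the ortholog links into wrong matches and refit — the
coupling degrades gracefully:

```r
map_err  <- perturb_orthology(sim$map, 0.3, seed = 42)
data_err <- build_paired_dataset(sim$expr1, sim$expr2, map_err)
fit_err  <- fit_scsc(data_err, K = 5, scsc_config(seed = 42))
hard_err <- harden_assignment(fit_err$soft, 0.5)
c(gamma = fit_err$params$gamma,
  misassignment = misassignment_proportion(sim$truth, hard_err))
#>         gamma misassignment
#>      2.806527      0.000000
```

γ drops from ~27 to ~2.8 — the estimated conservation reflects the
corrupted map — yet with the coupling relaxed every gene is still placed
in its true cluster: the rewired pairs are rescued by their own species'
expression signal.

Benchmarking against per-species K-means on the same design:

```r
bench <- run_benchmark(methods = c("scsc", "kmeans"), n_reps = 5,
                       error_fractions = 0, base_seed = 1,
                       specs = list(demo = spec))
subset(bench$summary, select = c(method, misassignment.mean))
#>   method misassignment.mean
#> 1 kmeans          0.2575758
#> 2   scsc          0.0000000
```

K-means cannot flag scattered genes and pays for every one of them, and it
cannot borrow strength across species; the joint model recovers the
clustering exactly on this design.

## Command-line interface

A thin launcher is installed with the package:

```sh
SCSC=$(Rscript -e 'cat(system.file("cli", "scsc.R", package = "scsclust"))')
Rscript $SCSC simulate --dataset 1 --seed 7 --out-dir sim/
Rscript $SCSC perturb  --map sim/map.tsv --fraction 0.2 --seed 7 --out sim/map_err.tsv
Rscript $SCSC fit      --expr1 sim/expr1.tsv --expr2 sim/expr2.tsv \
                       --map sim/map.tsv --k 10 --seed 7 --out-dir fit/
Rscript $SCSC evaluate --truth sim/truth.tsv --assignment fit/assignment.tsv \
                       --out metrics.csv
Rscript $SCSC benchmark --datasets 1 --methods scsc,kmeans --reps 5 \
                       --fractions 0,0.1,0.2,0.3 --seed 1 --out bench.csv
Rscript $SCSC select-k --expr1 sim/expr1.tsv --expr2 sim/expr2.tsv \
                       --map sim/map.tsv --candidates 8,10,12 --out bic.csv
```

File dialects: expression TSV (header of sample ids, first column gene id),
two-column ortholog-map TSV (`#`-prefixed header optional, one-to-one
required), assignment TSV (`gene_id`, `species`, `cluster` or `SCATTER`,
`max_posterior`), model JSON (all parameters, likelihood trace, seed and
config echo — reloadable with `read_model_json()`).

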