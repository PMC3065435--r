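# mirmod

Discovery of many-to-many **miRNA–mRNA regulatory modules** from a binary
target-prediction map and matched microarray expression profiles.

MicroRNAs repress their targets post-transcriptionally, and the relationship
is many-to-many: one miRNA targets hundreds of mRNAs, one mRNA is targeted
by many miRNAs. Screens that test miRNA–mRNA *pairs* one at a time ignore
this, and leave the experimentalist with tens of thousands of candidate
interactions. `mirmod` reduces them to a handful of modules — a miRNA
cluster paired with the mRNA cluster it detectably co-regulates — in two
steps:

1. **Cluster each side of the map matrix** `M` (Y mRNAs × X miRNAs,
   `M[j,i] = 1` iff miRNA *i* is predicted to target mRNA *j*), with PAM on
   either Euclidean distances between binary profiles (*unguided*) or on
   `1 − proximity` from a multivariate random forest whose splits are map
   columns scored by the drop in expression-space homogeneity
   `f = S(Q) − S(Q₁) − S(Q₂)`, `S(Q) = Σ_{l∈Q} d(x_l, x̄)²` (*guided*).
   Each cluster's tightness `ES_k = Σ_{o∈k} d(o, o_m)/N_k` (mean distance
   to the componentwise median profile) is referred to a bootstrap null of
   B random same-size clusters; `W₁/B < α` declares it enriched. The
   cluster count K and the clustering route are selected by `Pr_enrich`,
   the fraction of enriched clusters.
2. **Pair the retained clusters.** Every predicted pair is fit with
   `u = α + βv` on matched log2 fold-changes and the slope t-tested
   (one-sided `β < 0` by default — miRNAs are negative regulators).
   `Assoc(m,n)` counts the significant predicted pairs between the
   clusters; a bootstrap over random mRNA clusters gives `W₂`, and a
   module is *potentially regulatory* when `W₂/B < α` and every member
   miRNA targets a majority of the mRNA cluster.

Inputs are plain labelled TSV matrices; every result is a tibble with
`tidy()`/`glance()` methods and `autoplot()` figures. A synthetic-data
generator with planted, recoverable modules (and a pure null twin)
supports benchmarking and calibration. See `vignette("mirmod-methods")`
for the full model description and design choices.

## Worked example

```r
library(mirmod)

truth <- simulate_modules(synthetic_spec(seed = 1))   # 3 planted modules
cfg <- pipeline_config(
  truth$map, truth$mirna_expr, truth$mrna_expr,
  mrna_method = "unguided", mirna_method = "unguided",
  K_mrna = 4:6, K_mirna = 4:5, seed = 1
)
run <- run_pipeline(cfg)
```

```
[align] 300/300 mRNAs and 30/30 miRNAs retained
[mRNA] chose unguided clustering (best Pr_enrich: unguided = 1.000)
[miRNA] chose unguided clustering (best Pr_enrich: unguided = 1.000)
[enrich] 4 mRNA and 4 miRNA clusters retained for step 2
[modules] 16 candidates -> 3 regulatory
```

The log is the method's bookkeeping: all 300 mRNAs and 30 miRNAs survive
alignment; the K sweep keeps 4 clusters per side (the 3 planted groups plus
the diffuse background pool, every one tighter than chance, so
`Pr_enrich = 1`); pairing them yields 4 × 4 = 16 candidate modules, of
which exactly the 3 planted ones pass the association bootstrap and the
majority-targeting filter:

```r
print(run)
#> two-step miRmR module identification run
#> # A tibble: 8 × 2
#>   stage                       n
#>   <chr>                   <int>
#> 1 input_mrna                300
#> 2 input_mirna                30
#> 3 aligned_mrna              300
#> 4 aligned_mirna              30
#> 5 retained_mrna_clusters      4
#> 6 retained_mirna_clusters     4
#> 7 candidate_modules          16
#> 8 regulatory_modules          3

glance(run)
#> # A tibble: 1 × 8
#>   n_candidates n_significant n_regulatory direction alpha_level alpha ...
#> 1           16             3            3 negative         0.05  0.05
```

`tidy(run)` gives one row per candidate module (association count, `W₂`,
bootstrap p, per-miRNA targeting fractions, the regulatory verdict);
`module_edges(run$modules)` flattens the regulatory modules to a
(miRNA, mRNA, β̂, p) edge list for network tools.

## Command line

A thin CLI over the same functions lives at `inst/cli/mirmod`
(`simulate | cluster | enrich | associate | run`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","mirmod",package="mirmod"))')" \
  run --map map.tsv --mirna-expr mirna.tsv --mrna-expr mrna.tsv \
      --k-mrna 40,50,60 --k-mirna 10,15,20 --seed 1 --out results/
```

Stage outputs are TSV/JSON artefacts plus a manifest; identical
configuration and seed give byte-identical files.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch — it generates the default synthetic world under the given seed,
executes the full two-step pipeline, prints the run summary, and writes
the acceptance JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
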