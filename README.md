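# sphingolens

Multi-omic interrogation of the sphingomyelin (SM) / ceramide pathway for
researchers studying lipid dysregulation in Alzheimer's disease and related
neurodegenerative conditions. The package provides three self-contained
analysis arms plus seeded synthetic-data generators with planted effects,
so every method can be exercised and validated end-to-end without access to
controlled cohort data.

## What it computes

**1. Context-specific flux comparison.** A curated constraint-based model
of the SM pathway (35 enzymes, 18 enzymatic reactions, plus flagged
exchange/demand pseudo-reactions) is combined per sample with expression
data through GPR rules (`and` = min, `or` = max). Reaction expression is
discretized by within-sample quantiles into low/moderate/high, and a
context-specific model is extracted by solving the agreement MILP

&nbsp;&nbsp;maximize  #{high reactions with |v| ≥ ε} + #{low reactions with v = 0}
&nbsp;&nbsp;subject to S·v = 0, lb ≤ v ≤ ub

exactly, via branch-and-bound with LP-feasibility pruning over a
bounded-variable simplex written for the package. Flux variability analysis
(FVA) on the context model yields per-sample maximum fluxes, which are
z-scored per reaction and compared between diagnosis groups (AD / MCI /
NCI) with the Mann-Whitney rank-sum test and Benjamini-Hochberg adjustment
across all reaction × group-pair tests.

**2. Metabolite-ratio screen with p-gain ranking.** Lipid shorthand names
(`SM(d34:1)`, `Cer(d18:1/16:0)`) are parsed; the N-acyl chain length is
total − 18 carbons under the d18:1 base convention, with a C20 short/long
cut. Traits are log2 single-species values and log2 ratios — all ordered
pairs in `all` mode (112 species → 12,544 traits) or short/long SM pairs in
`targeted` mode. Medications are selected per trait by BIC backward
elimination, associations are covariate-adjusted regressions, and ratios
are ranked by the p-gain

&nbsp;&nbsp;Pgain = min(p_numerator, p_denominator) / p_ratio,

the factor by which the ratio improves on its best constituent.

**3. Gene-based genetic association.** Variant QC (sample call rate ≥ 0.95
first, then variant call rate ≥ 0.95, exact Hardy-Weinberg p ≥ 1e-5, MAF ≥
0.05; an imputation-era profile with HWE 1e-6 / MAF 0.01 is built in),
positional variant-to-gene projection with a flank, additive single-variant
association, per-gene Bonferroni thresholds 0.05/n_variants, and a
gene-wise empirical p from B = 20,000 phenotype permutations:
p = (1 + #{permuted min-p ≤ observed}) / (B + 1).

## Worked example

```r
library(sphingolens)

m <- bundled_sm_model()
m
#> pathway_model: 16 metabolites, 18 enzymatic + 8 pseudo reactions, 35 genes
fba(m)$objective_value
#> [1] 1000     # exit-route throughput at the substrate supply bound

# targeted ratio screen on a synthetic panel with a planted ratio effect
p <- simulate_panel(n = 400, n_short = 8, n_long = 8, ratio_effect = 1,
                    seed = 42)
res <- run_screen(p, "cognition", mode = "targeted")
head(res[, c("trait", "p", "pgain", "p_adj", "medications")], 3)
#>                 trait        p    pgain    p_adj medications
#> 1 SM(d30:0)/SM(d38:0) 3.68e-81 1.09e+33 2.36e-79        med1
#> 2 SM(d37:0)/SM(d44:0) 4.31e-02 4.13e+00 1.72e-01        <NA>
#> 3 SM(d34:0)/SM(d44:0) 8.93e-02 3.18e+00 2.76e-01        <NA>
```

The planted pair tops the ranking with a p-gain of ~1e33 — its ratio is far
more informative than either constituent because the two species share an
opposing latent factor — and the planted medication confounder (`med1`) was
selected for it by the BIC backward step.

```r
# gene-based permutation test on genotypes with a planted causal variant
sim <- simulate_genotypes(n = 1000, m_variants = 5, maf_range = c(0.3, 0.3),
                          causal = list(index = 3, beta = 0.5), seed = 42)
r <- gene_permutation_p(sim$geno$dosage, sim$phenotype, B = 999, seed = 42)
c(min_p = r$min_p, bonf = r$bonferroni_threshold, perm_p = r$perm_p)
#>    min_p     bonf   perm_p
#> 7.80e-19 1.00e-02 1.00e-03
```

The observed min-p beats every permutation, so the empirical p sits at its
add-one floor 1/(B+1).

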