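---
title: "Methods: flux, ratio, and gene-based arms of sphingolens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: flux, ratio, and gene-based arms of sphingolens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sphingolens` implements three complementary computational strategies for
interrogating the sphingomyelin (SM) / ceramide pathway in the context of
Alzheimer's disease: constraint-based flux comparison on a curated pathway
network, a metabolite-ratio screen ranked by the p-gain statistic, and
gene-based genetic association with permutation-derived significance. This
vignette documents the models, their assumptions, the tunable parameters,
the numerical machinery, and the limits of what the bundled synthetic data
can demonstrate.

## The curated pathway model

The bundled network (`bundled_sm_model()`, serialized in
`inst/extdata/sm_pathway.json`) encodes the SM subsystem as 18 enzymatic
reactions catalyzed by 35 enzymes, single cytosolic compartment, with
flagged exchange/demand pseudo-reactions supplying serine and palmitoyl-CoA
and draining the pathway's exit products (sphinganine-1-phosphate,
ceramide-1-phosphate, sphingomyelin, lactosylceramide as the
glycosphingolipid terminus, and the S1P-lyase products hexadecenal and
phosphoethanolamine). Pseudo-reactions are a separate class so that the
"18 enzymatic reactions" count is well defined.

Gene placement follows the conventional lettered steps: serine
palmitoyltransferase (SPTLC1 obligate, paired with SPTLC2 or SPTLC3),
3-ketosphinganine reductase (KDSR), ceramide synthases CERS1-6 (de novo and
salvage), dihydroceramide desaturase (DEGS1), ceramidases
(ACER1/2, ASAH1/2), ceramide kinase (CERK), sphingomyelin synthases
(SGMS1/2, reversible), sphingomyelinases (SMPD1-3, ENPP7), sphingosine
kinases (SPHK1/2, acting on sphingosine and sphinganine), S1P phosphatases
(SGPP1/2, PLPP2), S1P lyase (SGPL1), and the glycosphingolipid branch
(UGCG, GBA/GBA2, B4GALT5/6, UGT8, GALC). Where the literature admits
several placements for family members, any placement consistent with the
lettered steps preserves the machine-checkable facts the package asserts:
35 distinct gene symbols, 18 enzymatic reactions, and the presence of the
core, well-characterized pathway genes (SPTLC3, CERS2, CERS6, DEGS1,
SMPD3, SGMS1, CERK, SPHK2, SGPP1, SGPL1, PLPP2, ACER2 among them).

GPR (gene-protein-reaction) rules use an infix boolean grammar in which
`and` binds tighter than `or`. Numerically, `and` (complex subunits) maps
to the minimum of the operand expression values and `or` (isozymes) to the
maximum; a gene missing from the expression table is dropped from its
operator rather than poisoning it, and a rule with no measured genes leaves
the reaction unclassified. Default flux bounds are `[0, 1000]` for
irreversible and `[-1000, 1000]` for reversible reactions — the
conventional constraint-based defaults, in arbitrary flux units.

## Flux arm

For each sample the pipeline (1) maps expression onto reactions through the
GPR rules, (2) discretizes reaction expression into low/moderate/high by
the sample's own quantiles (`q_low = 0.25`, `q_high = 0.75`, the usual
choice for tri-level expression integration), (3) extracts a
context-specific model by maximizing agreement with that evidence, and
(4) runs flux variability analysis (FVA) on the context model.

The context extraction solves the classic mixed-integer agreement problem:
maximize the number of high-expression reactions carrying flux of magnitude
at least `epsilon` (default 1, i.e. 0.1% of the default bound) plus the
number of low-expression reactions carrying exactly zero flux, subject to
steady state (`S v = 0`) and bounds. Because no MILP solver package is
available as a dependency, the package solves this exactly by depth-first
branch-and-bound over per-reaction activity indicators with LP-feasibility
pruning; the bound is the count of satisfied reactions plus all undecided
ones, and satisfied branches are explored first so the incumbent rises
quickly. The test suite verifies the optimum against exhaustive enumeration
on randomized networks. Ties between optimal activity patterns are resolved
deterministically by the fixed exploration order (forward activation,
reverse activation, unsatisfied; high reactions before low ones, model
order within each class). Only low reactions assigned inactive are closed
(`lb = ub = 0`) in the returned context model.

The LP kernel itself is a dense bounded-variable two-phase simplex written
for the package (`R/lp.R`): the curated subsystem has ~26 columns, far
below the scale where sparse or factorization-caching methods matter.
Bland's rule is used throughout, so the method cannot cycle; the basis is
refactorized at every iteration for numerical safety. Optima agree with a
brute-force vertex-enumeration oracle to 1e-7 on randomized models.

The per-sample scalar entering group comparison is the FVA **maximum** flux
per reaction at objective fraction 1.0 (both extrema are returned). The
fixture's objective places equal demand weight on the four exit routes;
users supplying genome-scale models can direct the objective at a biomass
maintenance or exchange reaction instead. Flux tables are z-scored per
reaction (`scale()` semantics, n−1 denominator; zero-variance columns
become zero with a warning), compared between diagnosis groups with the
two-sided Mann-Whitney rank-sum test (exact null for both groups ≤ 8
without ties, otherwise the tie- and continuity-corrected normal
approximation), and adjusted by Benjamini-Hochberg across the joint family
of all reaction × group-pair tests — the conservative family choice, made
explicit because "adjusted p" alone does not pin down a family.

Two behaviors of this design are worth knowing. First, in a small network
at optimum many reactions sit at saturated or forced flux values, so
between-sample variance — and hence any group signal — comes mostly from
reactions that the context extraction closes; a planted expression change
only propagates to a flux difference when it flips discretization states.
Second, because discretization is by within-sample quantiles, states
compete by rank: strongly silencing one branch frees slots in the low band
and can shift the classification of untouched reactions, producing
collateral group differences. The recovery test asserts that the planted
reaction leads the ranking rather than that it is the sole flagged one.

## Ratio arm

Lipid names are parsed from shorthand nomenclature (`CLASS(dC:D)`, or
`CLASS(dB:Y/A:Z)` with an explicit base/acyl split). When only the total is
given, the sphingoid base is assumed d18:1, so the N-acyl chain length is
`total − 18` carbons; the short/long boundary is an acyl chain of 20
carbons (`chain_cut = 20`, short strictly below). This convention is forced
by the observation that SM(d34:1) must classify short and SM(d43:1) long
under a C20 cut — total carbons cannot satisfy that.

Trait enumeration has two modes. `all` builds every single-species trait
plus every ordered ratio of distinct species: 112 species yield
112 + 112 × 111 = 12,544 traits. (The same total also equals 112² ordered
pairs with self-ratios; the singles-plus-ordered-pairs reading is
implemented because the screen tests individual species and ratios.)
`targeted` builds short-over-long SM ratios only, one orientation per pair;
the p-gain is orientation-invariant because flipping a log-ratio's sign
leaves |t| unchanged, which the suite asserts to 1e-10.

Trait values are log2-transformed before regression. In targeted mode,
medication covariates are selected per trait by BIC backward elimination on
the unadjusted trait values (base covariates never dropped; linear BIC
computed as `n ln(RSS/n) + k ln(n)`, which differs from the full Gaussian
likelihood only by a model-independent constant), and then the ratio and
both constituents are tested with base + selected medications as
covariates. The p-gain of a ratio is
`min(p_numerator, p_denominator) / p_ratio`; no significance threshold is
imposed on it — it is a ranking criterion. BH adjustment runs across all
traits in a screen.

For continuous phenotypes the all-mode screen uses a residualization fast
path (project phenotype and log-abundances off the covariate design once;
every single and ratio t-test then follows from cross-products), which the
suite verifies is numerically identical to per-trait regression at 1e-10.
Binary phenotypes fall back to per-trait logistic fits; perfect separation
is reported with a missing p rather than a spurious one.

## Genetic arm

Variant QC follows the standard cascade, samples before variants: samples
with call rate < 0.95 are dropped first, then variants failing call rate
(< 0.95), exact Hardy-Weinberg equilibrium (p < 1e-5), or minor allele
frequency (< 0.05). The imputation-era profile (`qc_profile("adni2")`)
tightens HWE to 1e-6 and relaxes MAF to 0.01. MAF and HWE are computed from
non-missing calls among retained samples; the QC report retains every
pre-filter variant with its pass flag so exclusions are auditable.

The HWE test is the exact conditional (Levene-Haldane) test: given the
allele totals, heterozygote counts sharing the parity of the rare-allele
count are enumerated, and the two-sided p is the total probability of
outcomes no more probable than the observed one, computed in log space.

Variants are projected to genes positionally: the variant's 0-based
coordinate must fall in the gene's 0-based half-open interval widened by a
flank (default 5 kb). This is a declared surrogate for regulatory-aware
projection (eQTL/promoter links), which is out of scope. All internal
interval logic is 0-based half-open; user-facing positions are 1-based VCF
coordinates.

Per-gene inference uses the minimum single-variant association p across the
gene's variants (additive 0/1/2 coding, covariate-adjusted, per-variant
complete cases). Gene-wise Bonferroni thresholds are `0.05 / n_variants`.
Because variants within a gene are correlated through linkage
disequilibrium, Bonferroni is conservative, so the package also computes a
permutation-based empirical p: phenotype rows (with their covariates,
which travel with the phenotype) are shuffled against the genotypes
`B = 20,000` times by default, the min-p is recomputed each time, and the
empirical p is `(1 + #{permuted ≤ observed}) / (B + 1)` — never zero, and
reproducible under the recorded seed. Tests run at B ≤ 999. Continuous
phenotypes use the exact OLS t statistic throughout; binary phenotypes use
the logistic score test, whose null model is permutation-invariant up to
row order, applied identically to observed and permuted data so ranks
remain exchangeable.

## Synthetic data and what it shows

The generators are pure functions of their parameters and a seed.

* `simulate_expression()` draws a log-scale baseline mean per gene once per
  seed, adds i.i.d. Gaussian noise (SD 0.5) per sample, and applies planted
  group shifts in noise-SD units. It emulates group-shifted log-normal
  expression only — no library-size, batch, or correlation structure.
* `simulate_panel()` names species with valid SM shorthand spanning both
  chain classes (up to 56 + 56 species), draws log-abundances from an
  exchangeable-correlation Gaussian (ρ = 0.3, log-SD 0.4), and builds the
  continuous phenotype from covariate effects, medication effects, an
  optional planted ratio effect, and unit noise. When a ratio effect is
  planted, the designated pair shares an opposing latent factor, which is
  precisely the situation in which a ratio is more informative than either
  constituent — the signal the p-gain is designed to detect. The first
  medication also shifts the numerator species (a planted confounder sized
  for reliable backward-selection recovery at the default n = 400).
  Real lipidomics features deliberately not emulated: batch effects,
  limit-of-detection censoring, heavy-tailed technical error.
* `simulate_genotypes()` draws Hardy-Weinberg genotypes at uniform MAFs,
  optionally with Markov-style local LD (neighbor copying), a planted
  additive causal variant, and completely-at-random missingness. It does
  not emulate realistic LD maps or population structure.

Passing the recovery tests therefore demonstrates that each arm detects the
effect class it targets at desk-scale power — not that it reproduces
cohort-specific effect sizes, which depend on controlled-access data. The
flux recovery scenario silences the sphingomyelin branch in one group
(strong shifts, −10/+6 noise-SD units): within-sample quantile
discretization adapts its cutoffs, so moderate shifts can leave every
sample's classification unchanged; the recovery condition is a deliberate
strong perturbation that flips states regardless of the seed's baseline
draw.

Problem sizes in the test suite are chosen to keep the full run in minutes
on one core: oracle comparisons use networks of ≤ 12 reactions, HWE
enumeration uses counts ≤ 80, calibration loops use 100-200 repeats at
n = 30-200, and permutation tests run at B = 99-999 with full-size B
reserved for real analyses.

## Known limitations

* FVA on small loops (e.g. the reversible SM synthase against
  sphingomyelinase) reports bound-saturated extrema, as in any
  non-loopless FVA; thermodynamic or loopless constraints are out of scope.
* The branch-and-bound MILP is exact but exponential in the worst case; it
  is intended for curated subsystems (tens of reactions), not genome-scale
  models.
* Logistic permutation inference swaps the Wald statistic for the score
  statistic; the two agree asymptotically but can differ at small n.
* Positional variant-to-gene projection with a fixed flank ignores
  regulatory evidence; the flank is a tunable surrogate.
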