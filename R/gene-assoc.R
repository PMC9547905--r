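#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test: given the observed allele counts, the probability
#' of each possible heterozygote count is computed under Hardy-Weinberg
#' proportions, and the two-sided p-value is the total mass of outcomes no
#' more probable than the observed one.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative, sum >= 1).
#' @return p-value in (0, 1].
#' @examples
#' hwe_exact(50, 0, 0)   # monomorphic: 1
#' hwe_exact(0, 100, 0)  # all heterozygous: ~0
#' @export
hwe_exact <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  stopifnot(n >= 1)
  n_A <- 2 * n_AA + n_Aa          # minor/major labelling is irrelevant
  n_a <- 2 * n_aa + n_Aa
  rare <- min(n_A, n_a)
  if (rare == 0) return(1)
  # heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # log conditional probability of each het count (Levene-Haldane)
  logp <- vapply(hets, function(h) {
    n_rr <- (rare - h) / 2
    n_cc <- n - n_rr - h
    lgamma(n + 1) - lgamma(n_rr + 1) - lgamma(h + 1) - lgamma(n_cc + 1) +
      h * log(2) + lgamma(n_A + 1) + lgamma(n_a + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- which(hets == n_Aa)
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-9)]))
}

#' Variant and sample quality control
#'
#' Applies the standard genotype QC cascade: samples with call rate below
#' `cr_min` are removed first; then variants failing call rate, exact
#' Hardy-Weinberg equilibrium ([hwe_exact()]), or minor allele frequency
#' thresholds are removed. MAF and HWE are computed from non-missing calls
#' among the retained samples.
#'
#' Default thresholds follow the discovery-cohort profile (call rate 0.95,
#' HWE p >= 1e-5, MAF >= 0.05); `qc_profile("adni2")` gives the
#' imputation-era profile (HWE 1e-6, MAF 0.01).
#'
#' @param geno List with `variants` (data.frame: `chrom`, `pos`, `id`,
#'   `ref`, `alt`) and `dosage` (matrix samples x variants, entries 0/1/2 or
#'   `NA`).
#' @param cr_min,hwe_min,maf_min QC thresholds.
#' @return List with `geno` (filtered), `report` (per-variant data.frame
#'   with `call_rate`, `maf`, `hwe_p`, `pass` for every pre-filter variant),
#'   and `samples_removed`.
#' @export
qc_filter <- function(geno, cr_min = 0.95, hwe_min = 1e-5, maf_min = 0.05) {
  dos <- geno$dosage
  stopifnot(nrow(dos) >= 1, ncol(dos) >= 1)
  bad <- !(dos %in% c(0, 1, 2) | is.na(dos))
  if (any(bad)) stop("dosage entries must be 0, 1, 2, or NA", call. = FALSE)
  sample_cr <- rowMeans(!is.na(dos))
  keep_s <- sample_cr >= cr_min
  removed <- rownames(dos)[!keep_s]
  dos <- dos[keep_s, , drop = FALSE]
  stats_v <- t(apply(dos, 2, function(g) {
    ok <- !is.na(g)
    cr <- mean(ok)
    g <- g[ok]
    if (length(g) == 0) return(c(cr = cr, maf = 0, hwe = 1))
    af <- mean(g) / 2
    maf <- min(af, 1 - af)
    hwe <- hwe_exact(sum(g == 0), sum(g == 1), sum(g == 2))
    c(cr = cr, maf = maf, hwe = hwe)
  }))
  report <- data.frame(variant = geno$variants$id,
                       call_rate = stats_v[, "cr"], maf = stats_v[, "maf"],
                       hwe_p = stats_v[, "hwe"], stringsAsFactors = FALSE)
  report$pass <- report$call_rate >= cr_min & report$maf >= maf_min &
    report$hwe_p >= hwe_min
  if (!any(report$pass)) {
    stop("QC removed every variant (", nrow(report), " tested)",
         call. = FALSE)
  }
  out <- list(variants = geno$variants[report$pass, , drop = FALSE],
              dosage = dos[, report$pass, drop = FALSE])
  list(geno = out, report = report, samples_removed = removed)
}

#' Named QC threshold profiles
#' @param profile `"adni1"` (call rate 0.95, HWE 1e-5, MAF 0.05) or
#'   `"adni2"` (call rate 0.95, HWE 1e-6, MAF 0.01).
#' @return Named list of thresholds for [qc_filter()].
#' @export
qc_profile <- function(profile = c("adni1", "adni2")) {
  profile <- match.arg(profile)
  switch(profile,
         adni1 = list(cr_min = 0.95, hwe_min = 1e-5, maf_min = 0.05),
         adni2 = list(cr_min = 0.95, hwe_min = 1e-6, maf_min = 0.01))
}

#' Assign variants to gene regions
#'
#' Positional projection: a variant (1-based position `pos`) is assigned to
#' a gene iff the chromosome matches and `pos - 1` falls in
#' `[start - flank, end + flank)` of the gene's 0-based half-open region.
#' A variant may map to multiple genes.
#'
#' @param variants data.frame with `chrom`, `pos` (1-based), `id`.
#' @param regions data.frame with `gene`, `chrom`, `start`, `end` (0-based
#'   half-open, BED convention).
#' @param flank Flanking distance in bp added on both sides (default 5000).
#' @return Named list, gene -> character vector of variant ids; genes with
#'   no assigned variant are omitted (with a message).
#' @export
assign_variants <- function(variants, regions, flank = 5000) {
  stopifnot(flank >= 0, all(regions$start < regions$end))
  vgr <- GenomicRanges::GRanges(
    seqnames = variants$chrom,
    ranges = IRanges::IRanges(start = variants$pos, width = 1))
  rgr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = pmax(regions$start - flank, 0) + 1,
                              end = regions$end + flank))
  # disjoint chromosome sets between the two inputs are expected, not a
  # problem; silence the Seqinfo merge warning
  hits <- suppressWarnings(GenomicRanges::findOverlaps(vgr, rgr))
  out <- split(variants$id[S4Vectors::queryHits(hits)],
               regions$gene[S4Vectors::subjectHits(hits)])
  out <- lapply(out, unique)
  empty <- setdiff(regions$gene, names(out))
  if (length(empty)) {
    message("gene(s) with no assigned variant omitted: ",
            paste(empty, collapse = ", "))
  }
  out
}

#' Single-variant association tests
#'
#' Additive (0/1/2) association of each variant with the phenotype,
#' covariate-adjusted, on per-variant complete cases. Continuous phenotypes
#' use OLS with a two-sided t-based Wald p; binary phenotypes use logistic
#' regression. Numerically identical to [associate()] on the same input.
#'
#' @param dosages Matrix samples x variants (0/1/2/NA).
#' @param phenotype Numeric vector.
#' @param covariates Optional data.frame.
#' @return data.frame per variant: `variant`, `n`, `beta`, `se`, `p`,
#'   `note` (`"monomorphic"` with `p = NA` for variants with no dosage
#'   variation after missing-data removal).
#' @export
variant_association <- function(dosages, phenotype, covariates = NULL) {
  dosages <- as.matrix(dosages)
  ids <- colnames(dosages) %||% as.character(seq_len(ncol(dosages)))
  rows <- lapply(seq_len(ncol(dosages)), function(j) {
    g <- dosages[, j]
    ok <- !is.na(g)
    if (length(unique(g[ok])) < 2) {
      return(data.frame(variant = ids[j], n = sum(ok), beta = NA_real_,
                        se = NA_real_, p = NA_real_, note = "monomorphic",
                        stringsAsFactors = FALSE))
    }
    a <- associate(g[ok], phenotype[ok],
                   if (!is.null(covariates)) {
                     as.data.frame(covariates)[ok, , drop = FALSE]
                   })
    data.frame(variant = ids[j], n = a$n, beta = a$beta, se = a$se, p = a$p,
               note = a$note, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Gene-wise Bonferroni threshold
#' @param n_variants Number of variants assigned to the gene (>= 1).
#' @return `0.05 / n_variants`.
#' @export
gene_bonferroni <- function(n_variants) {
  if (any(n_variants < 1)) {
    stop("gene has no assigned variants", call. = FALSE)
  }
  0.05 / n_variants
}

#' Genome-wide significance threshold adjusted for multiple traits
#'
#' Bonferroni division of the conventional genome-wide level by the number
#' of traits tested (e.g. four metabolic traits give 1.25e-8).
#'
#' @param n_traits Number of traits analyzed genome-wide (>= 1).
#' @param alpha Genome-wide significance level (default 5e-8).
#' @return `alpha / n_traits`.
#' @export
trait_adjusted_threshold <- function(n_traits, alpha = 5e-8) {
  stopifnot(n_traits >= 1)
  alpha / n_traits
}

#' Permutation-based gene-wise empirical p-value
#'
#' The observed statistic is the minimum association p-value across the
#' gene's variants. Phenotype rows (together with their covariates) are
#' randomly permuted against the genotypes `B` times, the minimum p is
#' recomputed each time, and the empirical p-value is
#' `(1 + #\{permuted min-p <= observed\}) / (B + 1)`.
#'
#' Continuous phenotypes use the exact OLS t-test throughout. Binary
#' phenotypes use the logistic score test (whose null fit is shared across
#' permutations), applied to observed and permuted data alike so ranks are
#' exchangeable.
#'
#' @param dosages Matrix samples x variants for one gene (0/1/2/NA).
#' @param phenotype Numeric vector.
#' @param covariates Optional data.frame, permuted jointly with the
#'   phenotype.
#' @param B Number of permutations (default 20000).
#' @param seed Integer RNG seed (recorded in the result).
#' @return List: `min_p`, `n_variants`, `bonferroni_threshold`, `perm_p`,
#'   `B`, `seed`.
#' @export
gene_permutation_p <- function(dosages, phenotype, covariates = NULL,
                               B = 20000, seed = 1) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) == 0) stop("gene has no variants", call. = FALSE)
  stopifnot(B >= 1)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  binary <- length(unique(phenotype[!is.na(phenotype)])) == 2L
  statfun <- if (binary) minp_score_binary else minp_ols
  obs <- statfun(dosages, phenotype, C)
  set.seed(seed)
  count <- 0L
  n <- length(phenotype)
  for (b in seq_len(B)) {
    perm <- sample.int(n)
    mp <- statfun(dosages, phenotype[perm],
                  if (!is.null(C)) C[perm, , drop = FALSE])
    if (!is.na(mp) && mp <= obs) count <- count + 1L
  }
  list(min_p = obs, n_variants = ncol(dosages),
       bonferroni_threshold = gene_bonferroni(ncol(dosages)),
       perm_p = (1 + count) / (B + 1), B = B, seed = seed)
}

# min over variants of the exact OLS t-test p, per-variant complete cases
minp_ols <- function(G, y, C) {
  full <- !anyNA(G) && !anyNA(y) && (is.null(C) || !anyNA(C))
  if (full) {
    keepv <- apply(G, 2, function(g) length(unique(g)) > 1)
    if (!any(keepv)) return(NA_real_)
    sc <- fast_ols_scan(G[, keepv, drop = FALSE], y, C)
    return(min(sc$p))
  }
  ps <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    ok <- !is.na(g) & !is.na(y)
    if (!is.null(C)) ok <- ok & stats::complete.cases(C)
    if (length(unique(g[ok])) < 2) return(NA_real_)
    sc <- fast_ols_scan(matrix(g[ok], ncol = 1), y[ok],
                        if (!is.null(C)) C[ok, , drop = FALSE])
    sc$p[1]
  }, numeric(1))
  if (all(is.na(ps))) NA_real_ else min(ps, na.rm = TRUE)
}

# min over variants of the logistic score-test p (complete data path; rows
# with any missingness are dropped once for the gene block)
minp_score_binary <- function(G, y, C) {
  ok <- stats::complete.cases(G) & !is.na(y)
  if (!is.null(C)) ok <- ok & stats::complete.cases(C)
  G <- G[ok, , drop = FALSE]
  y <- as.numeric(factor(y[ok])) - 1
  X <- cbind(1, if (!is.null(C)) C[ok, , drop = FALSE])
  storage.mode(X) <- "double"
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
  mu <- fit$fitted.values
  r <- y - mu
  w <- mu * (1 - mu)
  XtWX <- crossprod(X * w, X)
  XtWG <- crossprod(X * w, G)
  U <- as.numeric(crossprod(G, r))
  V <- colSums(G^2 * w) - colSums(XtWG * solve(XtWX, XtWG))
  keep <- V > 1e-12
  if (!any(keep)) return(NA_real_)
  z2 <- U[keep]^2 / V[keep]
  min(stats::pchisq(z2, df = 1, lower.tail = FALSE))
}
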