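#' Simulate group-shifted expression profiles
#'
#' Per-gene log-normal baselines: each gene draws a log-scale mean once per
#' seed, each sample adds i.i.d. Gaussian noise on the log scale, and planted
#' genes receive a group-specific mean shift expressed in noise-SD units
#' (e.g. SGMS1 shifted up in AD). Deterministic given the seed.
#'
#' @param model A [pathway_model()] supplying the gene universe.
#' @param n_per_group Named integer vector of samples per diagnosis group,
#'   default `c(AD = 20, MCI = 20, NCI = 20)`.
#' @param shifts data.frame with columns `gene`, `group`, `effect` (shift in
#'   SD units); `NULL` for a global null.
#' @param noise_sd Log-scale noise SD (default 0.5).
#' @param seed Integer seed.
#' @return List with `profiles` (named list of gene -> expression vectors),
#'   `diagnosis` (named character vector), and `truth` (planted-effect
#'   ledger, JSON-serializable).
#' @export
simulate_expression <- function(model,
                                n_per_group = c(AD = 20, MCI = 20, NCI = 20),
                                shifts = NULL, noise_sd = 0.5, seed = 1) {
  stopifnot(all(n_per_group >= 2))
  genes <- model$genes
  if (length(genes) == 0) stop("model has no genes", call. = FALSE)
  if (!is.null(shifts)) {
    missing_g <- setdiff(shifts$gene, genes)
    if (length(missing_g)) {
      stop("shift names gene(s) absent from the model: ",
           paste(missing_g, collapse = ", "), call. = FALSE)
    }
  }
  set.seed(seed)
  base_mu <- stats::rnorm(length(genes), mean = 2, sd = 1)
  names(base_mu) <- genes
  groups <- rep(names(n_per_group), n_per_group)
  ids <- sprintf("S%03d", seq_along(groups))
  profiles <- vector("list", length(ids))
  names(profiles) <- ids
  for (i in seq_along(ids)) {
    mu <- base_mu
    if (!is.null(shifts)) {
      hit <- shifts$group == groups[i]
      if (any(hit)) {
        mu[shifts$gene[hit]] <- mu[shifts$gene[hit]] +
          shifts$effect[hit] * noise_sd
      }
    }
    profiles[[i]] <- exp(mu + stats::rnorm(length(genes), 0, noise_sd))
  }
  diagnosis <- setNames(groups, ids)
  truth <- list(kind = "expression",
                shifts = if (is.null(shifts)) list() else shifts,
                noise_sd = noise_sd, n_per_group = as.list(n_per_group),
                seed = seed)
  list(profiles = profiles, diagnosis = diagnosis, truth = truth)
}

#' Simulate a lipid panel with covariates, medications, and phenotypes
#'
#' Species are named with valid sphingomyelin shorthand (8 total-carbon x 7
#' double-bond combinations per chain class, so the default 56 + 56 covers
#' SM(d30:0)..SM(d45:6)), log-abundances are multivariate normal with
#' exchangeable correlation, and the continuous phenotype is built as
#' `beta * log2(numerator/denominator) + covariate effects + medication
#' effects + noise`. When `ratio_effect` is nonzero, the designated pair
#' additionally shares an opposing latent factor so the ratio is more
#' informative than either constituent (the situation the p-gain screen is
#' designed to detect). One medication acts on both the phenotype and the
#' numerator species, planting a recoverable confounder.
#'
#' @param n Number of samples (default 400).
#' @param n_short,n_long Species counts per chain class (default 56 + 56;
#'   at most 56 each with the built-in naming grid).
#' @param correlation Exchangeable correlation of log-abundances
#'   (default 0.3).
#' @param ratio_effect Phenotype effect per log2 unit of the planted ratio
#'   (default 0 = null panel).
#' @param med_effects Named numeric vector: phenotype effect per medication
#'   indicator. Default plants one active medication (`med1 = 2`) and one
#'   inert one (`med2 = 0`).
#' @param seed Integer seed.
#' @return List with `abundances` (samples x species), `covariates`,
#'   `medications`, `phenotypes` (data.frame `cognition`, `diagnosis`),
#'   `species` (parsed nomenclature), and `truth`.
#' @export
simulate_panel <- function(n = 400, n_short = 56, n_long = 56,
                           correlation = 0.3, ratio_effect = 0,
                           med_effects = c(med1 = 2, med2 = 0), seed = 1) {
  stopifnot(n_short + n_long >= 2, n_short <= 56, n_long <= 56,
            correlation >= 0, correlation < 1)
  short_grid <- expand.grid(c = 30:37, d = 0:6)
  long_grid <- expand.grid(c = 38:45, d = 0:6)
  short_names <- sprintf("SM(d%d:%d)", short_grid$c, short_grid$d)[seq_len(n_short)]
  long_names <- sprintf("SM(d%d:%d)", long_grid$c, long_grid$d)[seq_len(n_long)]
  species <- c(short_names, long_names)
  p <- length(species)
  set.seed(seed)
  mu <- stats::rnorm(p, mean = 5, sd = 1)
  sd_l <- 0.4
  f <- stats::rnorm(n)
  E <- matrix(stats::rnorm(n * p), n, p)
  logab <- sweep(sd_l * (sqrt(correlation) * f +
                           sqrt(1 - correlation) * E), 2, mu, "+")
  colnames(logab) <- species

  num <- short_names[1]
  den <- long_names[1]
  if (ratio_effect != 0) {
    u <- stats::rnorm(n, 0, sd_l)       # opposing latent factor in the pair
    logab[, num] <- logab[, num] + u
    logab[, den] <- logab[, den] - u
  }

  covariates <- data.frame(
    age = stats::rnorm(n, 75, 7),
    sex = stats::rbinom(n, 1, 0.5),
    bmi = stats::rnorm(n, 27, 4),
    hdl = stats::rnorm(n, 55, 14),
    chol = stats::rnorm(n, 200, 35),
    trig = exp(stats::rnorm(n, log(130), 0.4)),
    apoe4 = stats::rbinom(n, 2, 0.25),
    fasting = stats::rbinom(n, 1, 0.9))
  meds <- if (length(med_effects)) {
    md <- as.data.frame(lapply(seq_along(med_effects), function(i) {
      stats::rbinom(n, 1, 0.2)
    }))
    names(md) <- names(med_effects)
    md
  } else {
    data.frame(row.names = seq_len(n))
  }
  # medication confounding: the first medication also raises the numerator;
  # effect sized for reliable backward-selection recovery at the default n
  med_species_effect <- 0
  if (length(med_effects)) {
    med_species_effect <- 2 * sd_l
    logab[, num] <- logab[, num] + med_species_effect * meds[[1]]
  }
  ratio <- (logab[, num] - logab[, den]) / log(2)  # log2 ratio
  med_term <- if (length(med_effects)) {
    as.numeric(as.matrix(meds) %*% med_effects)
  } else {
    0
  }
  cognition <- 10 +
    0.05 * (covariates$age - 75) + 0.5 * covariates$apoe4 +
    0.02 * (covariates$bmi - 27) +
    med_term +
    ratio_effect * ratio +
    stats::rnorm(n, 0, 1)
  cognition <- as.numeric(cognition)
  diagnosis <- stats::rbinom(n, 1, stats::plogis((cognition - 11) / 2))
  rownames(logab) <- sprintf("P%04d", seq_len(n))
  truth <- list(kind = "panel", numerator = num, denominator = den,
                ratio_effect = ratio_effect,
                med_effects = as.list(med_effects),
                med_species_effect = med_species_effect,
                correlation = correlation, n = n, seed = seed)
  list(abundances = exp(logab), covariates = covariates,
       medications = meds,
       phenotypes = data.frame(cognition = cognition,
                               diagnosis = diagnosis),
       species = parse_lipid_name(species), truth = truth)
}

#' Simulate Hardy-Weinberg genotypes with an optional planted causal variant
#'
#' Minor allele frequencies are drawn uniformly from `maf_range`; genotypes
#' are Hardy-Weinberg draws, optionally with local linkage disequilibrium
#' (each successive variant copies the previous allele per haplotype with
#' probability `1 - switch_prob`). The phenotype is additive in the causal
#' dosage plus standard normal noise; missingness is applied completely at
#' random.
#'
#' @param n Samples (default 500).
#' @param m_variants Variants (default 50).
#' @param maf_range Length-2 numeric in (0, 0.5] (default `c(0.05, 0.5)`).
#' @param causal `NULL`, or list with `index` (variant index) and `beta`
#'   (phenotype effect per allele).
#' @param ld Optional list with `switch_prob` in (0, 1]; `NULL` for
#'   independent variants.
#' @param missing_rate Fraction of dosage entries set missing (default 0).
#' @param seed Integer seed.
#' @return List with `geno` (`variants`, `dosage`), `phenotype`,
#'   `covariates` (age, sex), and `truth`.
#' @export
simulate_genotypes <- function(n = 500, m_variants = 50,
                               maf_range = c(0.05, 0.5), causal = NULL,
                               ld = NULL, missing_rate = 0, seed = 1) {
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  if (!is.null(causal) &&
      (causal$index < 1 || causal$index > m_variants)) {
    stop("causal index out of range", call. = FALSE)
  }
  set.seed(seed)
  maf <- stats::runif(m_variants, maf_range[1], maf_range[2])
  hap <- function() {
    H <- matrix(0L, n, m_variants)
    H[, 1] <- stats::rbinom(n, 1, maf[1])
    if (m_variants > 1) {
      for (j in 2:m_variants) {
        fresh <- stats::rbinom(n, 1, maf[j])
        if (is.null(ld)) {
          H[, j] <- fresh
        } else {
          copy <- stats::rbinom(n, 1, 1 - ld$switch_prob)
          H[, j] <- ifelse(copy == 1, H[, j - 1], fresh)
        }
      }
    }
    H
  }
  dosage <- hap() + hap()
  storage.mode(dosage) <- "double"
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(n * m_variants) < missing_rate,
                   n, m_variants)
    dosage[mask] <- NA_real_
  }
  pos <- sort(sample.int(5e6, m_variants)) + 1e6
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, m_variants, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))
  variants <- data.frame(chrom = "1", pos = pos,
                         id = sprintf("var%04d", seq_len(m_variants)),
                         ref = ref, alt = alt, stringsAsFactors = FALSE)
  rownames(dosage) <- sprintf("I%04d", seq_len(n))
  colnames(dosage) <- variants$id
  g_causal <- if (is.null(causal)) 0 else {
    gc <- dosage[, causal$index]
    gc[is.na(gc)] <- 2 * maf[causal$index]   # phenotype built on true dosage
    causal$beta * gc
  }
  covariates <- data.frame(age = stats::rnorm(n, 75, 7),
                           sex = stats::rbinom(n, 1, 0.5))
  phenotype <- as.numeric(g_causal + 0.02 * (covariates$age - 75) +
                            stats::rnorm(n))
  truth <- list(kind = "genotypes",
                causal = if (is.null(causal)) NULL else
                  list(id = variants$id[causal$index],
                       index = causal$index, beta = causal$beta,
                       maf = maf[causal$index]),
                maf_range = maf_range, missing_rate = missing_rate,
                n = n, m_variants = m_variants, seed = seed)
  list(geno = list(variants = variants, dosage = dosage),
       phenotype = phenotype, covariates = covariates, truth = truth)
}
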