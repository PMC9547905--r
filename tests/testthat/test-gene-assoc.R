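perms_of <- function(n) {
  # all permutations of seq_len(n), tiny n only
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms_of(n - 1)) {
    for (k in 0:(n - 1)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

test_that("HWE exact test matches brute-force enumeration", {
  expect_equal(hwe_exact(50, 0, 0), 1)
  expect_equal(hwe_exact(3, 5, 2), oracle_hwe(3, 5, 2), tolerance = 1e-12)
  set.seed(14)
  for (i in 1:50) {
    cnt <- as.vector(stats::rmultinom(1, sample(5:60, 1), c(0.3, 0.4, 0.3)))
    expect_equal(hwe_exact(cnt[1], cnt[2], cnt[3]),
                 oracle_hwe(cnt[1], cnt[2], cnt[3]), tolerance = 1e-9,
                 label = paste(cnt, collapse = ","))
  }
})

test_that("HWE exact test is symmetric and chi-square-consistent", {
  expect_equal(hwe_exact(3, 5, 2), hwe_exact(2, 5, 3), tolerance = 1e-12)
  expect_equal(hwe_exact(30, 10, 25), hwe_exact(25, 10, 30),
               tolerance = 1e-12)
  # large balanced counts: agreement with the 1-df chi-square test
  nAA <- 2600; nAa <- 4900; naa <- 2500
  n <- nAA + nAa + naa
  pA <- (2 * nAA + nAa) / (2 * n)
  expd <- n * c(pA^2, 2 * pA * (1 - pA), (1 - pA)^2)
  stat <- sum((c(nAA, nAa, naa) - expd)^2 / expd)
  p_chi <- pchisq(stat, 1, lower.tail = FALSE)
  p_ex <- hwe_exact(nAA, nAa, naa)
  expect_lt(abs(p_ex - p_chi) / p_chi, 0.1)
})

test_that("an all-heterozygote variant fails HWE at 1e-5", {
  expect_lt(hwe_exact(0, 100, 0), 1e-5)
  g <- list(variants = data.frame(chrom = "1", pos = 1:2,
                                  id = c("ok", "allhet"), ref = "A",
                                  alt = "G"),
            dosage = cbind(ok = rbinom(100, 2, 0.4),
                           allhet = rep(1, 100)))
  rownames(g$dosage) <- paste0("S", 1:100)
  qc <- qc_filter(g)
  expect_false(qc$report$pass[qc$report$variant == "allhet"])
  expect_lt(qc$report$hwe_p[qc$report$variant == "allhet"], 1e-5)
})

test_that("QC fails monomorphic and low-call-rate variants", {
  set.seed(9)
  n <- 100
  # enough well-behaved variants that sample call rates stay above 0.95
  filler <- matrix(rbinom(n * 40, 2, 0.4), n, 40,
                   dimnames = list(NULL, paste0("f", 1:40)))
  sparse <- rbinom(n, 2, 0.3)
  sparse[1:10] <- NA                     # 10% missing
  dos <- cbind(mono = rep(0, n), sparse = sparse,
               good = rbinom(n, 2, 0.3), filler)
  rownames(dos) <- paste0("S", seq_len(n))
  g <- list(variants = data.frame(chrom = "1", pos = seq_len(ncol(dos)),
                                  id = colnames(dos), ref = "A", alt = "G"),
            dosage = dos)
  qc <- qc_filter(g, cr_min = 0.95)
  expect_length(qc$samples_removed, 0)
  rep_ <- qc$report
  expect_false(rep_$pass[rep_$variant == "mono"])
  expect_equal(rep_$maf[rep_$variant == "mono"], 0)
  expect_false(rep_$pass[rep_$variant == "sparse"])
  expect_lt(rep_$call_rate[rep_$variant == "sparse"], 0.95)
  expect_true(rep_$pass[rep_$variant == "good"])
})

test_that("samples are filtered before variants", {
  # one sample with 50% missing drags call rates down unless removed first
  dos <- cbind(v1 = c(NA, rep(c(0, 1, 2, 1), 5)),
               v2 = c(NA, rbinom(20, 2, 0.4)))
  dos[1, ] <- NA   # sample 1: fully missing
  rownames(dos) <- paste0("S", 1:21)
  g <- list(variants = data.frame(chrom = "1", pos = 1:2,
                                  id = c("v1", "v2"), ref = "A", alt = "G"),
            dosage = dos)
  qc <- qc_filter(g, cr_min = 0.9)
  expect_identical(qc$samples_removed, "S1")
  expect_true(all(qc$report$call_rate == 1))   # denominators post-filter
})

test_that("variant-to-gene assignment respects half-open intervals and flank", {
  regions <- data.frame(gene = "SGMS1", chrom = "chr1", start = 99, end = 100)
  v100 <- data.frame(chrom = "chr1", pos = 100, id = "v100")
  v101 <- data.frame(chrom = "chr1", pos = 101, id = "v101")
  expect_identical(assign_variants(v100, regions, flank = 0)$SGMS1, "v100")
  expect_null(suppressMessages(
    assign_variants(v101, regions, flank = 0))$SGMS1)
  # flank of 1000 captures a variant 500 bp upstream of the region
  wide <- data.frame(gene = "G", chrom = "chr1", start = 10000, end = 10100)
  up <- data.frame(chrom = "chr1", pos = 9500, id = "vup")
  expect_identical(assign_variants(up, wide, flank = 1000)$G, "vup")
  expect_null(suppressMessages(
    assign_variants(up, wide, flank = 400))$G)
  # wrong chromosome never matches
  off <- data.frame(chrom = "chr2", pos = 100, id = "voff")
  expect_null(suppressMessages(
    assign_variants(off, regions, flank = 1000))$SGMS1)
})

test_that("variant association equals the shared estimator", {
  set.seed(33)
  g <- rbinom(120, 2, 0.3)
  y <- 0.4 * g + rnorm(120)
  cv <- data.frame(age = rnorm(120))
  va <- variant_association(cbind(v = g), y, cv)
  a <- associate(g, y, cv)
  expect_equal(va$beta, a$beta, tolerance = 1e-10)
  expect_equal(va$p, a$p, tolerance = 1e-10)
  # monomorphic variants are flagged, not fatal
  va2 <- variant_association(cbind(v = rep(1, 120)), y, cv)
  expect_identical(va2$note, "monomorphic")
  expect_true(is.na(va2$p))
})

test_that("a planted additive effect is detected with high power", {
  set.seed(41)
  hits <- 0; reps <- 100
  for (r in seq_len(reps)) {
    g <- rbinom(1000, 2, 0.3)
    y <- 0.5 * g + rnorm(1000)
    if (variant_association(cbind(v = g), y)$p < 1e-4) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})

test_that("null variant p-values are uniform", {
  set.seed(51)
  ok <- 0; reps <- 5
  for (r in seq_len(reps)) {
    sim <- simulate_genotypes(n = 150, m_variants = 300, seed = 6000 + r)
    y <- rnorm(150)   # phenotype independent of all genotypes
    p <- variant_association(sim$geno$dosage, y)$p
    if (stats::ks.test(p, "punif")$p.value > 0.01) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("gene-wise Bonferroni thresholds follow 0.05/n", {
  expect_equal(gene_bonferroni(1), 0.05)
  expect_equal(gene_bonferroni(250), 2e-4)
  expect_error(gene_bonferroni(0), "no assigned variants")
  n <- c(1, 5, 50, 500)
  expect_true(all(diff(gene_bonferroni(n)) < 0))
})

test_that("permutation p agrees with exhaustive enumeration at tiny n", {
  set.seed(61)
  n <- 6
  G <- cbind(v1 = rbinom(n, 2, 0.4), v2 = rbinom(n, 2, 0.4))
  while (length(unique(G[, 1])) < 2 || length(unique(G[, 2])) < 2) {
    G <- cbind(v1 = rbinom(n, 2, 0.4), v2 = rbinom(n, 2, 0.4))
  }
  y <- rnorm(n, G[, 1])
  obs <- sphingolens:::minp_ols(G, y, NULL)
  exact <- mean(vapply(perms_of(n), function(pm) {
    sphingolens:::minp_ols(G, y[pm], NULL) <= obs
  }, logical(1)))
  r <- gene_permutation_p(G, y, B = 4000, seed = 3)
  # sampled estimate concentrates on the exhaustive value
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(r$perm_p - exact), 4 * se + 1 / 4000)
  expect_equal(r$min_p, obs)
})

test_that("an extreme observed statistic yields the add-one floor", {
  set.seed(71)
  g <- rbinom(400, 2, 0.3)
  y <- 2 * g + rnorm(400, sd = 0.2)
  r <- gene_permutation_p(cbind(v = g), y, B = 999, seed = 5)
  expect_equal(r$perm_p, 1 / 1000)
  # and is reproducible under the same seed
  r2 <- gene_permutation_p(cbind(v = g), y, B = 999, seed = 5)
  expect_identical(r, r2)
})

test_that("null permutation p-values are uniform on their grid", {
  set.seed(81)
  n_genes <- 120
  ps <- numeric(n_genes)
  for (i in seq_len(n_genes)) {
    sim <- simulate_genotypes(n = 60, m_variants = 3, seed = 7000 + i)
    y <- rnorm(60)
    ps[i] <- gene_permutation_p(sim$geno$dosage, y, B = 99,
                                seed = 100 + i)$perm_p
  }
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
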