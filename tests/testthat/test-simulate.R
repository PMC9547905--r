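test_that("generators are pure functions of parameters and seed", {
  m <- bundled_sm_model()
  e1 <- simulate_expression(m, c(AD = 3, NCI = 3), seed = 4)
  e2 <- simulate_expression(m, c(AD = 3, NCI = 3), seed = 4)
  expect_identical(e1, e2)
  p1 <- simulate_panel(n = 30, n_short = 2, n_long = 2, seed = 4)
  p2 <- simulate_panel(n = 30, n_short = 2, n_long = 2, seed = 4)
  expect_identical(p1, p2)
  g1 <- simulate_genotypes(n = 30, m_variants = 5, seed = 4)
  g2 <- simulate_genotypes(n = 30, m_variants = 5, seed = 4)
  expect_identical(g1, g2)
  expect_false(identical(
    simulate_panel(n = 30, n_short = 2, n_long = 2, seed = 5)$abundances,
    p1$abundances))
})

test_that("planted expression shifts are detectable at the stated power", {
  m <- bundled_sm_model()
  hits <- 0; reps <- 100
  for (r in seq_len(reps)) {
    e <- simulate_expression(
      m, c(AD = 20, NCI = 20),
      shifts = data.frame(gene = "SPTLC1", group = "AD", effect = 2),
      seed = 8000 + r)
    x <- log(vapply(e$profiles, `[[`, numeric(1), "SPTLC1"))
    pv <- stats::t.test(x[e$diagnosis == "AD"],
                        x[e$diagnosis == "NCI"])$p.value
    if (pv < 0.01) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})

test_that("zero shifts leave group expression exchangeable", {
  m <- bundled_sm_model()
  set.seed(2)
  pvals <- c()
  for (r in 1:20) {
    e <- simulate_expression(m, c(AD = 15, NCI = 15), seed = 8500 + r)
    x <- log(vapply(e$profiles, `[[`, numeric(1), "SGMS1"))
    pvals <- c(pvals, stats::t.test(x[e$diagnosis == "AD"],
                                    x[e$diagnosis == "NCI"])$p.value)
  }
  expect_lte(sum(pvals < 0.05), qbinom(0.999, 20, 0.05))
})

test_that("shift naming an unknown gene is rejected", {
  m <- bundled_sm_model()
  expect_error(
    simulate_expression(m, shifts = data.frame(gene = "NOPE", group = "AD",
                                               effect = 1)),
    "absent from the model")
})

test_that("panel species names round-trip through the parser", {
  p <- simulate_panel(n = 20, n_short = 56, n_long = 56, seed = 3)
  info <- parse_lipid_name(colnames(p$abundances))
  expect_identical(nrow(info), 112L)
  expect_identical(sum(info$chain_class == "short"), 56L)
  expect_identical(sum(info$chain_class == "long"), 56L)
  expect_true(all(p$abundances > 0))
  tr <- enumerate_traits(colnames(p$abundances), mode = "all")
  expect_identical(nrow(tr), 12544L)
})

test_that("generated genotypes sit in Hardy-Weinberg equilibrium", {
  g <- simulate_genotypes(n = 2000, m_variants = 200, seed = 12)
  pass <- vapply(seq_len(200), function(j) {
    d <- g$geno$dosage[, j]
    hwe_exact(sum(d == 0), sum(d == 1), sum(d == 2)) >= 1e-5
  }, logical(1))
  expect_gte(mean(pass), 0.99)
})

test_that("missingness hits the requested call rate", {
  g <- simulate_genotypes(n = 500, m_variants = 40, missing_rate = 0.1,
                          seed = 13)
  cr <- mean(!is.na(g$geno$dosage))
  expect_lt(abs(cr - 0.9), 3 * sqrt(0.1 * 0.9 / (500 * 40)) + 0.005)
})

test_that("LD blocks induce neighbor correlation", {
  g <- simulate_genotypes(n = 1500, m_variants = 20,
                          ld = list(switch_prob = 0.1), seed = 14)
  d <- g$geno$dosage
  neigh <- mean(vapply(1:19, function(j) cor(d[, j], d[, j + 1]),
                       numeric(1)))
  g0 <- simulate_genotypes(n = 1500, m_variants = 20, seed = 14)
  neigh0 <- mean(vapply(1:19, function(j) {
    cor(g0$geno$dosage[, j], g0$geno$dosage[, j + 1])
  }, numeric(1)))
  expect_gt(neigh, 0.5)
  expect_lt(abs(neigh0), 0.1)
})

test_that("causal index bounds are validated", {
  expect_error(simulate_genotypes(n = 30, m_variants = 5,
                                  causal = list(index = 9, beta = 1)),
               "out of range")
})

test_that("truth ledgers round-trip through JSON", {
  p <- simulate_panel(n = 20, n_short = 2, n_long = 2, ratio_effect = 1,
                      seed = 6)
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(p$truth, f, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(f)
  expect_identical(back$numerator, p$truth$numerator)
  expect_identical(back$denominator, p$truth$denominator)
  expect_equal(back$ratio_effect, p$truth$ratio_effect)
  expect_equal(back$seed, p$truth$seed)
})
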