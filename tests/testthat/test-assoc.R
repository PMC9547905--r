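test_that("an exact linear fit recovers the slope with vanishing p", {
  x <- 1:10
  a <- suppressWarnings(associate(x, 2 * x))  # "essentially perfect fit"
  expect_equal(a$beta, 2, tolerance = 1e-12)
  expect_lt(a$p, 1e-100)   # effectively zero for an exact fit
  expect_identical(a$family, "gaussian")
})

test_that("OLS coefficients match the normal equations", {
  set.seed(5)
  x <- rnorm(5)
  z <- rnorm(5)
  y <- 1 + 2 * x - z + rnorm(5)
  a <- associate(x, y, data.frame(z = z))
  X <- cbind(1, x, z)
  beta_hat <- solve(crossprod(X), crossprod(X, y))
  expect_equal(a$beta, beta_hat[2], tolerance = 1e-10)
  rss <- sum((y - X %*% beta_hat)^2)
  se <- sqrt(rss / (5 - 3) * solve(crossprod(X))[2, 2])
  expect_equal(a$se, se, tolerance = 1e-10)
})

test_that("the OLS estimate concentrates at the simulated effect", {
  set.seed(10)
  x <- rnorm(1000)
  y <- 0.5 * x + rnorm(1000)
  a <- associate(x, y)
  expect_gt(a$beta, 0.4)
  expect_lt(a$beta, 0.6)
})

test_that("zero-variance traits and logistic separation are handled", {
  expect_error(associate(rep(1, 10), rnorm(10)), "zero variance")
  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(0:1, each = 20)
  a <- associate(x, y, family = "binomial")
  expect_identical(a$note, "separation")
  expect_true(is.na(a$p))
})

test_that("linear BIC matches the closed-form Gaussian likelihood ordering", {
  set.seed(8)
  n <- 40
  x <- rnorm(n)
  y <- 1 + x + rnorm(n)
  sel <- backward_select_bic(y, candidates = data.frame(x = x))
  # spec formula: n log(RSS/n) + k log(n)
  fit <- lm(y ~ x)
  bic_kept <- n * log(sum(resid(fit)^2) / n) + 2 * log(n)
  expect_equal(sel$bic, bic_kept, tolerance = 1e-10)
  # full-likelihood BIC differs only by an additive constant in n, so the
  # same model ordering results
  bic_full <- function(f, k) {
    rss <- sum(resid(f)^2)
    n * log(2 * pi * rss / n) + n + k * log(n)
  }
  f0 <- lm(y ~ 1)
  expect_equal(bic_full(fit, 2) - bic_full(f0, 1),
               bic_kept - (n * log(sum(resid(f0)^2) / n) + log(n)),
               tolerance = 1e-10)
})

test_that("backward selection keeps planted medications, drops noise", {
  set.seed(12)
  kept_planted <- 0; kept_noise <- 0; reps <- 100
  for (r in seq_len(reps)) {
    n <- 500
    med_real <- rbinom(n, 1, 0.3)
    med_noise <- rbinom(n, 1, 0.3)
    y <- 1 * med_real + rnorm(n)
    sel <- backward_select_bic(
      y, candidates = data.frame(real = med_real, noise = med_noise))
    if ("real" %in% sel$selected) kept_planted <- kept_planted + 1
    if ("noise" %in% sel$selected) kept_noise <- kept_noise + 1
  }
  expect_gte(kept_planted / reps, 0.95)
  expect_lte(kept_noise / reps, 0.25)
})

test_that("selection with no candidates returns the base model", {
  set.seed(2)
  y <- rnorm(30)
  sel <- backward_select_bic(y, base = data.frame(a = rnorm(30)))
  expect_identical(sel$selected, character(0))
  expect_identical(nrow(sel$trace), 1L)
})

test_that("aliased candidates are dropped with a warning before selection", {
  set.seed(4)
  m1 <- rbinom(50, 1, 0.5)
  y <- m1 + rnorm(50)
  expect_warning(
    sel <- backward_select_bic(y, candidates = data.frame(m1 = m1,
                                                          m2 = m1)),
    "aliased")
  expect_lte(length(sel$selected), 1L)
})

test_that("pgain follows its definition and inverts consistently", {
  expect_equal(pgain(0.05, 0.05, 0.05), 1)
  expect_equal(pgain(0.2, 0.3, 0.001), 200)
  expect_error(pgain(0, 0.1, 0.1), "positive")
  # a reported (p_ratio, pgain) pair determines the min constituent p
  p_ratio <- 1.70e-4
  reported_pgain <- 178.37
  implied_min_p <- reported_pgain * p_ratio
  expect_equal(pgain(implied_min_p, 0.5, p_ratio), reported_pgain,
               tolerance = 1e-10)
})

test_that("pgain is invariant to swapping numerator and denominator", {
  set.seed(6)
  n <- 80
  num <- rnorm(n); den <- rnorm(n)
  covs <- data.frame(age = rnorm(n))
  y <- 0.8 * (num - den) + rnorm(n)
  a_r <- associate(num - den, y, covs)
  a_rs <- associate(den - num, y, covs)
  a_n <- associate(num, y, covs)
  a_d <- associate(den, y, covs)
  expect_equal(a_r$p, a_rs$p, tolerance = 1e-10)   # |t| unchanged by sign
  expect_equal(pgain(a_n$p, a_d$p, a_r$p),
               pgain(a_d$p, a_n$p, a_rs$p), tolerance = 1e-10)
})
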