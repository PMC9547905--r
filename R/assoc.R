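#' Covariate-adjusted association of a trait with a phenotype
#'
#' Ordinary least squares for a continuous phenotype or maximum-likelihood
#' logistic regression for a binary one, returning the estimate, standard
#' error, and two-sided Wald p-value for the trait coefficient.
#'
#' @param trait Numeric vector of trait values.
#' @param phenotype Numeric vector; with exactly two distinct values (or
#'   `family = "binomial"`) a logistic model is fit.
#' @param covariates Optional data.frame/matrix of adjustment covariates.
#' @param family `"auto"` (default), `"gaussian"`, or `"binomial"`.
#' @return List with `beta`, `se`, `p`, `n`, `family`, and `note`
#'   (`"separation"` when a logistic fit separates perfectly, in which case
#'   `p` is `NA`).
#' @export
associate <- function(trait, phenotype, covariates = NULL,
                      family = c("auto", "gaussian", "binomial")) {
  family <- match.arg(family)
  df <- data.frame(.y = phenotype, .x = trait)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(phenotype))
    df <- cbind(df, covariates)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (stats::var(df$.x) == 0) {
    stop("trait has zero variance", call. = FALSE)
  }
  if (family == "auto") {
    family <- if (length(unique(df$.y)) == 2L) "binomial" else "gaussian"
  }
  if (n <= ncol(df)) {
    stop("more parameters than observations", call. = FALSE)
  }
  if (family == "gaussian") {
    fit <- stats::lm(.y ~ ., data = df)
    cf <- summary(fit)$coefficients
    list(beta = cf[".x", 1], se = cf[".x", 2], p = cf[".x", 4], n = n,
         family = family, note = NA_character_)
  } else {
    df$.y <- as.numeric(factor(df$.y)) - 1
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(.y ~ ., data = df, family = stats::binomial()),
      warning = function(w) {
        msg <- conditionMessage(w)
        if (grepl("fitted probabilities numerically 0 or 1", msg)) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        } else if (grepl("did not converge", msg)) {
          invokeRestart("muffleWarning")
        }
      })
    cf <- summary(fit)$coefficients
    list(beta = cf[".x", 1], se = cf[".x", 2],
         p = if (sep) NA_real_ else cf[".x", 4], n = n, family = family,
         note = if (sep) "separation" else NA_character_)
  }
}

#' Backward medication selection by BIC
#'
#' Starts from the full model (base covariates plus all candidate
#' medications) and iteratively removes the candidate whose removal most
#' decreases the Bayesian Information Criterion, stopping when no removal
#' decreases it. Base covariates are never dropped. For linear models
#' `BIC = n ln(RSS/n) + k ln(n)` with `k` the number of coefficients; for
#' binary outcomes `BIC = -2 loglik + k ln(n)`.
#'
#' @param y Outcome vector (continuous, or binary for logistic selection).
#' @param base Optional data.frame of base covariates (always retained).
#' @param candidates data.frame of candidate medication indicators.
#' @param family `"auto"`, `"gaussian"`, or `"binomial"`.
#' @return List with `selected` (character vector of retained candidate
#'   names), `bic` (BIC of the final model), and `trace` (data.frame of the
#'   removal path).
#' @export
backward_select_bic <- function(y, base = NULL, candidates = NULL,
                                family = c("auto", "gaussian", "binomial")) {
  family <- match.arg(family)
  if (family == "auto") {
    family <- if (length(unique(y[!is.na(y)])) == 2L) "binomial" else "gaussian"
  }
  base <- if (is.null(base)) {
    data.frame(row.names = seq_along(y))
  } else {
    as.data.frame(base)
  }
  candidates <- if (is.null(candidates)) {
    data.frame(row.names = seq_along(y))
  } else {
    as.data.frame(candidates)
  }
  keep <- stats::complete.cases(cbind(data.frame(.y = y), base, candidates))
  y <- y[keep]
  base <- base[keep, , drop = FALSE]
  candidates <- candidates[keep, , drop = FALSE]
  n <- length(y)

  fit_bic <- function(cand_names) {
    X <- cbind(data.frame(.y = y), base, candidates[, cand_names, drop = FALSE])
    if (family == "gaussian") {
      fit <- stats::lm(.y ~ ., data = X)
      k <- sum(!is.na(stats::coef(fit)))
      rss <- sum(stats::resid(fit)^2)
      n * log(rss / n) + k * log(n)
    } else {
      yy <- as.numeric(factor(y)) - 1
      X$.y <- yy
      fit <- suppressWarnings(stats::glm(.y ~ ., data = X,
                                         family = stats::binomial()))
      k <- sum(!is.na(stats::coef(fit)))
      -2 * as.numeric(stats::logLik(fit)) + k * log(n)
    }
  }

  cur <- colnames(candidates)
  if (length(cur) + ncol(base) + 1 >= n) {
    stop("full model has at least as many parameters as observations",
         call. = FALSE)
  }
  # drop candidates aliased in the full design before selection
  if (length(cur)) {
    X <- cbind(1, as.matrix(cbind(base, candidates)))
    storage.mode(X) <- "double"
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      kept_cols <- sort(qrX$pivot[seq_len(qrX$rank)])
      aliased <- setdiff(seq_len(ncol(X)), kept_cols)
      aliased_names <- colnames(X)[aliased]
      dropped <- intersect(cur, aliased_names)
      if (length(dropped)) {
        warning("dropping aliased candidate column(s): ",
                paste(dropped, collapse = ", "), call. = FALSE)
        cur <- setdiff(cur, dropped)
      }
    }
  }
  cur_bic <- fit_bic(cur)
  trace <- data.frame(removed = "<none>", bic = cur_bic,
                      stringsAsFactors = FALSE)
  while (length(cur)) {
    bics <- vapply(cur, function(cn) fit_bic(setdiff(cur, cn)), numeric(1))
    if (min(bics) < cur_bic) {
      drop_name <- cur[which.min(bics)]
      cur <- setdiff(cur, drop_name)
      cur_bic <- min(bics)
      trace <- rbind(trace, data.frame(removed = drop_name, bic = cur_bic,
                                       stringsAsFactors = FALSE))
    } else {
      break
    }
  }
  list(selected = cur, bic = cur_bic, trace = trace)
}

#' The p-gain of a metabolite ratio
#'
#' Ratio of the smaller of the two constituent association p-values to the
#' ratio's association p-value; values much larger than 1 indicate that the
#' ratio carries information beyond its parts.
#'
#' @param p_numerator,p_denominator,p_ratio Association p-values in (0, 1].
#' @return `min(p_numerator, p_denominator) / p_ratio`.
#' @examples
#' pgain(0.2, 0.3, 0.001)  # 200
#' @export
pgain <- function(p_numerator, p_denominator, p_ratio) {
  ps <- c(p_numerator, p_denominator, p_ratio)
  if (any(!is.finite(ps)) || any(ps <= 0)) {
    stop("p-values must be positive", call. = FALSE)
  }
  pmin(p_numerator, p_denominator) / p_ratio
}

# Fast OLS t-tests of many traits against one phenotype with shared
# covariates, by residualizing both sides on the covariate design
# (Frisch-Waugh). Returns beta, se, p per trait column.
# Requires complete data; callers pre-filter.
fast_ols_scan <- function(traits, y, covariates = NULL) {
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(covariates)) as.matrix(covariates))
  storage.mode(X) <- "double"
  q <- qr(X)
  Q <- qr.Q(q)
  ry <- y - Q %*% crossprod(Q, y)
  R <- traits - Q %*% crossprod(Q, traits)
  cxy <- as.numeric(crossprod(R, ry))
  sxx <- colSums(R^2)
  syy <- sum(ry^2)
  df <- n - q$rank - 1
  beta <- cxy / sxx
  rss <- pmax(syy - cxy^2 / sxx, 0)
  se <- sqrt(rss / df / sxx)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  data.frame(beta = beta, se = se, t = tval, p = p,
             row.names = colnames(traits))
}
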