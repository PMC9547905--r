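#' Column-wise z-score normalization of a flux table
#'
#' Centers and scales each reaction column by its sample mean and standard
#' deviation (n - 1 denominator), matching `scale()`. Columns with zero
#' variance are set to all-zero with a warning rather than NaN.
#'
#' @param flux_table Numeric matrix or data.frame, samples x reactions.
#' @return Numeric matrix of z-scores with the input dimnames.
#' @export
normalize_flux <- function(flux_table) {
  x <- as.matrix(flux_table)
  if (nrow(x) < 2) {
    stop("normalize_flux needs at least 2 samples", call. = FALSE)
  }
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  zero <- sdv == 0 | is.na(sdv)
  if (any(zero)) {
    warning("zero-variance column(s) set to 0: ",
            paste(colnames(x)[zero], collapse = ", "), call. = FALSE)
    sdv[zero] <- 1
  }
  z <- sweep(sweep(x, 2, mu, "-"), 2, sdv, "/")
  z[, zero] <- 0
  z
}

#' Rank-based group comparison of reaction fluxes
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test per reaction for each pair
#' of diagnosis groups, with Benjamini-Hochberg adjustment across all
#' reaction x group-pair tests in one family. The exact null distribution is
#' used for small groups (both n <= 8, no ties); otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param normalized Numeric matrix, samples x reactions (typically from
#'   [normalize_flux()]).
#' @param diagnosis Character/factor vector of group labels, one per row of
#'   `normalized` (e.g. `"AD"`, `"MCI"`, `"NCI"`).
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @return data.frame with columns `reaction`, `pair`, `n1`, `n2`,
#'   `statistic` (Mann-Whitney U for the first group of the pair), `p`,
#'   `p_adj`, `significant`.
#' @export
compare_flux_groups <- function(normalized, diagnosis, alpha = 0.05) {
  x <- as.matrix(normalized)
  diagnosis <- as.character(diagnosis)
  stopifnot(length(diagnosis) == nrow(x))
  groups <- unique(diagnosis)
  if (length(groups) < 2) {
    stop("need at least two diagnosis groups", call. = FALSE)
  }
  cnt <- table(diagnosis)
  small <- names(cnt)[cnt < 2]
  if (length(small)) {
    stop("group(s) with fewer than 2 samples: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  # canonical ordering puts AD first, NCI last, so pairs read AD-NCI etc.
  pref <- c("AD", "MCI", "NCI")
  groups <- c(intersect(pref, groups), sort(setdiff(groups, pref)))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- list()
  for (j in seq_len(ncol(x))) {
    for (pr in pairs) {
      v1 <- x[diagnosis == pr[1], j]
      v2 <- x[diagnosis == pr[2], j]
      if (length(unique(c(v1, v2))) == 1L) {
        # fully tied (e.g. a reaction closed in no sample): no separation
        u <- length(v1) * length(v2) / 2
        pv <- 1
      } else {
        use_exact <- length(v1) <= 8 && length(v2) <= 8
        wt <- suppressWarnings(
          stats::wilcox.test(v1, v2, alternative = "two.sided",
                             exact = use_exact, correct = TRUE))
        u <- unname(wt$statistic)
        pv <- wt$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        reaction = colnames(x)[j] %||% as.character(j),
        pair = paste(pr, collapse = "-"),
        n1 = length(v1), n2 = length(v2),
        statistic = u, p = pv,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p_adj < alpha
  res
}

#' Per-sample context-specific flux table
#'
#' For each expression profile: evaluate GPR rules, discretize reaction
#' expression ([discretize_expression()]), extract the context-specific
#' model ([extract_context_model()]), then run FVA on the context model.
#' The per-sample scalar kept for downstream group comparison is the FVA
#' maximum flux per reaction (the minimum is also returned).
#'
#' @param model A [pathway_model()].
#' @param profiles Named list of expression profiles (named numeric vectors),
#'   one per sample; names are sample ids.
#' @param q_low,q_high Discretization quantiles (default 0.25 / 0.75).
#' @param epsilon iMAT activation flux (default 1).
#' @param objective_fraction FVA objective fraction (default 1).
#' @return List with matrices `v_max` and `v_min` (samples x reactions) and
#'   `imat_objective`, a named numeric vector of per-sample agreement scores.
#' @export
compute_flux_table <- function(model, profiles, q_low = 0.25, q_high = 0.75,
                               epsilon = 1, objective_fraction = 1) {
  rid <- model$reactions$id
  n <- length(profiles)
  v_max <- v_min <- matrix(NA_real_, n, length(rid),
                           dimnames = list(names(profiles), rid))
  scores <- setNames(numeric(n), names(profiles))
  for (i in seq_len(n)) {
    st <- discretize_expression(profiles[[i]], model, q_low, q_high)
    ctx <- extract_context_model(model, st, epsilon)
    fv <- fva(ctx$model, objective_fraction = objective_fraction)
    v_max[i, fv$reaction] <- fv$v_max
    v_min[i, fv$reaction] <- fv$v_min
    scores[i] <- ctx$objective
  }
  list(v_max = v_max, v_min = v_min, imat_objective = scores)
}

#' Expression-to-flux group comparison pipeline
#'
#' End-to-end flux arm: per-sample context models and FVA
#' ([compute_flux_table()]), z-score normalization of the maximum fluxes
#' ([normalize_flux()]), and rank-based group comparison
#' ([compare_flux_groups()]).
#'
#' @inheritParams compute_flux_table
#' @param diagnosis Character vector of group labels aligned with `profiles`.
#' @param alpha Adjusted-p significance level (default 0.05).
#' @return List with `flux` (the [compute_flux_table()] result), `normalized`
#'   (z-scored max-flux matrix), and `comparison` (the tidy test table).
#' @export
run_flux_diff <- function(model, profiles, diagnosis, q_low = 0.25,
                          q_high = 0.75, epsilon = 1,
                          objective_fraction = 1, alpha = 0.05) {
  fl <- compute_flux_table(model, profiles, q_low, q_high, epsilon,
                           objective_fraction)
  z <- suppressWarnings(normalize_flux(fl$v_max))
  cmp <- compare_flux_groups(z, diagnosis, alpha)
  list(flux = fl, normalized = z, comparison = cmp)
}
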