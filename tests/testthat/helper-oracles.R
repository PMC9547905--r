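# Independent brute-force oracles used across the suite.

# LP maximum by vertex enumeration: every basic solution of
# { S v = b, lb <= v <= ub } fixes (n - rank(S)) variables at a bound and
# solves for the rest.
oracle_lp_max <- function(cc, S, b, lb, ub) {
  n <- length(cc)
  k <- n - qr(S)$rank
  best <- -Inf
  fixsets <- if (k > 0) combn(n, k, simplify = FALSE) else list(integer(0))
  for (fix in fixsets) {
    free <- setdiff(seq_len(n), fix)
    grid <- if (k > 0) {
      expand.grid(rep(list(c(FALSE, TRUE)), k))
    } else {
      data.frame(row.names = 1)
    }
    for (g in seq_len(nrow(grid))) {
      x <- numeric(n)
      if (k > 0) {
        at_ub <- unlist(grid[g, ])
        x[fix] <- ifelse(at_ub, ub[fix], lb[fix])
        if (any(!is.finite(x[fix]))) next
      }
      rhs <- b - if (k > 0) S[, fix, drop = FALSE] %*% x[fix] else 0
      sol <- tryCatch(qr.solve(S[, free, drop = FALSE], rhs),
                      error = function(e) NULL)
      if (is.null(sol)) next
      x[free] <- sol
      if (max(abs(S %*% x - b)) < 1e-7 &&
          all(x >= lb - 1e-7) && all(x <= ub + 1e-7)) {
        best <- max(best, sum(cc * x))
      }
    }
  }
  best
}

# iMAT agreement optimum by exhaustive enumeration over activity patterns:
# every subset of classified reactions is tried as the satisfied set, with
# every sign combination for satisfied high reactions.
oracle_imat_objective <- function(model, states, epsilon) {
  S <- stoichiometric_matrix(model)
  b <- rep(0, nrow(S))
  rid <- model$reactions$id
  high <- match(states$reaction[states$level == "high"], rid)
  low <- match(states$reaction[states$level == "low"], rid)
  idx <- c(high, low)
  ishigh <- c(rep(TRUE, length(high)), rep(FALSE, length(low)))
  k <- length(idx)
  best <- -1L
  feasible_with <- function(lb, ub) {
    res <- sphingolens:::lp_solve(rep(0, ncol(S)), S, b, lb, ub)
    res$status == "optimal"
  }
  for (mask in 0:(2^k - 1)) {
    sat <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    if (length(sat) <= best) next
    sat_high <- sat[ishigh[sat]]
    sat_low <- sat[!ishigh[sat]]
    nh <- length(sat_high)
    signsets <- if (nh > 0) {
      expand.grid(rep(list(c(1, -1)), nh))
    } else {
      data.frame(row.names = 1)
    }
    for (s in seq_len(nrow(signsets))) {
      lb <- model$reactions$lb
      ub <- model$reactions$ub
      ok <- TRUE
      for (t in seq_len(nh)) {
        j <- idx[sat_high[t]]
        if (signsets[s, t] > 0) {
          if (ub[j] < epsilon) { ok <- FALSE; break }
          lb[j] <- max(lb[j], epsilon)
        } else {
          if (lb[j] > -epsilon) { ok <- FALSE; break }
          ub[j] <- min(ub[j], -epsilon)
        }
      }
      if (!ok) next
      for (t in sat_low) {
        j <- idx[t]
        if (lb[j] > 0 || ub[j] < 0) { ok <- FALSE; break }
        lb[j] <- 0; ub[j] <- 0
      }
      if (!ok) next
      if (feasible_with(lb, ub)) {
        best <- max(best, length(sat))
        break
      }
    }
  }
  best
}

# Exact HWE p by direct enumeration of the conditional distribution over
# heterozygote counts, computed with plain factorials (small counts only).
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_A <- 2 * n_AA + n_Aa
  n_a <- 2 * n_aa + n_Aa
  rare <- min(n_A, n_a)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  prob <- sapply(hets, function(h) {
    n_rr <- (rare - h) / 2
    n_cc <- n - n_rr - h
    (factorial(n) / (factorial(n_rr) * factorial(h) * factorial(n_cc))) *
      2^h * factorial(n_A) * factorial(n_a) / factorial(2 * n)
  })
  prob <- prob / sum(prob)
  obs <- prob[hets == n_Aa]
  min(1, sum(prob[prob <= obs * (1 + 1e-9)]))
}

# Mann-Whitney U by counting pairs.
oracle_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Benjamini-Hochberg by the textbook step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# small random loop-free flux models for LP/iMAT oracle comparisons
random_toy_model <- function(n_internal = 4, seed = 1) {
  set.seed(seed)
  # linear chain with random branches off each internal metabolite
  mets <- paste0("M", seq_len(n_internal))
  rxns <- list()
  add <- function(id, st, rev = FALSE, ub = 10, pseudo = FALSE) {
    rxns[[length(rxns) + 1]] <<- list(id = id, st = st, rev = rev,
                                      ub = ub, pseudo = pseudo)
  }
  add("SRC", setNames(1, "M1"), ub = stats::runif(1, 5, 10), pseudo = TRUE)
  for (i in seq_len(n_internal - 1)) {
    add(paste0("R", i), setNames(c(-1, 1), mets[c(i, i + 1)]),
        rev = stats::runif(1) < 0.3, ub = stats::runif(1, 3, 10))
  }
  # one random shortcut branch
  if (n_internal >= 3 && stats::runif(1) < 0.7) {
    ft <- sort(sample(n_internal, 2))
    add("RB", setNames(c(-1, 1), mets[ft]), ub = stats::runif(1, 1, 6))
  }
  add("SNK", setNames(-1, mets[n_internal]), ub = 1000, pseudo = TRUE)
  reactions <- do.call(rbind, lapply(rxns, function(r) {
    data.frame(id = r$id, label = NA_character_, reversible = r$rev,
               lb = if (r$rev) -r$ub else 0, ub = r$ub,
               gene_rule = NA_character_, pseudo = r$pseudo,
               stringsAsFactors = FALSE)
  }))
  st <- lapply(rxns, `[[`, "st")
  names(st) <- reactions$id
  pathway_model(
    data.frame(id = mets, name = mets, compartment = "c"),
    reactions, st, data.frame(rxn = "SNK", weight = 1))
}
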