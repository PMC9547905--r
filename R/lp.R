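# Dense bounded-variable two-phase simplex.
#
# Solves  max/min c'x  s.t.  A x = b,  lb <= x <= ub  (bounds may be +-Inf).
# Written for the small dense LPs arising from curated pathway models
# (tens of variables); uses Bland's rule throughout, so it cannot cycle,
# and refactorizes the basis at every iteration for numerical safety.

lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE, tol = 1e-9,
                     max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n,
            length(b) == m)
  if (any(lb > ub)) return(list(status = "infeasible", value = NA_real_,
                                x = rep(NA_real_, n)))
  cvec <- if (maximize) as.numeric(obj) else -as.numeric(obj)

  # augment with one artificial per row
  Af <- cbind(A, diag(1, m))
  nt <- n + m
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(Inf, m))

  # initial nonbasic placement for structural variables
  stat <- character(nt)
  xval <- numeric(nt)
  for (j in seq_len(n)) {
    if (is.finite(lb[j])) {
      stat[j] <- "L"; xval[j] <- lb[j]
    } else if (is.finite(ub[j])) {
      stat[j] <- "U"; xval[j] <- ub[j]
    } else {
      stat[j] <- "F"; xval[j] <- 0
    }
  }
  resid <- b - A %*% xval[seq_len(n)]
  sgn <- ifelse(resid >= 0, 1, -1)
  Af[, n + seq_len(m)] <- diag(as.numeric(sgn), m)
  basis <- n + seq_len(m)
  stat[basis] <- "B"
  xval[basis] <- abs(resid)

  run_phase <- function(cost, basis, stat, xval, max_iter) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) {
        return(list(status = "maxiter", basis = basis, stat = stat,
                    xval = xval))
      }
      B <- Af[, basis, drop = FALSE]
      nb <- which(stat != "B")
      rhs <- b - Af[, nb, drop = FALSE] %*% xval[nb]
      xB <- tryCatch(solve(B, rhs), error = function(e) NULL)
      if (is.null(xB)) {
        return(list(status = "singular", basis = basis, stat = stat,
                    xval = xval))
      }
      xval[basis] <- as.numeric(xB)
      y <- tryCatch(solve(t(B), cost[basis]), error = function(e) NULL)
      if (is.null(y)) {
        return(list(status = "singular", basis = basis, stat = stat,
                    xval = xval))
      }
      d <- cost - as.numeric(t(Af) %*% y)
      enter <- NA_integer_
      for (j in nb) {       # Bland: smallest eligible index
        if (ubf[j] - lbf[j] < tol) next   # fixed variable
        if ((stat[j] == "L" && d[j] > tol) ||
            (stat[j] == "U" && d[j] < -tol) ||
            (stat[j] == "F" && abs(d[j]) > tol)) {
          enter <- j; break
        }
      }
      if (is.na(enter)) {
        return(list(status = "optimal", basis = basis, stat = stat,
                    xval = xval))
      }
      dir <- if (stat[enter] == "U" || (stat[enter] == "F" && d[enter] < 0)) -1 else 1
      w <- as.numeric(solve(B, Af[, enter]))
      # step limits
      t_own <- ubf[enter] - lbf[enter]     # bound-flip limit (Inf if free range)
      t_best <- t_own
      leave <- NA_integer_
      leave_to <- NA_character_
      for (i in seq_len(m)) {
        delta <- -dir * w[i]               # change of basic i per unit step
        bi <- basis[i]
        if (delta > tol) {
          lim <- (ubf[bi] - xval[bi]) / delta
          to <- "U"
        } else if (delta < -tol) {
          lim <- (lbf[bi] - xval[bi]) / delta
          to <- "L"
        } else next
        if (!is.finite(lim)) next
        lim <- max(lim, 0)
        if (lim < t_best - tol) {
          t_best <- lim; leave <- i; leave_to <- to
        } else if (lim <= t_best + tol && !is.na(leave) &&
                   bi < basis[leave]) {
          # Bland tie-break on leaving variable index
          t_best <- min(t_best, lim); leave <- i; leave_to <- to
        }
      }
      if (!is.finite(t_best)) {
        return(list(status = "unbounded", basis = basis, stat = stat,
                    xval = xval))
      }
      t_best <- max(t_best, 0)
      # apply step
      xval[basis] <- xval[basis] - dir * w * t_best
      xval[enter] <- xval[enter] + dir * t_best
      if (is.na(leave)) {
        # bound flip: entering moves to its opposite bound
        stat[enter] <- if (dir > 0) "U" else "L"
        xval[enter] <- if (dir > 0) ubf[enter] else lbf[enter]
      } else {
        out <- basis[leave]
        stat[out] <- leave_to
        xval[out] <- if (leave_to == "U") ubf[out] else lbf[out]
        stat[enter] <- "B"
        basis[leave] <- enter
      }
    }
  }

  # phase 1: drive artificials to zero
  c1 <- c(rep(0, n), rep(-1, m))
  ph1 <- run_phase(c1, basis, stat, xval, max_iter)
  if (ph1$status %in% c("maxiter", "singular")) {
    return(list(status = ph1$status, value = NA_real_, x = rep(NA_real_, n)))
  }
  art_sum <- sum(ph1$xval[n + seq_len(m)])
  if (art_sum > 1e-7) {
    return(list(status = "infeasible", value = NA_real_,
                x = rep(NA_real_, n)))
  }
  # phase 2: pin artificials at zero and optimize the true objective
  ubf <- c(ub, rep(0, m))
  lbf <- c(lb, rep(0, m))
  ph1$xval[n + seq_len(m)] <- pmin(pmax(ph1$xval[n + seq_len(m)], 0), 0)
  c2 <- c(cvec, rep(0, m))
  ph2 <- run_phase(c2, ph1$basis, ph1$stat, ph1$xval, max_iter)
  if (ph2$status %in% c("maxiter", "singular")) {
    return(list(status = ph2$status, value = NA_real_, x = rep(NA_real_, n)))
  }
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", value = if (maximize) Inf else -Inf,
                x = rep(NA_real_, n)))
  }
  x <- ph2$xval[seq_len(n)]
  x <- pmin(pmax(x, lb), ub)   # clamp tiny numerical overshoot
  list(status = "optimal", value = sum(obj * x), x = x)
}

# Feasibility of { A x = b, lb <= x <= ub } (phase-1 only).
lp_feasible <- function(A, b, lb, ub) {
  res <- lp_solve(rep(0, ncol(A)), A, b, lb, ub, maximize = TRUE)
  res$status == "optimal"
}

#' Flux balance analysis
#'
#' Maximizes a linear objective over the steady-state flux polytope
#' `S v = 0`, `lb <= v <= ub`.
#'
#' @param model A [pathway_model()].
#' @param objective Objective specification: `NULL` to use the model's own
#'   objective, a reaction id (maximize that flux), or a named numeric vector
#'   of reaction weights.
#' @return List with `objective_value` (the maximum) and `fluxes`, a named
#'   numeric vector giving one optimal flux distribution.
#' @seealso [fva()]
#' @export
fba <- function(model, objective = NULL) {
  S <- stoichiometric_matrix(model)
  cv <- fba_objective_vector(model, objective)
  res <- lp_solve(cv, S, rep(0, nrow(S)), model$reactions$lb,
                  model$reactions$ub, maximize = TRUE)
  if (res$status == "infeasible") {
    stop("FBA: model is infeasible (no steady-state flux distribution ",
         "within bounds)", call. = FALSE)
  }
  if (res$status == "unbounded") {
    stop("FBA: objective is unbounded (check reaction bounds)",
         call. = FALSE)
  }
  if (res$status != "optimal") {
    stop("FBA: LP solve failed with status '", res$status, "'",
         call. = FALSE)
  }
  fl <- res$x
  names(fl) <- model$reactions$id
  list(objective_value = res$value, fluxes = fl)
}

fba_objective_vector <- function(model, objective) {
  rid <- model$reactions$id
  cv <- setNames(rep(0, length(rid)), rid)
  if (is.null(objective)) {
    if (is.null(model$objective) || nrow(model$objective) == 0) {
      stop("model has no objective; supply one", call. = FALSE)
    }
    cv[model$objective$rxn] <- model$objective$weight
  } else if (is.character(objective)) {
    missing_rxn <- setdiff(objective, rid)
    if (length(missing_rxn)) {
      stop("objective reaction(s) not in model: ",
           paste(missing_rxn, collapse = ", "), call. = FALSE)
    }
    cv[objective] <- 1
  } else {
    missing_rxn <- setdiff(names(objective), rid)
    if (length(missing_rxn)) {
      stop("objective reaction(s) not in model: ",
           paste(missing_rxn, collapse = ", "), call. = FALSE)
    }
    cv[names(objective)] <- as.numeric(objective)
  }
  as.numeric(cv)
}

#' Flux variability analysis
#'
#' For each reaction, the minimum and maximum flux attainable while the
#' objective is held at at least `objective_fraction` times its optimum.
#'
#' @param model A [pathway_model()].
#' @param objective_fraction Fraction of the FBA optimum to enforce, in
#'   `[0, 1]`. Default 1 (optimum held exactly at its maximum).
#' @param objective As in [fba()].
#' @param reactions Optional character vector restricting the reactions
#'   analyzed (default: all).
#' @return data.frame with columns `reaction`, `v_min`, `v_max`; attribute
#'   `objective_value` carries the FBA optimum.
#' @export
fva <- function(model, objective_fraction = 1, objective = NULL,
                reactions = NULL) {
  stopifnot(objective_fraction >= 0, objective_fraction <= 1)
  opt <- fba(model, objective)
  S <- stoichiometric_matrix(model)
  cv <- fba_objective_vector(model, objective)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  # append objective row with a surplus variable: c'v - s = f * opt, s >= 0
  A <- rbind(cbind(S, 0), c(cv, -1))
  b <- c(rep(0, nrow(S)), objective_fraction * opt$objective_value)
  lbx <- c(lb, 0)
  ubx <- c(ub, Inf)
  rid <- model$reactions$id
  targets <- if (is.null(reactions)) rid else intersect(rid, reactions)
  n <- length(lbx)
  out <- lapply(targets, function(r) {
    e <- as.numeric(rid == r)
    e <- c(e, 0)
    hi <- lp_solve(e, A, b, lbx, ubx, maximize = TRUE)
    lo <- lp_solve(e, A, b, lbx, ubx, maximize = FALSE)
    if (hi$status != "optimal" || lo$status != "optimal") {
      stop("FVA failed for reaction ", r, " (status ", hi$status, "/",
           lo$status, ")", call. = FALSE)
    }
    data.frame(reaction = r, v_min = lo$value, v_max = hi$value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "objective_value") <- opt$objective_value
  res
}
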