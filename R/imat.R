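#' Discretize reaction expression into high/moderate/low states
#'
#' Maps a sample's gene expression onto reactions through the GPR rules
#' ([evaluate_gpr()]), then classifies each gene-associated reaction by its
#' rank within the sample: reaction expression strictly below the `q_low`
#' sample quantile is `low`, strictly above the `q_high` quantile is `high`,
#' anything else (including all-equal expression) is `moderate`. Reactions
#' with no measured gene, and pseudo-reactions, are `unknown`.
#'
#' @param profile Named numeric vector of gene expression for one sample
#'   (gene symbol -> non-negative value).
#' @param model A [pathway_model()].
#' @param q_low,q_high Quantile cutoffs, `0 <= q_low < q_high <= 1`.
#'   Defaults 0.25 / 0.75.
#' @return data.frame with columns `reaction`, `expression`, `level`
#'   (`"high"`, `"moderate"`, `"low"`, `"unknown"`).
#' @export
discretize_expression <- function(profile, model, q_low = 0.25,
                                  q_high = 0.75) {
  stopifnot(q_low >= 0, q_high <= 1, q_low < q_high)
  rxns <- model$reactions
  expr_vals <- vapply(seq_len(nrow(rxns)), function(i) {
    if (rxns$pseudo[i] || is.na(rxns$gene_rule[i])) return(NA_real_)
    as.numeric(evaluate_gpr(rxns$gene_rule[i], profile))
  }, numeric(1))
  level <- rep("unknown", nrow(rxns))
  meas <- which(!is.na(expr_vals))
  if (length(meas)) {
    lo_cut <- stats::quantile(expr_vals[meas], q_low, names = FALSE)
    hi_cut <- stats::quantile(expr_vals[meas], q_high, names = FALSE)
    level[meas] <- "moderate"
    level[meas][expr_vals[meas] < lo_cut] <- "low"
    level[meas][expr_vals[meas] > hi_cut] <- "high"
  }
  data.frame(reaction = rxns$id, expression = expr_vals, level = level,
             stringsAsFactors = FALSE)
}

#' Extract a context-specific model from expression states (iMAT-style)
#'
#' Finds a steady-state flux pattern maximizing agreement with tri-level
#' expression evidence: the score is the number of `high` reactions carrying
#' flux of magnitude at least `epsilon` plus the number of `low` reactions
#' carrying zero flux. The discrete optimum is found by branch-and-bound over
#' per-reaction activity indicators with LP feasibility pruning, which solves
#' the same mixed-integer program as the classic formulation exactly.
#'
#' The returned context model closes (`lb = ub = 0`) every `low` reaction
#' assigned inactive in the optimal pattern; other reactions keep their
#' original bounds.
#'
#' @param model A [pathway_model()].
#' @param states data.frame from [discretize_expression()].
#' @param epsilon Minimum activation flux for `high` reactions (default 1).
#' @return List with elements `model` (context model), `activity` (named
#'   character vector over classified reactions: `"active_forward"`,
#'   `"active_reverse"`, `"inactive"`, or `"unsatisfied"`), and `objective`
#'   (the optimal agreement score).
#' @export
extract_context_model <- function(model, states, epsilon = 1) {
  stopifnot(epsilon > 0)
  S <- stoichiometric_matrix(model)
  b0 <- rep(0, nrow(S))
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  rid <- model$reactions$id
  high <- states$reaction[states$level == "high"]
  low <- states$reaction[states$level == "low"]
  hi_idx <- match(high, rid)
  lo_idx <- match(low, rid)
  if (length(hi_idx)) {
    can_activate <- ub[hi_idx] >= epsilon | lb[hi_idx] <= -epsilon
    if (!any(can_activate)) {
      stop("epsilon = ", epsilon, " exceeds the attainable flux of every ",
           "high-expression reaction; no activation is feasible",
           call. = FALSE)
    }
  }
  classified <- c(hi_idx, lo_idx)
  is_high <- c(rep(TRUE, length(hi_idx)), rep(FALSE, length(lo_idx)))
  k <- length(classified)
  best <- list(score = -1L, assign = NULL)
  # depth-first branch and bound; satisfied options explored first so the
  # incumbent rises quickly, bound = score so far + reactions left undecided
  recurse <- function(pos, lb_cur, ub_cur, score, assign) {
    if (score + (k - pos + 1L) <= best$score) return(invisible())
    if (pos > k) {
      if (score > best$score) best <<- list(score = score, assign = assign)
      return(invisible())
    }
    j <- classified[pos]
    if (is_high[pos]) {
      # forward activation
      if (ub_cur[j] >= epsilon) {
        lb2 <- lb_cur; lb2[j] <- max(lb2[j], epsilon)
        if (lp_feasible(S, b0, lb2, ub_cur)) {
          recurse(pos + 1L, lb2, ub_cur, score + 1L,
                  c(assign, setNames("active_forward", rid[j])))
        }
      }
      # reverse activation
      if (lb_cur[j] <= -epsilon) {
        ub2 <- ub_cur; ub2[j] <- min(ub2[j], -epsilon)
        if (lp_feasible(S, b0, lb_cur, ub2)) {
          recurse(pos + 1L, lb_cur, ub2, score + 1L,
                  c(assign, setNames("active_reverse", rid[j])))
        }
      }
      recurse(pos + 1L, lb_cur, ub_cur, score,
              c(assign, setNames("unsatisfied", rid[j])))
    } else {
      if (lb_cur[j] <= 0 && ub_cur[j] >= 0) {
        lb2 <- lb_cur; ub2 <- ub_cur
        lb2[j] <- 0; ub2[j] <- 0
        if (lp_feasible(S, b0, lb2, ub2)) {
          recurse(pos + 1L, lb2, ub2, score + 1L,
                  c(assign, setNames("inactive", rid[j])))
        }
      }
      recurse(pos + 1L, lb_cur, ub_cur, score,
              c(assign, setNames("unsatisfied", rid[j])))
    }
  }
  if (k == 0L) {
    best <- list(score = 0L, assign = setNames(character(), character()))
  } else {
    if (!lp_feasible(S, b0, lb, ub)) {
      stop("model is infeasible before context extraction", call. = FALSE)
    }
    recurse(1L, lb, ub, 0L, setNames(character(), character()))
  }
  ctx <- model
  closed <- names(best$assign)[best$assign == "inactive"]
  ci <- match(closed, rid)
  ctx$reactions$lb[ci] <- 0
  ctx$reactions$ub[ci] <- 0
  list(model = ctx, activity = best$assign, objective = best$score)
}
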