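gene_chain <- function(n = 4, ub = 1000) {
  # linear chain M1 -> ... -> Mn with one gene per internal reaction
  mets <- paste0("M", seq_len(n))
  ids <- c("SRC", paste0("R", seq_len(n - 1)), "SNK")
  st <- c(list(setNames(1, "M1")),
          lapply(seq_len(n - 1), function(i) {
            setNames(c(-1, 1), mets[c(i, i + 1)])
          }),
          list(setNames(-1, mets[n])))
  names(st) <- ids
  pathway_model(
    data.frame(id = mets, name = mets, compartment = "c"),
    data.frame(id = ids, label = NA_character_, reversible = FALSE, lb = 0,
               ub = ub, gene_rule = c(NA, paste0("G", seq_len(n - 1)), NA),
               pseudo = c(TRUE, rep(FALSE, n - 1), TRUE)),
    st, data.frame(rxn = "SNK", weight = 1))
}

states_for <- function(model, levels) {
  data.frame(reaction = names(levels), expression = NA_real_,
             level = unname(levels), stringsAsFactors = FALSE)
}

test_that("discretization tags sample-wise expression tails", {
  m <- gene_chain(5)
  prof <- c(G1 = 1, G2 = 2, G3 = 3, G4 = 4)
  st <- discretize_expression(prof, m, 0.25, 0.75)
  st <- st[!is.na(st$expression), ]
  expect_identical(st$level[st$reaction == "R1"], "low")
  expect_identical(st$level[st$reaction == "R4"], "high")
  expect_identical(st$level[st$reaction %in% c("R2", "R3")],
                   c("moderate", "moderate"))
  # constant expression: everything moderate
  st2 <- discretize_expression(c(G1 = 2, G2 = 2, G3 = 2, G4 = 2), m)
  expect_true(all(st2$level[!is.na(st2$expression)] == "moderate"))
  # empty tails
  st3 <- discretize_expression(prof, m, 0, 1)
  expect_true(all(st3$level[!is.na(st3$expression)] == "moderate"))
  # pseudo-reactions stay unknown
  expect_identical(unique(st2$level[st2$reaction %in% c("SRC", "SNK")]),
                   "unknown")
})

test_that("an all-high feasible chain activates everything", {
  m <- gene_chain(4)
  st <- states_for(m, c(R1 = "high", R2 = "high", R3 = "high"))
  res <- extract_context_model(m, st, epsilon = 1)
  expect_identical(res$objective, 3L)
  expect_true(all(res$activity == "active_forward"))
})

test_that("an essential reaction marked low stays open", {
  m <- gene_chain(4)
  st <- states_for(m, c(R1 = "high", R2 = "low", R3 = "high"))
  res <- extract_context_model(m, st, epsilon = 1)
  # R2 cannot be closed while R1 and R3 carry flux: best satisfies 2 of 3
  expect_identical(res$objective,
                   oracle_imat_objective(m, st, 1))
  expect_identical(res$objective, 2L)
  expect_identical(unname(res$activity["R2"]), "unsatisfied")
  expect_equal(res$model$reactions$ub, m$reactions$ub)  # nothing closed
})

test_that("a low parallel branch is closed while the high one carries flux", {
  m <- pathway_model(
    data.frame(id = c("A", "B"), name = c("A", "B"), compartment = "c"),
    data.frame(id = c("SRC", "HI", "LO", "SNK"), label = NA_character_,
               reversible = FALSE, lb = 0, ub = c(10, 1000, 1000, 1000),
               gene_rule = c(NA, "G1", "G2", NA),
               pseudo = c(TRUE, FALSE, FALSE, TRUE)),
    list(SRC = c(A = 1), HI = c(A = -1, B = 1), LO = c(A = -1, B = 1),
         SNK = c(B = -1)),
    data.frame(rxn = "SNK", weight = 1))
  st <- states_for(m, c(HI = "high", LO = "low"))
  res <- extract_context_model(m, st, epsilon = 1)
  expect_identical(res$objective, 2L)
  expect_identical(unname(res$activity[c("HI", "LO")]),
                   c("active_forward", "inactive"))
  expect_equal(res$model$reactions$ub[res$model$reactions$id == "LO"], 0)
  fv <- fva(res$model, objective_fraction = 1)
  expect_equal(fv$v_max[fv$reaction == "LO"], 0, tolerance = 1e-9)
  expect_gte(fv$v_min[fv$reaction == "HI"], 1)
})

test_that("an unreachable activation threshold is reported", {
  m <- gene_chain(3, ub = 0.5)
  st <- states_for(m, c(R1 = "high", R2 = "high"))
  expect_error(extract_context_model(m, st, epsilon = 1),
               "epsilon.*exceeds")
})

test_that("branch-and-bound matches exhaustive enumeration on random instances", {
  set.seed(99)
  n_checked <- 0
  for (seed in 1:40) {
    m <- random_toy_model(n_internal = sample(3:5, 1), seed = seed)
    rid <- m$reactions$id[!m$reactions$pseudo]
    k <- length(rid)
    lv <- sample(c("high", "low", "moderate"), k, replace = TRUE)
    keep <- lv != "moderate"
    if (!any(keep)) next
    st <- data.frame(reaction = rid[keep], expression = NA_real_,
                     level = lv[keep], stringsAsFactors = FALSE)
    eps <- 0.5
    got <- tryCatch(extract_context_model(m, st, epsilon = eps),
                    error = function(e) e)
    if (inherits(got, "error")) {
      # only legitimate when no high reaction can reach epsilon
      hi <- match(st$reaction[st$level == "high"], m$reactions$id)
      expect_true(length(hi) > 0 &&
                    all(m$reactions$ub[hi] < eps & m$reactions$lb[hi] > -eps))
      next
    }
    want <- oracle_imat_objective(m, st, eps)
    expect_identical(got$objective, as.integer(want),
                     label = paste("seed", seed))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 25)
})
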