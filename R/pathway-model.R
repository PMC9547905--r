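#' Construct a pathway model
#'
#' A `pathway_model` is a small constraint-based metabolic model: a set of
#' metabolites, a set of reactions with signed stoichiometry, flux bounds and
#' optional GPR rules, and a linear objective over reactions. Exchange/demand
#' pseudo-reactions (sources and sinks crossing the system boundary) are
#' flagged with `pseudo = TRUE` and excluded from counts of enzymatic
#' reactions.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions data.frame with columns `id`, `label` (enzyme-step letter
#'   or `NA`), `reversible`, `lb`, `ub`, `gene_rule` (GPR string or `NA`),
#'   `pseudo`.
#' @param stoichiometry named list (by reaction id) of named numeric vectors
#'   (metabolite id -> signed coefficient; negative = consumed).
#' @param objective data.frame with columns `rxn`, `weight`.
#' @return An object of class `pathway_model` with derived element `genes`
#'   (sorted union of gene symbols over all GPR rules).
#' @export
pathway_model <- function(metabolites, reactions, stoichiometry, objective) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$compartment)) metabolites$compartment <- "c"
  metabolites$compartment[is.na(metabolites$compartment)] <- "c"
  if (is.null(reactions$label)) reactions$label <- NA_character_
  if (is.null(reactions$pseudo)) reactions$pseudo <- FALSE
  if (is.null(reactions$gene_rule)) reactions$gene_rule <- NA_character_
  genes <- sort(unique(unlist(lapply(reactions$gene_rule, function(r) {
    tryCatch(gpr_genes(r), error = function(e) {
      stop("invalid gene_rule: ", conditionMessage(e), call. = FALSE)
    })
  }))))
  m <- structure(
    list(metabolites = metabolites, reactions = reactions,
         stoichiometry = stoichiometry, objective = objective,
         genes = genes),
    class = "pathway_model")
  issues <- validate_pathway_model(m)
  if (length(issues)) {
    stop("invalid pathway model:\n  ", paste(issues, collapse = "\n  "),
         call. = FALSE)
  }
  m
}

#' Validate a pathway model
#'
#' Checks referential integrity and bound invariants; used by the constructor
#' and by [load_model()].
#'
#' @param m A `pathway_model` (or untrusted list with the same shape).
#' @return Character vector of violations (empty when valid).
#' @export
validate_pathway_model <- function(m) {
  issues <- character()
  met_ids <- m$metabolites$id
  if (any(!nzchar(met_ids) | is.na(met_ids))) {
    issues <- c(issues, "metabolite with empty id")
  }
  if (anyDuplicated(met_ids)) {
    issues <- c(issues, paste0("duplicated metabolite id: ",
                               paste(unique(met_ids[duplicated(met_ids)]), collapse = ", ")))
  }
  rxn_ids <- m$reactions$id
  if (anyDuplicated(rxn_ids)) {
    issues <- c(issues, paste0("duplicated reaction id: ",
                               paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", ")))
  }
  if (!setequal(names(m$stoichiometry), rxn_ids)) {
    issues <- c(issues, "stoichiometry entries do not match reaction ids")
  }
  for (rid in rxn_ids) {
    st <- m$stoichiometry[[rid]]
    if (is.null(st) || length(st) == 0L) {
      issues <- c(issues, paste0("reaction ", rid, ": empty stoichiometry"))
      next
    }
    dangling <- setdiff(names(st), met_ids)
    if (length(dangling)) {
      issues <- c(issues, paste0("reaction ", rid,
                                 ": references unknown metabolite(s) ",
                                 paste(dangling, collapse = ", ")))
    }
  }
  bad_bounds <- which(m$reactions$lb > m$reactions$ub)
  for (i in bad_bounds) {
    issues <- c(issues, paste0("reaction ", rxn_ids[i], ": lb > ub"))
  }
  bad_irrev <- which(!m$reactions$reversible & m$reactions$lb < 0)
  for (i in bad_irrev) {
    issues <- c(issues, paste0("reaction ", rxn_ids[i],
                               ": irreversible but lower bound < 0"))
  }
  if (!is.null(m$objective) && nrow(m$objective) > 0) {
    unknown <- setdiff(m$objective$rxn, rxn_ids)
    if (length(unknown)) {
      issues <- c(issues, paste0("objective references unknown reaction(s) ",
                                 paste(unknown, collapse = ", ")))
    }
  }
  issues
}

#' @export
print.pathway_model <- function(x, ...) {
  n_enz <- sum(!x$reactions$pseudo)
  cat("pathway_model: ", nrow(x$metabolites), " metabolites, ",
      n_enz, " enzymatic + ", nrow(x$reactions) - n_enz,
      " pseudo reactions, ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Load a pathway model from JSON
#'
#' Reads the documented model schema:
#' `{"metabolites":[{"id","name","compartment"}],`
#' `"reactions":[{"id","label","stoichiometry":{met: coef},"reversible",`
#' `"lb","ub","gene_rule","pseudo"}], "objective":[{"rxn","weight"}]}`.
#' All type invariants are validated; a reaction citing a metabolite absent
#' from the metabolite list is a fatal error naming the reaction.
#'
#' @param path Path to a model JSON file.
#' @return A validated [pathway_model()].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  js <- jsonlite::read_json(path)
  mets <- do.call(rbind, lapply(js$metabolites, function(x) {
    data.frame(id = x$id, name = x$name %||% x$id,
               compartment = x$compartment %||% "c",
               stringsAsFactors = FALSE)
  }))
  rxns <- do.call(rbind, lapply(js$reactions, function(x) {
    data.frame(id = x$id, label = x$label %||% NA_character_,
               reversible = isTRUE(x$reversible),
               lb = as.numeric(x$lb %||% if (isTRUE(x$reversible)) -1000 else 0),
               ub = as.numeric(x$ub %||% 1000),
               gene_rule = x$gene_rule %||% NA_character_,
               pseudo = isTRUE(x$pseudo),
               stringsAsFactors = FALSE)
  }))
  stoich <- lapply(js$reactions, function(x) {
    v <- unlist(x$stoichiometry)
    if (is.null(v)) stop("reaction ", x$id, ": empty stoichiometry",
                         call. = FALSE)
    v
  })
  names(stoich) <- rxns$id
  obj <- if (length(js$objective)) {
    do.call(rbind, lapply(js$objective, function(x) {
      data.frame(rxn = x$rxn, weight = as.numeric(x$weight %||% 1),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(rxn = character(), weight = numeric())
  }
  pathway_model(mets, rxns, stoich, obj)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a pathway model to JSON
#'
#' Inverse of [load_model()]: `load_model(save_model(m, f))` reproduces `m`
#' (modulo JSON key ordering).
#'
#' @param m A `pathway_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(m, path) {
  js <- list(
    metabolites = lapply(seq_len(nrow(m$metabolites)), function(i) {
      as.list(m$metabolites[i, c("id", "name", "compartment")])
    }),
    reactions = lapply(seq_len(nrow(m$reactions)), function(i) {
      r <- m$reactions[i, ]
      out <- list(id = r$id, stoichiometry = as.list(m$stoichiometry[[r$id]]),
                  reversible = r$reversible, lb = r$lb, ub = r$ub,
                  pseudo = r$pseudo)
      if (!is.na(r$label)) out$label <- r$label
      if (!is.na(r$gene_rule)) out$gene_rule <- r$gene_rule
      out
    }),
    objective = lapply(seq_len(nrow(m$objective)), function(i) {
      as.list(m$objective[i, c("rxn", "weight")])
    })
  )
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Stoichiometric matrix of a model
#'
#' @param m A `pathway_model`.
#' @return Dense numeric matrix S, one row per metabolite and one column per
#'   reaction (dimnames set); entry (i, j) is the signed coefficient of
#'   metabolite i in reaction j.
#' @export
stoichiometric_matrix <- function(m) {
  S <- matrix(0, nrow(m$metabolites), nrow(m$reactions),
              dimnames = list(m$metabolites$id, m$reactions$id))
  for (rid in m$reactions$id) {
    st <- m$stoichiometry[[rid]]
    S[names(st), rid] <- st
  }
  S
}

#' Reactions reachable from a set of seed metabolites
#'
#' Simple forward closure on the reaction digraph: a reaction fires when all
#' of its substrates are available, making its products available. Used to
#' assert that every exit route of the curated pathway is reachable from the
#' serine + palmitoyl-CoA entry.
#'
#' @param m A `pathway_model`.
#' @param seeds Character vector of initially available metabolite ids.
#' @return List with `metabolites` and `reactions` reachable.
#' @export
reachable_from <- function(m, seeds) {
  avail <- unique(seeds)
  fired <- character()
  repeat {
    progress <- FALSE
    for (rid in setdiff(m$reactions$id, fired)) {
      st <- m$stoichiometry[[rid]]
      subs <- names(st)[st < 0]
      prods <- names(st)[st > 0]
      ok_fwd <- length(subs) == 0L || all(subs %in% avail)
      rev_ok <- m$reactions$reversible[m$reactions$id == rid] &&
        (length(prods) == 0L || all(prods %in% avail))
      if (ok_fwd || rev_ok) {
        fired <- c(fired, rid)
        newmets <- if (ok_fwd) prods else subs
        if (length(setdiff(newmets, avail))) progress <- TRUE
        avail <- union(avail, newmets)
        progress <- TRUE
      }
    }
    if (!progress) break
  }
  list(metabolites = avail, reactions = fired)
}
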