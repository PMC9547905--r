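#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are infix boolean expressions over gene symbols, e.g.
#' `"(SPTLC1 and SPTLC2) or (SPTLC1 and SPTLC3)"`. `and` binds tighter than
#' `or`; parentheses group. Operator keywords are case-insensitive; gene
#' symbols may contain letters, digits, `_`, `.` and `-`.
#'
#' @param rule Character scalar. The empty string or `NA` yields `NULL`
#'   (reaction not gene-associated, e.g. exchange pseudo-reactions).
#' @return A parse tree: either a gene symbol (character scalar) or a list
#'   with elements `op` (`"and"`/`"or"`) and `args` (list of subtrees).
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0L || is.na(rule) || !nzchar(trimws(rule))) {
    return(NULL)
  }
  toks <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("GPR parse error in rule '", rule, "': unexpected token '",
         st$toks[st$pos], "'", call. = FALSE)
  }
  tree
}

gpr_tokenize <- function(rule) {
  pat <- "\\(|\\)|[A-Za-z0-9_.:-]+"
  m <- gregexpr(pat, rule)[[1]]
  toks <- regmatches(rule, list(m))[[1]]
  # anything not matched must be whitespace
  residue <- gsub(pat, "", rule)
  if (grepl("[^[:space:]]", residue)) {
    bad <- regmatches(residue, regexpr("[^[:space:]]+", residue))
    stop("GPR parse error: illegal character(s) '", bad, "' in rule '",
         rule, "'", call. = FALSE)
  }
  toks
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.na(tk)) stop("GPR parse error: unexpected end of rule", call. = FALSE)
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (!identical(gpr_peek(st), ")")) {
      stop("GPR parse error: missing ')'", call. = FALSE)
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or")) {
    stop("GPR parse error: unexpected token '", tk, "'", call. = FALSE)
  }
  st$pos <- st$pos + 1L
  tk
}

#' Genes referenced by a GPR rule
#' @param rule GPR rule string (or parse tree).
#' @return Character vector of distinct gene symbols (empty for `NULL` rules).
#' @export
gpr_genes <- function(rule) {
  tree <- if (is.list(rule)) rule else parse_gpr(as.character(rule))
  if (is.null(tree)) return(character())
  walk <- function(nd) {
    if (is.character(nd)) return(nd)
    unlist(lapply(nd$args, walk))
  }
  unique(walk(tree))
}

#' Evaluate a GPR rule against a gene expression map
#'
#' Maps boolean structure to numbers the way expression-integration methods
#' expect: `and` (enzyme complex) takes the minimum of its operands, `or`
#' (isozymes) the maximum. A gene absent from `expr` is treated as a missing
#' operand and dropped from its operator; a node whose operands are all
#' missing propagates `NA`. A rule none of whose genes are measured evaluates
#' to `NA` (reaction expression unknown).
#'
#' @param rule GPR rule string or parse tree from [parse_gpr()].
#' @param expr Named numeric vector (or list), gene symbol -> expression value.
#' @return Numeric scalar reaction expression, or `NA_real_` when no gene in
#'   the rule is measured. The return carries attribute `n_missing`, the count
#'   of rule genes absent from `expr`.
#' @examples
#' evaluate_gpr("SPTLC1 and SPTLC2", c(SPTLC1 = 5, SPTLC2 = 2)) # 2
#' evaluate_gpr("SGMS1 or SGMS2", c(SGMS1 = 1, SGMS2 = 7))      # 7
#' @export
evaluate_gpr <- function(rule, expr) {
  tree <- if (is.list(rule)) rule else parse_gpr(as.character(rule))
  if (is.null(tree)) return(structure(NA_real_, n_missing = 0L))
  expr <- unlist(expr)
  genes <- gpr_genes(tree)
  n_missing <- sum(!genes %in% names(expr))
  eval_node <- function(nd) {
    if (is.character(nd)) {
      if (nd %in% names(expr)) return(as.numeric(expr[[nd]]))
      return(NA_real_)
    }
    vals <- vapply(nd$args, eval_node, numeric(1))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) return(NA_real_)
    if (nd$op == "and") min(vals) else max(vals)
  }
  structure(eval_node(tree), n_missing = as.integer(n_missing))
}
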