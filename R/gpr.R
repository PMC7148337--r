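# Gene-protein-reaction (GPR) rules: Boolean AND/OR trees over gene ids.
#
# A rule is a nested list. Node types:
#   list(type = "empty")                    no gene association
#   list(type = "leaf",  gene = <chr>)      a single gene
#   list(type = "false", gene = <chr>)      marker for a reference gene with
#                                           no orthologue (always FALSE);
#                                           `gene` records the source id
#   list(type = "and"|"or", children = <list of nodes>)
# AND/OR nodes always have >= 2 children; duplicate children are collapsed
# (Boolean idempotence) and single-child nodes are unwrapped, giving a
# canonical form up to child ordering.

gpr_empty <- function() structure(list(type = "empty"), class = "gpr")

gpr_leaf <- function(gene) {
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene))
  structure(list(type = "leaf", gene = gene), class = "gpr")
}

gpr_false <- function(gene) structure(list(type = "false", gene = gene), class = "gpr")

# canonical sort key: child order does not affect it
gpr_key <- function(rule) {
  switch(rule$type,
    empty = "0",
    leaf  = paste0("g:", rule$gene),
    false = paste0("f:", rule$gene),
    paste0(rule$type, "(",
           paste(sort(vapply(rule$children, gpr_key, "")), collapse = ","),
           ")"))
}

gpr_node <- function(type, children) {
  flat <- list()
  for (ch in children) {
    if (ch$type == type) flat <- c(flat, ch$children) else flat <- c(flat, list(ch))
  }
  keys <- vapply(flat, gpr_key, "")
  flat <- flat[!duplicated(keys)]
  if (length(flat) == 1L) return(structure(flat[[1L]], class = "gpr"))
  structure(list(type = type, children = flat), class = "gpr")
}

gpr_and <- function(...) gpr_node("and", list(...))
gpr_or  <- function(...) gpr_node("or", list(...))

#' Parse a GPR rule string
#'
#' Parses the infix `"and"`/`"or"` notation used in SBML-FBC and COBRA-style
#' model files (e.g. `"(g1 and g2) or g3"`) into a canonical Boolean tree.
#' Keywords are case-insensitive, whitespace is ignored and `and` binds
#' tighter than `or`. The empty string (or `NA`) yields the empty rule,
#' meaning the reaction has no gene association.
#'
#' @param text a single GPR string.
#' @return an object of class `"gpr"`.
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' parse_gpr("")
#' @export
parse_gpr <- function(text) {
  if (length(text) == 0L || is.na(text) || !nzchar(trimws(text))) return(gpr_empty())
  stopifnot(is.character(text), length(text) == 1L)

  m <- gregexpr("\\(|\\)|[^()[:space:]]+", text)[[1L]]
  toks <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1L]]
  pos <- as.integer(m)
  i <- 1L
  n <- length(toks)

  peek <- function() if (i <= n) toks[i] else NA_character_
  is_kw <- function(tk, kw) !is.na(tk) && tolower(tk) == kw
  bad <- function(msg, at) {
    stop(sprintf("GPR parse error at position %d: %s (in %s)",
                 at, msg, deparse(substr(text, 1, 60))), call. = FALSE)
  }

  parse_atom <- function() {
    tk <- peek()
    at <- if (i <= n) pos[i] else nchar(text) + 1L
    if (is.na(tk)) bad("expected gene or '('", at)
    if (tk == "(") {
      i <<- i + 1L
      e <- parse_or()
      if (!identical(peek(), ")")) bad("unbalanced parentheses: expected ')'",
                                       if (i <= n) pos[i] else nchar(text) + 1L)
      i <<- i + 1L
      return(e)
    }
    if (tk == ")") bad("unbalanced parentheses: unexpected ')'", at)
    if (is_kw(tk, "and") || is_kw(tk, "or")) bad("empty operand", at)
    i <<- i + 1L
    gpr_leaf(tk)
  }
  parse_and <- function() {
    parts <- list(parse_atom())
    while (is_kw(peek(), "and")) {
      i <<- i + 1L
      parts <- c(parts, list(parse_atom()))
    }
    gpr_node("and", parts)
  }
  parse_or <- function() {
    parts <- list(parse_and())
    while (is_kw(peek(), "or")) {
      i <<- i + 1L
      parts <- c(parts, list(parse_and()))
    }
    gpr_node("or", parts)
  }

  out <- parse_or()
  if (i <= n) bad(if (toks[i] == ")") "unbalanced parentheses: unexpected ')'"
                  else "trailing input", pos[i])
  out
}

#' Evaluate a GPR rule against a set of present genes
#'
#' AND nodes are conjunctions (enzyme complexes), OR nodes disjunctions
#' (isozymes) and leaves test membership in `present`. The empty rule
#' evaluates `TRUE`: reactions without gene association are not constrained
#' by gene presence. Orthology FALSE-marker leaves always evaluate `FALSE`.
#'
#' @param rule a `"gpr"` object.
#' @param present character vector of present gene ids.
#' @return `TRUE` or `FALSE`.
#' @export
eval_gpr <- function(rule, present) {
  switch(rule$type,
    empty = TRUE,
    false = FALSE,
    leaf  = rule$gene %in% present,
    and   = all(vapply(rule$children, eval_gpr, NA, present = present)),
    or    = any(vapply(rule$children, eval_gpr, NA, present = present)),
    stop("malformed GPR node type: ", rule$type))
}

#' Genes referenced by a GPR rule
#'
#' @param rule a `"gpr"` object.
#' @param markers if `TRUE`, also return source genes recorded in orthology
#'   FALSE-marker leaves.
#' @return sorted character vector of gene ids (may be empty).
#' @export
gpr_genes <- function(rule, markers = FALSE) {
  acc <- character(0)
  walk <- function(nd) {
    if (nd$type == "leaf") acc[[length(acc) + 1L]] <<- nd$gene
    else if (nd$type == "false" && markers) acc[[length(acc) + 1L]] <<- nd$gene
    else if (nd$type %in% c("and", "or")) for (ch in nd$children) walk(ch)
  }
  walk(rule)
  sort(unique(acc))
}

#' Expression score of a GPR rule (mCADRE convention)
#'
#' Propagates per-gene ubiquity scores through the rule with AND -> min
#' (a complex is only as expressed as its scarcest subunit) and OR -> max
#' (any isozyme suffices). Empty rules and FALSE markers score 0; genes
#' missing from `ubiquity` score 0.
#'
#' @param rule a `"gpr"` object.
#' @param ubiquity named numeric vector of per-gene scores in `[0, 1]`.
#' @return a single numeric score in `[0, 1]`.
#' @export
score_gpr <- function(rule, ubiquity) {
  switch(rule$type,
    empty = 0,
    false = 0,
    leaf  = if (rule$gene %in% names(ubiquity)) unname(ubiquity[[rule$gene]]) else 0,
    and   = min(vapply(rule$children, score_gpr, 0, ubiquity = ubiquity)),
    or    = max(vapply(rule$children, score_gpr, 0, ubiquity = ubiquity)))
}

#' Test two GPR rules for Boolean-tree equality
#'
#' Equality is up to child ordering (the canonical form collapses duplicate
#' children and flattens nested nodes of the same operator).
#'
#' @param a,b `"gpr"` objects.
#' @return `TRUE` or `FALSE`.
#' @export
gpr_equal <- function(a, b) identical(gpr_key(a), gpr_key(b))

gpr_has_marker <- function(rule) {
  if (rule$type == "false") return(TRUE)
  if (rule$type %in% c("and", "or"))
    return(any(vapply(rule$children, gpr_has_marker, NA)))
  FALSE
}

# serialize; `parent` controls parenthesisation ("and" binds tighter than "or")
gpr_deparse <- function(rule, parent = "or") {
  switch(rule$type,
    empty = "",
    leaf  = rule$gene,
    false = stop("cannot serialize a GPR containing orthology FALSE markers; ",
                 "prune it first (see apply_curation)", call. = FALSE),
    and   = {
      s <- paste(vapply(rule$children, gpr_deparse, "", parent = "and"),
                 collapse = " and ")
      s
    },
    or    = {
      s <- paste(vapply(rule$children, gpr_deparse, "", parent = "or"),
                 collapse = " or ")
      if (parent == "and") paste0("(", s, ")") else s
    })
}

#' @export
as.character.gpr <- function(x, ...) gpr_deparse(x)

#' @export
print.gpr <- function(x, ...) {
  show <- function(nd) {
    switch(nd$type,
      empty = "<no gene association>",
      false = paste0("!", nd$gene),
      leaf  = nd$gene,
      and   = paste0("(", paste(vapply(nd$children, show, ""), collapse = " and "), ")"),
      or    = paste0("(", paste(vapply(nd$children, show, ""), collapse = " or "), ")"))
  }
  cat("GPR:", show(x), "\n")
  invisible(x)
}
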