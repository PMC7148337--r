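# Orthology-based GPR translation and reaction triage.
#
# Reference-model genes are replaced by target-organism orthologues; the
# presence/absence of an orthologue is read as a Boolean value on the
# reference GPR, splitting reactions into:
#   NGA  - non-gene-associated (empty GPR)
#   GAHM - gene-associated, supported in both organisms (GPR still TRUE)
#   GAH  - gene-associated in the reference only (GPR falsified)
# GAH reactions require a curation decision (keep with a corrected rule,
# remove, or demote to a non-gene-associated reaction) before assembly.

PROVENANCE_TAGS <- c("homologene", "gene_record", "kegg_ko", "ensembl", "manual")

#' Construct an orthology map
#'
#' @param entries data.frame with columns `source_gene`, `target_gene`,
#'   `provenance` (one of `r paste(PROVENANCE_TAGS, collapse = ", ")`).
#'   A source gene absent from the table has no orthologue.
#' @return an object of class `"orthology_map"`.
#' @export
orthology_map <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  stopifnot(all(c("source_gene", "target_gene", "provenance") %in% names(entries)))
  bad <- !(entries$provenance %in% PROVENANCE_TAGS)
  if (any(bad)) stop("unknown provenance tag(s): ",
                     paste(unique(entries$provenance[bad]), collapse = ", "))
  if (any(!nzchar(entries$source_gene)) || any(!nzchar(entries$target_gene)))
    stop("empty gene id in orthology map")
  entries <- unique(entries[, c("source_gene", "target_gene", "provenance")])
  rownames(entries) <- NULL
  structure(list(entries = entries,
                 targets = split(entries$target_gene, entries$source_gene)),
            class = "orthology_map")
}

#' Read an orthology map from TSV
#'
#' @param path TSV with columns `source_gene`, `target_gene`, `provenance`.
#' @return an `"orthology_map"`.
#' @export
read_orthology_map <- function(path) {
  orthology_map(utils::read.delim(path, stringsAsFactors = FALSE,
                                  colClasses = "character"))
}

map_targets <- function(map, gene) {
  t <- map$targets[[gene]]
  if (is.null(t)) character(0) else sort(unique(t))
}

#' Genes of the reference with at least one orthologue
#'
#' @param map an `"orthology_map"`.
#' @return character vector of source gene ids.
#' @export
mapped_genes <- function(map) sort(unique(map$entries$source_gene))

#' Translate a GPR rule through an orthology map
#'
#' Each leaf with k >= 1 orthologues becomes an OR over the k target genes
#' (k = 1 stays a plain leaf; OR is the permissive convention for
#' one-to-many orthology). A leaf with no orthologue is replaced by a
#' FALSE-marker leaf that records the failed source gene — markers are kept
#' in the tree (not silently dropped) so that reaction triage can see
#' exactly which genes lack support; they are pruned later by
#' [apply_curation()].
#'
#' @param rule a `"gpr"` object in reference gene space.
#' @param map an `"orthology_map"`.
#' @return list with `translated` (a `"gpr"`) and `unmapped` (character
#'   vector of source genes without orthologues).
#' @export
translate_gpr <- function(rule, map) {
  unmapped <- character(0)
  walk <- function(nd) {
    switch(nd$type,
      empty = gpr_empty(),
      false = nd,
      leaf  = {
        t <- map_targets(map, nd$gene)
        if (length(t) == 0L) {
          unmapped <<- c(unmapped, nd$gene)
          gpr_false(nd$gene)
        } else if (length(t) == 1L) gpr_leaf(t)
        else gpr_node("or", lapply(t, gpr_leaf))
      },
      gpr_node(nd$type, lapply(nd$children, walk)))
  }
  list(translated = walk(rule), unmapped = sort(unique(unmapped)))
}

#' Classify a reaction by orthology support
#'
#' @param rxn reaction id, or a `"gpr"` object.
#' @param model the reference model (needed when `rxn` is an id).
#' @param map an `"orthology_map"`.
#' @return `"NGA"`, `"GAHM"` or `"GAH"`.
#' @export
classify_reaction <- function(rxn, map, model = NULL) {
  rule <- if (inherits(rxn, "gpr")) rxn else model$gpr[[rxn]]
  if (is.null(rule)) stop("unknown reaction: ", rxn)
  if (rule$type == "empty") return("NGA")
  if (eval_gpr(rule, mapped_genes(map))) "GAHM" else "GAH"
}

#' Classify every reaction of a model
#'
#' @param model the reference model.
#' @param map an `"orthology_map"`.
#' @return named character vector (reaction id -> class).
#' @export
classify_reactions <- function(model, map) {
  present <- mapped_genes(map)
  vapply(stats::setNames(model$reactions$id, model$reactions$id), function(r) {
    g <- model$gpr[[r]]
    if (g$type == "empty") "NGA" else if (eval_gpr(g, present)) "GAHM" else "GAH"
  }, "")
}

CURATION_ACTIONS <- c("keep_with_gpr", "remove", "demote_to_non_gene")
CURATION_CATEGORIES <- c("GAH1", "GAH2", "GAH3", "specific_addition")

#' Read a curation-decision table
#'
#' TSV with columns `reaction_id`, `action` (`keep_with_gpr`, `remove`,
#' `demote_to_non_gene`), `corrected_gpr` (for `keep_with_gpr`),
#' `category` (`GAH1`/`GAH2`/`GAH3`/`specific_addition`) and `rationale`.
#'
#' @param path TSV file path.
#' @return a data.frame of class `"curation_decisions"`.
#' @export
read_curation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  curation_decisions(df)
}

#' Construct a curation-decision table
#'
#' @param df data.frame with columns `reaction_id`, `action`, and optionally
#'   `corrected_gpr`, `category`, `rationale`.
#' @return the validated data.frame, classed `"curation_decisions"`.
#' @export
curation_decisions <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("reaction_id", "action") %in% names(df)))
  if (is.null(df$corrected_gpr)) df$corrected_gpr <- character(nrow(df))
  if (is.null(df$category)) df$category <- character(nrow(df))
  if (is.null(df$rationale)) df$rationale <- character(nrow(df))
  df$corrected_gpr[is.na(df$corrected_gpr)] <- ""
  bad <- !(df$action %in% CURATION_ACTIONS)
  if (any(bad)) stop("unknown curation action(s): ",
                     paste(unique(df$action[bad]), collapse = ", "))
  bad <- nzchar(df$category) & !(df$category %in% CURATION_CATEGORIES)
  if (any(bad)) stop("unknown curation category(s): ",
                     paste(unique(df$category[bad]), collapse = ", "))
  if (anyDuplicated(df$reaction_id))
    stop("duplicate curation decisions for: ",
         paste(unique(df$reaction_id[duplicated(df$reaction_id)]), collapse = ", "))
  structure(df, class = c("curation_decisions", "data.frame"))
}

# prune orthology FALSE markers: FALSE under OR drops the leaf; FALSE under
# AND falsifies the whole rule, which is forbidden for core reactions
prune_markers <- function(rule, rxn_id = "?") {
  walk <- function(nd) {
    switch(nd$type,
      empty = nd,
      leaf  = nd,
      false = NULL,
      and   = {
        kids <- lapply(nd$children, walk)
        if (any(vapply(kids, is.null, NA)))
          stop("core reaction ", rxn_id,
               " has an unmapped gene inside an AND complex; ",
               "its GPR would be falsified - it needs a curation decision",
               call. = FALSE)
        gpr_node("and", kids)
      },
      or    = {
        kids <- Filter(Negate(is.null), lapply(nd$children, walk))
        if (length(kids) == 0L) return(NULL)
        gpr_node("or", kids)
      })
  }
  out <- walk(rule)
  if (is.null(out))
    stop("core reaction ", rxn_id, " lost all gene support during marker pruning",
         call. = FALSE)
  out
}

#' Partition a reference model into core and non-core reactions
#'
#' Implements the reconstruction triage: reactions supported in both
#' organisms (GAHM), curated keeps (GAH1), designated specific additions and
#' artificial reactions (biomass, ATP maintenance) form the core; non-gene
#' reactions (NGA) and demoted reactions (GAH3) form the non-core;
#' `remove` decisions (GAH2) delete the reaction outright. Every GAH
#' reaction must be covered by a decision — the manual triage obligation is
#' enforced, not skipped. Core GPRs are translated to target gene space with
#' FALSE markers pruned; demoted reactions get the empty rule; bounds are
#' never changed (demoted reactions keep their original bounds).
#'
#' @param model the reference model (including any curated additions).
#' @param map an `"orthology_map"`.
#' @param decisions a `"curation_decisions"` table (may be empty).
#' @param artificial reaction ids always placed in the core regardless of
#'   gene association; defaults to the model objective plus `"ATPM"` when
#'   present.
#' @return an object of class `"core_partition"`: list with `core`,
#'   `non_core` (character vectors), `classification` (named vector),
#'   `removed`, and `model` — the translated model over which the partition
#'   is defined.
#' @export
apply_curation <- function(model, map, decisions = NULL, artificial = NULL) {
  if (is.null(decisions))
    decisions <- curation_decisions(data.frame(reaction_id = character(0),
                                               action = character(0)))
  if (is.null(artificial)) {
    artificial <- intersect(c(model$objective, "ATPM"), model$reactions$id)
    artificial <- artificial[!is.na(artificial)]
  }
  unknown <- setdiff(decisions$reaction_id, model$reactions$id)
  if (length(unknown)) stop("curation decision(s) for unknown reaction(s): ",
                            paste(unknown, collapse = ", "))

  cls <- classify_reactions(model, map)
  specific <- decisions$reaction_id[decisions$category == "specific_addition"]
  gah <- setdiff(names(cls)[cls == "GAH"], specific)
  uncovered <- setdiff(gah, decisions$reaction_id)
  if (length(uncovered))
    stop("GAH reaction(s) lack a curation decision: ",
         paste(sort(uncovered), collapse = ", "))

  removed <- character(0)
  core <- character(0)
  non_core <- character(0)

  for (r in model$reactions$id) {
    dec_i <- match(r, decisions$reaction_id)
    if (!is.na(dec_i)) {
      act <- decisions$action[dec_i]
      if (act == "remove") { removed <- c(removed, r); next }
      if (act == "demote_to_non_gene") {
        model$gpr[[r]] <- gpr_empty()
        non_core <- c(non_core, r)
        next
      }
      # keep_with_gpr
      corrected <- parse_gpr(decisions$corrected_gpr[dec_i])
      if (decisions$category[dec_i] == "specific_addition") {
        # already in target gene space
        model$gpr[[r]] <- corrected
      } else {
        tr <- translate_gpr(corrected, map)
        if (length(tr$unmapped))
          stop("corrected GPR for ", r, " still has unmapped gene(s): ",
               paste(tr$unmapped, collapse = ", "))
        model$gpr[[r]] <- tr$translated
      }
      core <- c(core, r)
      next
    }
    if (cls[[r]] == "NGA") {
      if (r %in% artificial) core <- c(core, r) else non_core <- c(non_core, r)
      next
    }
    if (cls[[r]] == "GAHM") {
      tr <- translate_gpr(model$gpr[[r]], map)
      model$gpr[[r]] <- prune_markers(tr$translated, r)
      core <- c(core, r)
      next
    }
    stop("internal: unhandled GAH reaction ", r)  # nocov
  }

  if (length(removed)) model <- remove_reactions(model, removed)
  cls <- cls[model$reactions$id]
  structure(list(core = core, non_core = non_core, classification = cls,
                 removed = removed, model = model),
            class = "core_partition")
}

#' @export
print.core_partition <- function(x, ...) {
  cat("Core/non-core partition:\n")
  cat("  core:    ", length(x$core), "reactions\n")
  cat("  non-core:", length(x$non_core), "reactions\n")
  cat("  removed: ", length(x$removed), "reactions\n")
  cat("  classes: ", paste(names(table(x$classification)),
                           table(x$classification), collapse = ", "), "\n")
  invisible(x)
}

#' Add curated organism-specific reactions to a model
#'
#' Additions are records with `id`, `stoichiometry` (metabolite -> signed
#' coefficient), `lb`, `ub`, `gpr` (target gene space) and a `metabolites`
#' list describing any metabolites new to the model. After insertion, any
#' new metabolite that cannot be both produced and consumed gets an
#' automatic reversible sink reaction (`SK_<metabolite>`), keeping the
#' additions flux-consistent.
#'
#' @param model a `"metabolic_model"`.
#' @param additions list of addition records, or a path to a JSON file of
#'   them.
#' @return the extended model; added reaction ids (including auto-sinks) are
#'   in `attr(, "curated_additions")`.
#' @export
add_curated_reactions <- function(model, additions) {
  if (is.character(additions) && length(additions) == 1L)
    additions <- jsonlite::fromJSON(additions, simplifyVector = FALSE)$reactions %||%
      jsonlite::fromJSON(additions, simplifyVector = FALSE)
  if (length(additions) == 0L) {
    attr(model, "curated_additions") <- character(0)
    return(model)
  }
  ids <- vapply(additions, function(a) a$id, "")
  clash <- intersect(ids, model$reactions$id)
  if (length(clash)) stop("addition id(s) already in model: ",
                          paste(clash, collapse = ", "))
  new_mets <- character(0)
  for (a in additions) {
    nm <- NULL
    if (!is.null(a$metabolites) && length(a$metabolites)) {
      nm <- do.call(rbind, lapply(a$metabolites, function(m)
        data.frame(id = m$id, name = m$name %||% m$id,
                   compartment = m$compartment %||% sub("^.*_([a-z0-9]+)$", "\\1", m$id),
                   formula = m$formula %||% NA_character_,
                   charge = m$charge %||% NA_integer_, stringsAsFactors = FALSE)))
      new_mets <- c(new_mets, setdiff(nm$id, model$metabolites$id))
    }
    s <- unlist(a$stoichiometry)
    s <- stats::setNames(as.numeric(s), names(s))
    unknown <- setdiff(names(s), c(model$metabolites$id, if (!is.null(nm)) nm$id))
    if (length(unknown))
      stop("addition ", a$id, " references metabolite(s) neither in the model ",
           "nor declared in the record: ", paste(unknown, collapse = ", "))
    model <- add_reaction(model, a$id, s, lb = a$lb %||% -1000, ub = a$ub %||% 1000,
                          gpr = a$gpr %||% "", name = a$name %||% a$id,
                          subsystem = a$subsystem %||% "", new_metabolites = nm)
  }
  sinks <- character(0)
  cap <- met_capability(model)
  for (m in unique(new_mets)) {
    if (!(cap$produced[[m]] && cap$consumed[[m]])) {
      sk <- paste0("SK_", m)
      model <- add_reaction(model, sk, stats::setNames(-1, m),
                            lb = -1000, ub = 1000,
                            name = paste("sink for", m))
      sinks <- c(sinks, sk)
    }
  }
  attr(model, "curated_additions") <- c(ids, sinks)
  model
}
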