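# The metabolic model container: metabolites, reactions, stoichiometry,
# GPR rules and an objective. Plain S3 on base-R data frames; the
# stoichiometry is a per-reaction named list so that reaction-level edits
# (knockouts, media, pruning) stay cheap and explicit.

#' Construct a metabolic model
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id` (unique), and optionally
#'   `name`, `compartment`, `formula`, `charge`. A missing compartment is
#'   inferred from the trailing `_<tag>` of the metabolite id
#'   (BIGG convention, e.g. `"glc__D_c"` -> `"c"`).
#' @param reactions data.frame with columns `id` (unique), `lb`, `ub`
#'   (flux bounds, mmol/gDW/h convention), and optionally `name`,
#'   `subsystem`.
#' @param stoichiometry named list (one element per reaction id) of named
#'   numeric vectors mapping metabolite id to signed coefficient
#'   (negative = consumed).
#' @param gpr named list of `"gpr"` objects or GPR strings, indexed by
#'   reaction id; reactions absent from the list get the empty rule.
#' @param objective id of the objective (biomass) reaction, or `NA`.
#' @return an object of class `"metabolic_model"`.
#' @export
metabolic_model <- function(id = "model", metabolites, reactions, stoichiometry,
                            gpr = list(), objective = NA_character_) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$compartment))
    metabolites$compartment <- sub("^.*_([a-z0-9]+)$", "\\1", metabolites$id)
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(metabolites$charge)) metabolites$charge <- NA_integer_
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  metabolites <- metabolites[, c("id", "name", "compartment", "formula", "charge")]
  reactions <- reactions[, c("id", "name", "lb", "ub", "subsystem")]
  rownames(metabolites) <- NULL
  rownames(reactions) <- NULL

  stoichiometry <- stoichiometry[reactions$id]
  gprs <- stats::setNames(vector("list", nrow(reactions)), reactions$id)
  for (r in reactions$id) {
    g <- gpr[[r]]
    gprs[[r]] <- if (is.null(g)) gpr_empty()
                 else if (is.character(g)) parse_gpr(g)
                 else g
  }
  nmet <- vapply(stoichiometry, length, 0L)
  reactions$is_exchange <- nmet == 1L

  model <- structure(list(id = id, metabolites = metabolites,
                          reactions = reactions, stoichiometry = stoichiometry,
                          gpr = gprs, objective = objective),
                     class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate metabolic model invariants
#'
#' Checks id uniqueness, bound ordering (`lb <= ub`), that every
#' stoichiometry entry resolves to a known metabolite and is non-empty,
#' and that the objective (if set) resolves to a reaction.
#'
#' @param model a `"metabolic_model"`.
#' @return the model, invisibly; errors describe the first violation.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  if (anyDuplicated(mets)) stop("duplicate metabolite ids: ",
                                paste(unique(mets[duplicated(mets)]), collapse = ", "))
  if (anyDuplicated(rxns)) stop("duplicate reaction ids: ",
                                paste(unique(rxns[duplicated(rxns)]), collapse = ", "))
  bad <- model$reactions$lb > model$reactions$ub
  if (any(bad)) stop("lb > ub for reaction(s): ", paste(rxns[bad], collapse = ", "))
  if (!identical(names(model$stoichiometry), rxns))
    stop("stoichiometry list does not match reaction ids")
  for (r in rxns) {
    s <- model$stoichiometry[[r]]
    if (length(s) == 0L) stop("empty stoichiometry for reaction ", r)
    unknown <- setdiff(names(s), mets)
    if (length(unknown))
      stop("reaction ", r, " references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
  }
  if (!is.na(model$objective) && !(model$objective %in% rxns))
    stop("objective reaction not in model: ", model$objective)
  invisible(model)
}

#' Genes of a model
#'
#' The gene set of a model is the union of all GPR leaves.
#'
#' @param model a `"metabolic_model"`.
#' @return sorted character vector of gene ids.
#' @export
model_genes <- function(model) {
  sort(unique(unlist(lapply(model$gpr, gpr_genes), use.names = FALSE)))
}

#' Exchange (boundary) reaction ids
#'
#' Exchange, sink and demand reactions all touch exactly one metabolite;
#' they are the model's boundary with the environment.
#'
#' @param model a `"metabolic_model"`.
#' @return character vector of reaction ids.
#' @export
exchanges <- function(model) model$reactions$id[model$reactions$is_exchange]

#' Stoichiometric matrix
#'
#' @param model a `"metabolic_model"`.
#' @return a dense numeric matrix, metabolites x reactions.
#' @export
stoichiometry_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    s <- model$stoichiometry[[j]]
    S[names(s), j] <- s
  }
  S
}

#' Set flux bounds on reactions
#'
#' @param model a `"metabolic_model"`.
#' @param rxns reaction ids.
#' @param lb,ub new bounds, recycled over `rxns`; `NA` leaves a bound as is.
#' @return the modified model.
#' @export
set_bounds <- function(model, rxns, lb = NA, ub = NA) {
  idx <- match(rxns, model$reactions$id)
  if (anyNA(idx)) stop("unknown reaction id(s): ",
                       paste(rxns[is.na(idx)], collapse = ", "))
  lb <- rep_len(lb, length(idx)); ub <- rep_len(ub, length(idx))
  keep <- !is.na(lb); model$reactions$lb[idx[keep]] <- lb[keep]
  keep <- !is.na(ub); model$reactions$ub[idx[keep]] <- ub[keep]
  bad <- model$reactions$lb[idx] > model$reactions$ub[idx]
  if (any(bad)) stop("lb > ub after update for: ", paste(rxns[bad], collapse = ", "))
  model
}

#' Remove reactions from a model
#'
#' @param model a `"metabolic_model"`.
#' @param rxns reaction ids to delete.
#' @param drop_orphans drop metabolites no longer used by any reaction.
#' @return the reduced model.
#' @export
remove_reactions <- function(model, rxns, drop_orphans = TRUE) {
  unknown <- setdiff(rxns, model$reactions$id)
  if (length(unknown)) stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  keep <- !(model$reactions$id %in% rxns)
  model$reactions <- model$reactions[keep, , drop = FALSE]
  rownames(model$reactions) <- NULL
  model$stoichiometry <- model$stoichiometry[model$reactions$id]
  model$gpr <- model$gpr[model$reactions$id]
  if (!is.na(model$objective) && !(model$objective %in% model$reactions$id))
    model$objective <- NA_character_
  if (drop_orphans) {
    used <- unique(unlist(lapply(model$stoichiometry, names), use.names = FALSE))
    model$metabolites <- model$metabolites[model$metabolites$id %in% used, , drop = FALSE]
    rownames(model$metabolites) <- NULL
  }
  model
}

#' Keep only the given reactions
#'
#' @param model a `"metabolic_model"`.
#' @param rxns reaction ids to retain.
#' @param drop_orphans drop metabolites no longer used.
#' @return the restricted model.
#' @export
subset_reactions <- function(model, rxns, drop_orphans = TRUE) {
  unknown <- setdiff(rxns, model$reactions$id)
  if (length(unknown)) stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  remove_reactions(model, setdiff(model$reactions$id, rxns), drop_orphans = drop_orphans)
}

#' Add a single reaction
#'
#' @param model a `"metabolic_model"`.
#' @param id new reaction id (must not collide).
#' @param stoichiometry named numeric vector, metabolite id -> coefficient.
#' @param lb,ub flux bounds.
#' @param gpr GPR string or `"gpr"` object (default: no gene association).
#' @param name,subsystem optional annotation.
#' @param new_metabolites optional data.frame of metabolites to add first
#'   (columns as in [metabolic_model()]).
#' @return the extended model.
#' @export
add_reaction <- function(model, id, stoichiometry, lb = -1000, ub = 1000,
                         gpr = "", name = id, subsystem = "",
                         new_metabolites = NULL) {
  if (id %in% model$reactions$id) stop("reaction id already in model: ", id)
  if (!is.null(new_metabolites)) {
    nm <- as.data.frame(new_metabolites, stringsAsFactors = FALSE)
    if (is.null(nm$name)) nm$name <- nm$id
    if (is.null(nm$compartment))
      nm$compartment <- sub("^.*_([a-z0-9]+)$", "\\1", nm$id)
    if (is.null(nm$formula)) nm$formula <- NA_character_
    if (is.null(nm$charge)) nm$charge <- NA_integer_
    nm <- nm[!(nm$id %in% model$metabolites$id), , drop = FALSE]
    model$metabolites <- rbind(model$metabolites,
                               nm[, c("id", "name", "compartment", "formula", "charge")])
    rownames(model$metabolites) <- NULL
  }
  unknown <- setdiff(names(stoichiometry), model$metabolites$id)
  if (length(unknown))
    stop("reaction ", id, " references unknown metabolite(s): ",
         paste(unknown, collapse = ", "))
  model$reactions <- rbind(model$reactions,
                           data.frame(id = id, name = name, lb = lb, ub = ub,
                                      subsystem = subsystem,
                                      is_exchange = length(stoichiometry) == 1L,
                                      stringsAsFactors = FALSE))
  rownames(model$reactions) <- NULL
  model$stoichiometry[[id]] <- stoichiometry
  model$gpr[[id]] <- if (is.character(gpr)) parse_gpr(gpr) else gpr
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model:", x$id, "\n")
  cat("  metabolites:", nrow(x$metabolites), "\n")
  cat("  reactions:  ", nrow(x$reactions),
      sprintf("(%d exchange)", sum(x$reactions$is_exchange)), "\n")
  cat("  genes:      ", length(model_genes(x)), "\n")
  cat("  objective:  ", if (is.na(x$objective)) "<unset>" else x$objective, "\n")
  invisible(x)
}

# signed production/consumption capability of each metabolite, honouring
# reversibility: a reversible reaction both produces and consumes each of
# its metabolites
met_capability <- function(model, rxns = NULL) {
  if (is.null(rxns)) rxns <- model$reactions$id
  mets <- model$metabolites$id
  prod <- stats::setNames(logical(length(mets)), mets)
  cons <- prod
  idx <- match(rxns, model$reactions$id)
  for (k in seq_along(rxns)) {
    s <- model$stoichiometry[[rxns[k]]]
    lbk <- model$reactions$lb[idx[k]]; ubk <- model$reactions$ub[idx[k]]
    fwd <- ubk > 0; rev <- lbk < 0
    pos <- names(s)[s > 0]; neg <- names(s)[s < 0]
    if (fwd) { prod[pos] <- TRUE; cons[neg] <- TRUE }
    if (rev) { prod[neg] <- TRUE; cons[pos] <- TRUE }
  }
  list(produced = prod, consumed = cons)
}
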