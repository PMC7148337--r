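# Tissue-specific model extraction: an mCADRE-style ranking and sequential
# pruning of low-evidence reactions, with three guards per tentative
# removal — key-metabolite producibility from glucose, core-reaction flux
# consistency, and a biomass-production floor relative to the parent
# genome-scale model. Reaction confidence scores are not used in the
# ranking (only expression- and connectivity-based scores).

#' Expression- and connectivity-based reaction scores
#'
#' The expression score propagates gene ubiquity through the GPR with
#' AND -> min and OR -> max; reactions without gene association score 0.
#' The connectivity score of a reaction is the mean expression score of its
#' adjacent reactions — those sharing at least one non-currency metabolite
#' (currency metabolites such as protons, water and common cofactors would
#' otherwise make the adjacency graph nearly complete).
#'
#' @param model a `"metabolic_model"`.
#' @param ubiquity named numeric vector of gene ubiquity scores (missing
#'   genes score 0).
#' @param currency metabolite base ids (compartment suffix stripped)
#'   excluded from adjacency.
#' @return data.frame with columns `reaction`, `expression_score`,
#'   `connectivity_score`.
#' @export
score_reactions <- function(model, ubiquity,
                            currency = c("h", "h2o", "atp", "adp", "pi",
                                         "nad", "nadh")) {
  rxns <- model$reactions$id
  expr <- vapply(rxns, function(r) score_gpr(model$gpr[[r]], ubiquity), 0)

  base <- stats::setNames(sub("_[a-z0-9]+$", "", model$metabolites$id),
                          model$metabolites$id)
  rxn_mets <- lapply(model$stoichiometry,
                     function(s) names(s)[!(base[names(s)] %in% currency)])
  met2rxn <- list()
  for (r in rxns) for (m in rxn_mets[[r]])
    met2rxn[[m]] <- c(met2rxn[[m]], r)
  conn <- vapply(rxns, function(r) {
    adj <- setdiff(unique(unlist(met2rxn[rxn_mets[[r]]], use.names = FALSE)), r)
    if (length(adj) == 0L) 0 else mean(expr[adj])
  }, 0)
  data.frame(reaction = rxns, expression_score = unname(expr),
             connectivity_score = unname(conn), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Pruning configuration for tissue extraction
#'
#' @param core_threshold expression score at or above which a reaction is
#'   core (inclusive).
#' @param biomass_fraction minimum retained fraction of the parent model's
#'   biomass optimum (default 0.8: a removal dropping biomass below 80% of
#'   the genome-scale optimum is rejected).
#' @param key_metabolites metabolite ids that must stay producible from the
#'   source metabolite throughout pruning.
#' @param medium a `"medium"` object (growth condition for the biomass and
#'   producibility checks).
#' @param source_metabolite substrate for the producibility checks
#'   (glucose).
#' @param tol "almost zero" flux threshold.
#' @return an object of class `"prune_config"`.
#' @export
prune_config <- function(core_threshold = 0.5, biomass_fraction = 0.8,
                         key_metabolites = character(0), medium,
                         source_metabolite = "glc__D_e", tol = 1e-6) {
  stopifnot(core_threshold >= 0, core_threshold <= 1,
            biomass_fraction >= 0, biomass_fraction <= 1,
            inherits(medium, "medium"))
  structure(list(core_threshold = core_threshold,
                 biomass_fraction = biomass_fraction,
                 key_metabolites = key_metabolites, medium = medium,
                 source_metabolite = source_metabolite, tol = tol),
            class = "prune_config")
}

#' Rank reactions and split into core and ordered non-core
#'
#' Core: expression score at or above the threshold (inclusive). Non-core
#' reactions are ordered for removal by ascending expression score, ties by
#' ascending connectivity score, remaining ties lexicographic by id — the
#' weakest-evidence reactions are attacked first.
#'
#' @param scores data.frame from [score_reactions()].
#' @param config a `"prune_config"`.
#' @return list with `core` (ids) and `removal_order` (ids).
#' @export
rank_and_partition <- function(scores, config) {
  core <- scores$reaction[scores$expression_score >= config$core_threshold]
  nc <- scores[!(scores$reaction %in% core), , drop = FALSE]
  ord <- nc[order(nc$expression_score, nc$connectivity_score, nc$reaction), ]
  list(core = core, removal_order = ord$reaction)
}

# can `met` be made from the source under the medium? (sink in, demand out)
producible <- function(model, met, source, med, tol) {
  if (!(met %in% model$metabolites$id)) return(FALSE)
  m <- apply_medium(model, med, skip_missing = TRUE)
  if (source %in% m$metabolites$id) {
    b <- boundary_for(m, source)
    if (is.na(b)) m <- add_reaction(m, paste0("SK_", source, "__chk"),
                                    stats::setNames(-1, source), lb = -1000, ub = 1000)
    else m <- set_bounds(m, b, lb = -1000, ub = 1000)
  }
  b <- boundary_for(m, met)
  if (is.na(b)) {
    b <- paste0("DM_", met, "__chk")
    m <- add_reaction(m, b, stats::setNames(-1, met), lb = 0, ub = 1000)
  } else m <- set_bounds(m, b, ub = 1000)
  sol <- fba(m, objective = b)
  sol$status == "optimal" && sol$objective_value > tol
}

#' Sequentially prune non-core reactions from a genome-scale model
#'
#' Walks the removal order; each reaction is tentatively removed and
#' retained if the removal (a) makes a key metabolite non-producible from
#' the source metabolite under the configured medium, (b) blocks any core
#' reaction, or (c) drops the biomass optimum under the medium below
#' `biomass_fraction` of the parent model's optimum. Otherwise the removal
#' is committed. The trace records every non-core reaction exactly once.
#'
#' @param model the parent genome-scale model.
#' @param core core reaction ids (never removed).
#' @param removal_order non-core reaction ids in removal order.
#' @param config a `"prune_config"`.
#' @return list with `model` (the tissue model) and `trace` (data.frame:
#'   reaction, action, reason).
#' @export
prune_model <- function(model, core, removal_order, config) {
  base <- apply_medium(model, config$medium, skip_missing = TRUE)
  wt <- fba(base)
  if (wt$status != "optimal" || wt$objective_value <= config$tol)
    stop("parent model does not grow under the pruning medium (status ",
         wt$status, ")")
  floor_val <- config$biomass_fraction * wt$objective_value

  cur <- model
  trace <- vector("list", length(removal_order))
  core_present <- intersect(core, cur$reactions$id)

  for (k in seq_along(removal_order)) {
    r <- removal_order[k]
    if (identical(r, cur$objective)) {
      # the biomass reaction itself can never survive its own removal
      trace[[k]] <- data.frame(reaction = r, action = "retained",
                               reason = "breaks_biomass", stringsAsFactors = FALSE)
      next
    }
    tent <- remove_reactions(cur, r)
    reason <- "ok"

    for (km in config$key_metabolites) {
      if (!producible(tent, km, config$source_metabolite, config$medium,
                      config$tol)) {
        reason <- "breaks_function"; break
      }
    }
    if (reason == "ok") {
      open <- set_bounds(tent, exchanges(tent), lb = -1000, ub = 1000)
      ok <- certify_cores(open, intersect(core_present, tent$reactions$id),
                          config$tol)
      if (!all(ok)) reason <- "breaks_consistency"
    }
    if (reason == "ok") {
      sol <- fba(apply_medium(tent, config$medium, skip_missing = TRUE))
      if (sol$status != "optimal" || sol$objective_value < floor_val)
        reason <- "breaks_biomass"
    }

    if (reason == "ok") {
      cur <- tent
      trace[[k]] <- data.frame(reaction = r, action = "removed", reason = "ok",
                               stringsAsFactors = FALSE)
    } else {
      trace[[k]] <- data.frame(reaction = r, action = "retained",
                               reason = reason, stringsAsFactors = FALSE)
    }
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(reaction = character(0), action = character(0),
               reason = character(0))
  list(model = cur, trace = trace)
}

#' Extract a tissue-specific model
#'
#' Convenience wrapper: score reactions against the tissue's gene ubiquity,
#' rank and partition at the configured threshold, then prune.
#'
#' @param model the parent genome-scale model.
#' @param ubiquity named numeric gene ubiquity vector for the tissue.
#' @param config a `"prune_config"`.
#' @param currency passed to [score_reactions()].
#' @return list with `model`, `trace`, `scores`, `core`.
#' @export
extract_tissue_model <- function(model, ubiquity, config,
                                 currency = c("h", "h2o", "atp", "adp", "pi",
                                              "nad", "nadh")) {
  scores <- score_reactions(model, ubiquity, currency = currency)
  rp <- rank_and_partition(scores, config)
  pr <- prune_model(model, rp$core, rp$removal_order, config)
  list(model = pr$model, trace = pr$trace, scores = scores, core = rp$core)
}
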