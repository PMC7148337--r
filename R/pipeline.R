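# End-to-end reconstruction: reference model + orthology map + curation
# decisions + organism-specific additions -> core/non-core partition ->
# gap-filled minimal model and maximal model.

#' Path to the bundled synthetic organism-specific additions
#'
#' A synthetic stand-in for the curated table of target-organism-specific
#' reactions (the four KEGG reactions missing from the reference organism,
#' with their four new metabolites), expressed over the synthetic reference
#' model's namespace.
#'
#' @return file path of the bundled JSON.
#' @export
example_additions <- function() {
  system.file("extdata", "mouse_specific_reactions_synthetic.json",
              package = "gemrecon")
}

#' Orthology-based reconstruction of minimal and maximal target models
#'
#' Runs the full draft-reconstruction workflow: insert curated
#' organism-specific additions (with automatic consistency sinks), translate
#' GPRs through the orthology map and triage reactions into core and
#' non-core sets under the curation decisions, gap-fill the core from the
#' non-core candidates, and assemble the minimal (core + gap-filled subset)
#' and maximal (core + all non-core) models. Non-core reactions demoted for
#' consistency reasons (GAH3-style) get gap-fill weight 0: they are always
#' admissible, mirroring their role of preserving reference-model
#' consistency.
#'
#' @param reference the reference `"metabolic_model"`.
#' @param map an `"orthology_map"`.
#' @param decisions a `"curation_decisions"` table covering every GAH
#'   reaction (additions are appended automatically as
#'   `specific_addition` keeps).
#' @param additions organism-specific reaction records (list or JSON path),
#'   or `NULL`.
#' @param epsilon gap-fill flux threshold.
#' @param artificial reaction ids always kept in the core (default: the
#'   objective plus `"ATPM"`).
#' @return list with `min_model`, `max_model`, `partition`, `gapfill`.
#' @export
reconstruct_models <- function(reference, map, decisions = NULL,
                               additions = NULL, epsilon = 1e-4,
                               artificial = NULL) {
  if (!is.null(additions)) {
    reference <- add_curated_reactions(reference, additions)
    added_ids <- attr(reference, "curated_additions")
    real <- added_ids[!startsWith(added_ids, "SK_")]
    add_dec <- curation_decisions(data.frame(
      reaction_id = real, action = "keep_with_gpr",
      corrected_gpr = vapply(reference$gpr[real], as.character, ""),
      category = "specific_addition",
      rationale = "curated organism-specific addition",
      stringsAsFactors = FALSE))
    decisions <- if (is.null(decisions)) add_dec else
      curation_decisions(rbind(as.data.frame(decisions), as.data.frame(add_dec)))
  }
  partition <- apply_curation(reference, map, decisions, artificial = artificial)
  demoted <- intersect(
    partition$non_core,
    if (is.null(decisions)) character(0) else
      decisions$reaction_id[decisions$action == "demote_to_non_gene"])
  w <- stats::setNames(rep(1, length(partition$non_core)), partition$non_core)
  w[demoted] <- 0
  gf <- minimal_gapfill(partition$model, core = partition$core,
                        candidates = partition$non_core, weights = w,
                        epsilon = epsilon)
  models <- assemble_models(partition$model, partition, gf)
  c(models, list(partition = partition, gapfill = gf))
}
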