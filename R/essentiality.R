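# Single-gene essentiality: FBA re-optimization or linear MOMA against a
# cached wild-type flux distribution, the 30% growth-ratio essentiality
# call, and confusion-matrix evaluation against experimental lethal/viable
# gene labels.

#' Wild-type flux reference
#'
#' Computes and caches the wild-type FBA optimum and flux vector used as the
#' fixed reference point for linear MOMA. The optimal vertex may be
#' degenerate; the deterministic solver makes the recorded vector
#' reproducible, and it is stored so downstream results can be audited.
#'
#' @param model the (medium-constrained) wild-type model.
#' @return an object of class `"wildtype_reference"`: `fluxes`,
#'   `objective_value`, `objective_id`, `reaction_ids`.
#' @export
wildtype_reference <- function(model) {
  sol <- fba(model)
  if (sol$status != "optimal")
    stop("wild-type model is ", sol$status, "; cannot build a MOMA reference")
  structure(list(fluxes = sol$fluxes, objective_value = sol$objective_value,
                 objective_id = model$objective,
                 reaction_ids = model$reactions$id),
            class = "wildtype_reference")
}

#' Linear MOMA flux distribution
#'
#' Minimizes the L1 distance `sum(|v_w - v_d|)` between the wild-type flux
#' vector and the perturbed model's fluxes, subject to the perturbed model's
#' mass balance and bounds (absolute values via positive/negative split
#' variables). The perturbed biomass flux is read off the resulting
#' distribution — growth is not re-optimized, capturing the minimal
#' metabolic adjustment after a knockout. An infeasible perturbed model
#' yields status `"infeasible"` with objective 0 by convention.
#'
#' @param reference a `"wildtype_reference"` on the same reaction namespace.
#' @param model the perturbed model (wild type plus knockout bounds).
#' @return a `"flux_solution"`; the minimized L1 distance is in
#'   `attr(, "distance")`.
#' @export
lmoma_flux <- function(reference, model) {
  if (!identical(reference$reaction_ids, model$reactions$id))
    stop("reference and perturbed model have different reaction namespaces")
  S <- stoichiometry_matrix(model)
  m <- nrow(S); n <- ncol(S)
  vw <- unname(reference$fluxes[colnames(S)])
  # vars: v (n), p (n), q (n);   v + p - q = v_w,  min sum(p + q)
  A <- cbind(rbind(S, diag(n)),
             rbind(matrix(0, m, n), diag(n)),
             rbind(matrix(0, m, n), -diag(n)))
  b <- c(rep(0, m), vw)
  lb <- c(pmax(model$reactions$lb, -BOUND_CLAMP), rep(0, 2 * n))
  ub <- c(pmin(model$reactions$ub, BOUND_CLAMP), rep(2 * BOUND_CLAMP, 2 * n))
  cost <- c(numeric(n), rep(1, 2 * n))
  res <- .lp_solve_dense(A, b, cost, lb, ub, FALSE)
  if (res$status != 0L) {
    out <- flux_solution("infeasible", 0,
                         stats::setNames(rep(NA_real_, n), colnames(S)))
    attr(out, "distance") <- NA_real_
    return(out)
  }
  v <- stats::setNames(res$x[seq_len(n)], colnames(S))
  out <- flux_solution("optimal", unname(v[reference$objective_id]), v)
  attr(out, "distance") <- sum(res$x[(n + 1):(3 * n)])
  out
}

#' Single-gene deletion analysis
#'
#' For each gene: constrain the reactions disabled by its deletion to zero
#' flux, then either re-maximize biomass (FBA) or compute the linear-MOMA
#' flux distribution against the cached wild type. A gene is called
#' essential when the knockout/wild-type growth ratio falls strictly below
#' `threshold` (default 0.30). Genes absent from the model are reported as
#' skipped rather than silently dropped.
#'
#' @param model a `"metabolic_model"`.
#' @param genes genes to delete (default: all model genes).
#' @param method `"fba"` or `"lmoma"`.
#' @param medium optional `"medium"` applied before analysis.
#' @param policy exchange-closure policy for the medium.
#' @param threshold essentiality growth-ratio cutoff (strict `<`).
#' @return data.frame (class `"knockout_results"`) with columns `gene`,
#'   `method`, `wild_type_objective`, `knockout_objective`, `growth_ratio`,
#'   `essential`, `skipped`; the wild-type reference is attached as an
#'   attribute.
#' @export
single_gene_deletion <- function(model, genes = NULL,
                                 method = c("fba", "lmoma"), medium = NULL,
                                 policy = c("organic_only", "all"),
                                 threshold = 0.30) {
  method <- match.arg(method)
  policy <- match.arg(policy)
  if (!is.null(medium)) model <- apply_medium(model, medium, policy = policy,
                                              skip_missing = TRUE)
  present <- model_genes(model)
  if (is.null(genes)) genes <- present
  ref <- wildtype_reference(model)   # errors if wild type infeasible
  wt <- ref$objective_value

  rows <- lapply(genes, function(g) {
    if (!(g %in% present))
      return(data.frame(gene = g, method = method, wild_type_objective = wt,
                        knockout_objective = NA_real_, growth_ratio = NA_real_,
                        essential = NA, skipped = TRUE, stringsAsFactors = FALSE))
    ko <- knockout_bounds(model, g)
    val <- if (method == "fba") {
      sol <- fba(ko)
      if (sol$status == "optimal") sol$objective_value else 0
    } else {
      lmoma_flux(ref, ko)$objective_value
    }
    ratio <- if (wt > 0) max(0, val) / wt else NA_real_
    data.frame(gene = g, method = method, wild_type_objective = wt,
               knockout_objective = val, growth_ratio = ratio,
               essential = ratio < threshold, skipped = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  n_skip <- sum(out$skipped)
  if (n_skip) message(n_skip, " gene(s) absent from the model were skipped")
  attr(out, "wild_type") <- ref
  attr(out, "threshold") <- threshold
  class(out) <- c("knockout_results", "data.frame")
  out
}

#' Construct a confusion matrix for essentiality predictions
#'
#' Positives are lethal genes: TP = lethal predicted essential, TN = viable
#' predicted non-essential. Sensitivity `TP/(TP+FN)` and specificity
#' `TN/(TN+FP)` are reported both as proportions and as nearest-integer
#' percentages (the convention used when tabulating knockout screens).
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return an object of class `"confusion_matrix"`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = sens, specificity = spec,
                 sensitivity_pct = round(100 * sens),
                 specificity_pct = round(100 * spec)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("sensitivity %d%%  specificity %d%%\n",
              x$sensitivity_pct, x$specificity_pct))
  invisible(x)
}

#' Evaluate essentiality predictions against lethal/viable labels
#'
#' @param results a `"knockout_results"` data.frame.
#' @param labels named character vector (gene -> `"lethal"`/`"viable"`), or
#'   a data.frame with columns `gene_id`, `label`.
#' @return a `"confusion_matrix"`; the numbers of evaluated and skipped
#'   genes (coverage-adjusted denominators) are attached as attributes.
#' @export
evaluate_essentiality <- function(results, labels) {
  if (is.data.frame(labels))
    labels <- stats::setNames(labels$label, labels$gene_id)
  ev <- results[!results$skipped, , drop = FALSE]
  unlab <- setdiff(ev$gene, names(labels))
  if (length(unlab)) stop("unlabelled gene(s): ", paste(unlab, collapse = ", "))
  lab <- labels[ev$gene]
  bad <- !(lab %in% c("lethal", "viable"))
  if (any(bad)) stop("labels must be 'lethal' or 'viable'; got: ",
                     paste(unique(lab[bad]), collapse = ", "))
  cm <- confusion_matrix(
    tp = sum(lab == "lethal" & ev$essential),
    fp = sum(lab == "viable" & ev$essential),
    fn = sum(lab == "lethal" & !ev$essential),
    tn = sum(lab == "viable" & !ev$essential))
  attr(cm, "n_evaluated") <- nrow(ev)
  attr(cm, "n_skipped") <- sum(results$skipped)
  cm
}
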