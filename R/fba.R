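# Constraint-based analysis core: FBA, FVA, blocked reactions and dead-end
# metabolites, growth media, and gene-knockout bound constraining.
#
# All solves go through the package's bounded-variable simplex (src/), which
# is deterministic (fixed pricing and tie-break rules, single-threaded), so
# degenerate alternate optima are resolved identically on every run. Only
# objective values are contractual; flux vectors at degenerate optima are a
# reproducible but arbitrary vertex.

BOUND_CLAMP <- 1e6   # finite box substituted for infinite bounds at solve time

lp_status <- function(code) {
  switch(as.character(code), "0" = "optimal", "1" = "infeasible",
         "2" = "unbounded", "iteration_limit")
}

flux_solution <- function(status, objective_value, fluxes) {
  structure(list(status = status, objective_value = objective_value,
                 fluxes = fluxes), class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("Flux solution:", x$status,
      if (x$status == "optimal") sprintf("(objective %.6g)", x$objective_value),
      "\n")
  invisible(x)
}

# low-level: solve min/max cost'v s.t. S v = 0, bounds; extra_rows allows
# additional equality rows (each a list(coefs = named numeric over reaction
# ids and/or slack specs)); used for the FVA objective-fraction constraint.
model_lp <- function(model, cost, maximize,
                     extra_row = NULL, extra_rhs = 0,
                     slack_bounds = NULL) {
  S <- stoichiometry_matrix(model)
  n <- ncol(S)
  lb <- pmax(model$reactions$lb, -BOUND_CLAMP)
  ub <- pmin(model$reactions$ub, BOUND_CLAMP)
  b <- rep(0, nrow(S))
  A <- S
  cc <- cost
  if (!is.null(extra_row)) {
    # extra_row: named numeric over reactions; constraint extra_row'v - s = rhs
    row <- rep(0, n); row[match(names(extra_row), colnames(S))] <- extra_row
    A <- rbind(A, row)
    A <- cbind(A, c(rep(0, nrow(S)), -1))
    b <- c(b, extra_rhs)
    lb <- c(lb, slack_bounds[1]); ub <- c(ub, slack_bounds[2])
    cc <- c(cc, 0)
  }
  res <- .lp_solve_dense(A, b, cc, lb, ub, maximize)
  if (res$status == 3L) stop("LP iteration limit reached; model too ill-conditioned")
  fluxes <- stats::setNames(res$x[seq_len(n)], model$reactions$id)
  list(status = lp_status(res$status),
       objective = if (res$status == 0L) sum(cost * res$x[seq_len(n)]) else NA_real_,
       fluxes = fluxes)
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) an objective flux subject to steady-state mass
#' balance `S v = 0` and the model's flux bounds. Infeasibility and
#' unboundedness are reported in the solution status, never raised.
#'
#' @param model a `"metabolic_model"`.
#' @param sense `"max"` or `"min"`.
#' @param objective objective reaction id, or a named numeric vector of
#'   objective coefficients over reaction ids; defaults to the model's
#'   objective reaction.
#' @return a `"flux_solution"` with fields `status`
#'   (`optimal`/`infeasible`/`unbounded`), `objective_value` and `fluxes`.
#' @export
fba <- function(model, sense = c("max", "min"), objective = NULL) {
  sense <- match.arg(sense)
  if (is.null(objective)) objective <- model$objective
  if (length(objective) == 1L && is.character(objective)) {
    if (is.na(objective)) stop("no objective set on model and none supplied")
    if (!(objective %in% model$reactions$id))
      stop("objective reaction not in model: ", objective)
    cost <- stats::setNames(numeric(nrow(model$reactions)), model$reactions$id)
    cost[objective] <- 1
  } else {
    cost <- stats::setNames(numeric(nrow(model$reactions)), model$reactions$id)
    cost[names(objective)] <- objective
  }
  r <- model_lp(model, unname(cost), maximize = sense == "max")
  flux_solution(r$status,
                if (r$status == "optimal") r$objective else
                  if (r$status == "infeasible") 0 else NA_real_,
                r$fluxes)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum feasible flux, optionally subject to the
#' model objective staying at or above a fraction of its optimum.
#' `objective_fraction = 0` is a pure feasibility sweep (used for blocked
#' reaction detection).
#'
#' @param model a `"metabolic_model"`.
#' @param reactions reaction ids to scan (default: all).
#' @param objective_fraction number in `[0, 1]`.
#' @return a data.frame (class `"fva_result"`) with columns `reaction`,
#'   `min`, `max`.
#' @export
fva <- function(model, reactions = NULL, objective_fraction = 0) {
  stopifnot(objective_fraction >= 0, objective_fraction <= 1)
  if (is.null(reactions)) reactions <- model$reactions$id
  unknown <- setdiff(reactions, model$reactions$id)
  if (length(unknown)) stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))

  extra_row <- NULL; extra_rhs <- 0; slack <- NULL
  if (objective_fraction > 0) {
    opt <- fba(model)
    if (opt$status != "optimal") stop("model infeasible; cannot run FVA at fraction > 0")
    extra_row <- stats::setNames(1, model$objective)
    extra_rhs <- objective_fraction * opt$objective_value
    slack <- c(0, 2 * BOUND_CLAMP)  # objective >= fraction * optimum
  }
  n <- nrow(model$reactions)
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(reactions)) {
    cost <- numeric(n); cost[match(reactions[k], model$reactions$id)] <- 1
    for (mx in c(FALSE, TRUE)) {
      r <- model_lp(model, cost, maximize = mx, extra_row = extra_row,
                    extra_rhs = extra_rhs, slack_bounds = slack)
      if (r$status != "optimal") stop("FVA subproblem not optimal (", r$status,
                                      ") for reaction ", reactions[k])
      out[[if (mx) "max" else "min"]][k] <- r$objective
    }
  }
  class(out) <- c("fva_result", "data.frame")
  out
}

# feasibility sweep with flux caching: which of `targets` can carry
# |flux| >= tol (exchanges assumed already set by the caller)
carries_flux <- function(model, targets, tol = 1e-6) {
  n <- nrow(model$reactions)
  seen <- stats::setNames(numeric(n), model$reactions$id)
  can <- stats::setNames(logical(length(targets)), targets)
  for (r in targets) {
    if (seen[r] >= tol) { can[r] <- TRUE; next }
    cost <- numeric(n); cost[match(r, model$reactions$id)] <- 1
    for (mx in c(TRUE, FALSE)) {
      sol <- model_lp(model, cost, maximize = mx)
      if (sol$status != "optimal") return(can)  # infeasible model: nothing carries flux
      seen <- pmax(seen, abs(sol$fluxes))
      if (abs(sol$objective) >= tol) break
    }
    can[r] <- seen[r] >= tol
  }
  can
}

#' Blocked reactions and dead-end metabolites
#'
#' A reaction is blocked when its feasible flux range is within `tol` of
#' zero under a pure-feasibility FVA with every exchange fully open. A
#' metabolite is a dead end when, across non-blocked reactions and honouring
#' reaction reversibility, it can only be produced or only consumed (or
#' participates in no unblocked reaction at all).
#'
#' @param model a `"metabolic_model"`.
#' @param tol flux threshold, default `1e-6`.
#' @return list with character vectors `blocked` and `deadends`.
#' @export
blocked_and_deadends <- function(model, tol = 1e-6) {
  open <- set_bounds(model, exchanges(model), lb = -1000, ub = 1000)
  can <- carries_flux(open, open$reactions$id, tol = tol)
  blocked <- names(can)[!can]
  alive <- setdiff(model$reactions$id, blocked)
  cap <- met_capability(model, alive)
  dead <- model$metabolites$id[!(cap$produced & cap$consumed)[model$metabolites$id]]
  list(blocked = blocked, deadends = dead)
}

#' Read a growth-medium definition
#'
#' Media are TSV files with columns `exchange_id`, `lb`, `ub` and
#' `always_open` (logical: exchanges never closed by medium application,
#' e.g. water and protons).
#'
#' @param path TSV file path.
#' @param name medium name (default: file name without extension).
#' @return an object of class `"medium"`.
#' @export
read_medium <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("exchange_id", "lb", "ub", "always_open") %in% names(df)))
  medium(name, df[!df$always_open, c("exchange_id", "lb", "ub")],
         always_open = df$exchange_id[as.logical(df$always_open)])
}

#' Construct a growth medium
#'
#' @param name medium name.
#' @param bounds data.frame with columns `exchange_id`, `lb`, `ub`.
#' @param always_open exchange ids never touched by medium application.
#' @return an object of class `"medium"`.
#' @export
medium <- function(name, bounds, always_open = character(0)) {
  bounds <- as.data.frame(bounds, stringsAsFactors = FALSE)
  stopifnot(all(c("exchange_id", "lb", "ub") %in% names(bounds)),
            all(bounds$lb <= bounds$ub))
  structure(list(name = name, bounds = bounds, always_open = always_open),
            class = "medium")
}

# does the metabolite contain carbon? NA formula -> fall back to the
# organic_ids list (ids compared without compartment suffix)
is_organic_met <- function(model, met_ids, organic_ids = character(0)) {
  idx <- match(met_ids, model$metabolites$id)
  formula <- model$metabolites$formula[idx]
  base <- sub("_[a-z0-9]+$", "", met_ids)
  out <- logical(length(met_ids))
  for (k in seq_along(met_ids)) {
    f <- formula[k]
    if (!is.na(f) && nzchar(f)) {
      els <- regmatches(f, gregexpr("[A-Z][a-z]?", f))[[1L]]
      out[k] <- "C" %in% els
    } else {
      out[k] <- base[k] %in% organic_ids
    }
  }
  out
}

#' Apply a growth medium to a model
#'
#' Exchanges listed in the medium get the medium's bounds; every other
#' exchange has its uptake closed (`lb = 0`) — either all of them
#' (`policy = "all"`) or only those of organic (carbon-containing)
#' metabolites (`policy = "organic_only"`). Exchanges in the medium's
#' `always_open` set are left untouched. Applying the same medium twice is
#' idempotent.
#'
#' @param model a `"metabolic_model"`.
#' @param medium a `"medium"` object.
#' @param policy closure policy for non-medium exchanges.
#' @param organic_ids fallback list of organic metabolite base ids for
#'   metabolites without a formula.
#' @param skip_missing if `TRUE`, medium exchanges absent from the model are
#'   ignored (useful on pruned models) instead of raising an error.
#' @return the constrained model.
#' @export
apply_medium <- function(model, medium, policy = c("organic_only", "all"),
                         organic_ids = character(0), skip_missing = FALSE) {
  policy <- match.arg(policy)
  ex <- exchanges(model)
  ids <- medium$bounds$exchange_id
  missing <- setdiff(ids, ex)
  if (length(missing)) {
    if (!skip_missing) stop("medium exchange id(s) not in model: ",
                            paste(missing, collapse = ", "))
    ids <- setdiff(ids, missing)
  }
  rows <- match(ids, medium$bounds$exchange_id)
  model <- set_bounds(model, ids, lb = medium$bounds$lb[rows],
                      ub = medium$bounds$ub[rows])
  others <- setdiff(ex, c(ids, medium$always_open))
  if (policy == "organic_only" && length(others)) {
    met1 <- vapply(model$stoichiometry[others], function(s) names(s)[1L], "")
    others <- others[is_organic_met(model, met1, organic_ids)]
  }
  if (length(others)) {
    idx <- match(others, model$reactions$id)
    # close uptake; pmin keeps lb <= ub if an exchange has a negative ub
    model$reactions$lb[idx] <- pmin(0, model$reactions$ub[idx])
  }
  model
}

#' Constrain reactions disabled by a gene knockout
#'
#' Every reaction whose GPR evaluates `TRUE` with all genes present but
#' `FALSE` once the deleted genes are removed gets `lb = ub = 0`; all other
#' reactions are untouched (isozymes rescue OR rules, complexes break on
#' AND rules).
#'
#' @param model a `"metabolic_model"`.
#' @param genes gene id(s) to delete.
#' @return the constrained model, with attribute `"disabled_reactions"`.
#' @export
knockout_bounds <- function(model, genes) {
  all_genes <- model_genes(model)
  unknown <- setdiff(genes, all_genes)
  if (length(unknown)) stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  remaining <- setdiff(all_genes, genes)
  hit <- character(0)
  for (r in model$reactions$id) {
    g <- model$gpr[[r]]
    if (g$type == "empty") next
    if (!any(genes %in% gpr_genes(g))) next
    if (eval_gpr(g, all_genes) && !eval_gpr(g, remaining)) hit <- c(hit, r)
  }
  if (length(hit)) model <- set_bounds(model, hit, lb = 0, ub = 0)
  attr(model, "disabled_reactions") <- hit
  model
}
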