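# Minimal/maximal model assembly: flux-consistency extraction, a
# FASTCORE-style LP gap-filler that rescues core reactions with a compact
# set of non-core candidates, and the final min/max assembly step.

#' Restrict a model to its flux-consistent subnetwork
#'
#' Removes blocked reactions and iterates to a fixed point, mirroring how a
#' flux-consistent reference model is derived from its extended version.
#'
#' @param model a `"metabolic_model"`.
#' @param tol blocked-reaction flux threshold.
#' @return the consistent submodel; empty-reaction models yield a warning.
#' @export
consistent_subnetwork <- function(model, tol = 1e-6) {
  repeat {
    if (nrow(model$reactions) == 0L) {
      warning("all reactions blocked; returning empty model")
      return(model)
    }
    bd <- blocked_and_deadends(model, tol = tol)
    if (length(bd$blocked) == 0L) return(model)
    model <- remove_reactions(model, bd$blocked)
  }
}

# can every id in `core` individually carry |flux| >= eps in `net`?
# returns named logical; shares discovered fluxes across solves
certify_cores <- function(net, core, eps) {
  n <- nrow(net$reactions)
  seen <- stats::setNames(numeric(n), net$reactions$id)
  ok <- stats::setNames(logical(length(core)), core)
  for (r in core) {
    if (!(r %in% net$reactions$id)) next
    if (seen[r] >= eps) { ok[r] <- TRUE; next }
    cost <- numeric(n); cost[match(r, net$reactions$id)] <- 1
    for (mx in c(TRUE, FALSE)) {
      sol <- model_lp(net, cost, maximize = mx)
      if (sol$status != "optimal") break
      seen <- pmax(seen, abs(sol$fluxes))
      if (abs(sol$objective) >= eps) break
    }
    ok[r] <- seen[r] >= eps
  }
  ok
}

# one L1 support-minimization LP: force |v[target]| >= eps (direction given)
# over the network, penalizing |v| of candidate reactions by weight.
# Returns NULL if infeasible, else the flux vector.
gapfill_lp <- function(net, target, forward, penalized, weights, eps) {
  S <- stoichiometry_matrix(net)
  m <- nrow(S); n <- ncol(S)
  rid <- colnames(S)
  lb <- pmax(net$reactions$lb, -BOUND_CLAMP)
  ub <- pmin(net$reactions$ub, BOUND_CLAMP)
  ti <- match(target, rid)
  if (forward) lb[ti] <- max(lb[ti], eps) else ub[ti] <- min(ub[ti], -eps)
  if (lb[ti] > ub[ti]) return(NULL)

  p <- length(penalized)
  # vars: v (n), z (p), s1 (p), s2 (p); rows: S v = 0 (m),
  # v_c - z_c + s1_c = 0, -v_c - z_c + s2_c = 0  (z_c >= |v_c|)
  nv <- n + 3L * p
  A <- matrix(0, m + 2L * p, nv)
  A[seq_len(m), seq_len(n)] <- S
  ci <- match(penalized, rid)
  for (k in seq_len(p)) {
    r1 <- m + 2L * k - 1L; r2 <- m + 2L * k
    A[r1, ci[k]] <- 1;  A[r1, n + k] <- -1; A[r1, n + p + k] <- 1
    A[r2, ci[k]] <- -1; A[r2, n + k] <- -1; A[r2, n + 2L * p + k] <- 1
  }
  lbx <- c(lb, rep(0, 3L * p))
  ubx <- c(ub, rep(2 * BOUND_CLAMP, 3L * p))
  cost <- c(numeric(n), weights, numeric(2L * p))
  res <- .lp_solve_dense(A, rep(0, m + 2L * p), cost, lbx, ubx, FALSE)
  if (res$status != 0L) return(NULL)
  stats::setNames(res$x[seq_len(n)], rid)
}

#' Gap-fill a core reaction set from non-core candidates
#'
#' Finds a compact subset of candidate (non-core) reactions such that every
#' core reaction can individually carry flux of at least `epsilon` in the
#' assembled network — an LP sweep in the FASTCORE style (L1 penalty on
#' candidate usage) followed by a compaction pass that drops any added
#' reaction whose removal leaves all cores fillable. The result is
#' inclusion-compact: no added reaction is redundant. Global
#' minimum-cardinality is not guaranteed by the LP (it is checked against
#' exhaustive enumeration on small instances in the test suite).
#'
#' @param model model containing at least `core` and `candidates` (other
#'   reactions are ignored).
#' @param core reaction ids that must carry flux.
#' @param candidates non-core reaction ids available for addition (default:
#'   all non-core reactions of the model).
#' @param weights named numeric selection costs per candidate (default 1;
#'   weight 0 marks candidates that are always admissible, e.g. reactions
#'   required for reference-model consistency).
#' @param epsilon minimum absolute flux certifying a core reaction.
#' @param open_exchanges open all exchange bounds to (-1000, 1000) before
#'   gap-filling (media are applied downstream, not here).
#' @return an object of class `"gapfill_result"`: `added` (in order of
#'   addition), `epsilon`, `certified_consistent`, `unfillable`.
#' @export
minimal_gapfill <- function(model, core, candidates = NULL, weights = NULL,
                            epsilon = 1e-4, open_exchanges = TRUE) {
  if (is.null(candidates)) candidates <- setdiff(model$reactions$id, core)
  stopifnot(length(intersect(core, candidates)) == 0L)
  universe <- c(core, candidates)
  unknown <- setdiff(universe, model$reactions$id)
  if (length(unknown)) stop("unknown reaction id(s): ", paste(unknown, collapse = ", "))
  net_all <- subset_reactions(model, universe)
  if (open_exchanges)
    net_all <- set_bounds(net_all, exchanges(net_all), lb = -1000, ub = 1000)
  w <- stats::setNames(rep(1, length(candidates)), candidates)
  if (!is.null(weights)) w[names(weights)] <- weights

  core <- sort(core)
  candidates <- sort(candidates)
  added <- character(0)
  unfillable <- character(0)

  net_of <- function(add) subset_reactions(net_all, c(core, add))

  # which cores are already fine with no candidates at all?
  ok <- certify_cores(net_of(added), core, epsilon)
  todo <- names(ok)[!ok]

  for (r in todo) {
    # might already be rescued by candidates added for an earlier core
    if (length(added)) {
      if (all(certify_cores(net_of(added), r, epsilon))) next
    }
    pen <- setdiff(candidates, added)
    v <- gapfill_lp(net_all, r, forward = TRUE, penalized = pen,
                    weights = unname(w[pen]), eps = epsilon)
    if (is.null(v))
      v <- gapfill_lp(net_all, r, forward = FALSE, penalized = pen,
                      weights = unname(w[pen]), eps = epsilon)
    if (is.null(v)) { unfillable <- c(unfillable, r); next }
    used <- pen[abs(v[pen]) > 1e-7]
    added <- c(added, used)
  }

  # compaction: drop any added reaction whose removal keeps all cores
  # fillable; scan expensive candidates first, ties lexicographic
  fillable <- setdiff(core, unfillable)
  repeat {
    scan <- added[order(-w[added], added)]
    dropped <- FALSE
    for (a in scan) {
      rest <- setdiff(added, a)
      if (all(certify_cores(net_of(rest), fillable, epsilon))) {
        added <- rest
        dropped <- TRUE
      }
    }
    if (!dropped) break
  }

  certified <- length(unfillable) == 0L &&
    all(certify_cores(net_of(added), core, epsilon))
  structure(list(added = added, epsilon = epsilon,
                 certified_consistent = certified,
                 unfillable = sort(unfillable), weights = w),
            class = "gapfill_result")
}

#' @export
print.gapfill_result <- function(x, ...) {
  cat("Gap-fill result:", length(x$added), "reaction(s) added",
      sprintf("(epsilon %g)", x$epsilon), "\n")
  if (length(x$unfillable))
    cat("  unfillable core reactions:", paste(x$unfillable, collapse = ", "), "\n")
  cat("  certified consistent:", x$certified_consistent, "\n")
  invisible(x)
}

#' Assemble minimal and maximal models
#'
#' The minimal model is core plus the gap-filled non-core subset; the
#' maximal model is core plus all non-core reactions. Gene-associated
#' reaction sets (and hence gene sets) are identical between the two by
#' construction: the non-core set carries no gene associations.
#'
#' @param model the translated, curated model (the `model` field of a
#'   `"core_partition"`).
#' @param partition a `"core_partition"` over `model`.
#' @param gapfill a `"gapfill_result"` whose `added` set is a subset of the
#'   partition's non-core set.
#' @return list with `min_model` and `max_model`.
#' @export
assemble_models <- function(model, partition, gapfill) {
  if (!setequal(c(partition$core, partition$non_core), model$reactions$id))
    stop("partition does not cover the model's reactions")
  stray <- setdiff(gapfill$added, partition$non_core)
  if (length(stray))
    stop("gap-fill added reaction(s) outside the partition's non-core set: ",
         paste(stray, collapse = ", "))
  min_model <- subset_reactions(model, c(partition$core, gapfill$added))
  max_model <- subset_reactions(model, c(partition$core, partition$non_core))
  min_model$id <- paste0(model$id, "_min")
  max_model$id <- paste0(model$id, "_max")
  list(min_model = min_model, max_model = max_model)
}

#' Write a gap-fill result as TSV
#'
#' @param x a `"gapfill_result"`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_gapfill <- function(x, path) {
  df <- data.frame(reaction_id = x$added,
                   weight = unname(x$weights[x$added]),
                   order_added = seq_along(x$added))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
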