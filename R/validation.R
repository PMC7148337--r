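# Functional validation: metabolite conversion tests (MCTs) and reaction
# optimization tests (ROTs) with the three-mode failure taxonomy:
# missing_component (a participating metabolite or the objective reaction is
# absent), infeasible (no optimal solution), zero_objective (optimum ~ 0).

#' Define a functional test
#'
#' @param id test identifier.
#' @param kind `"MCT"` (source -> target conversion under a medium) or
#'   `"ROT"` (a named reaction must carry non-zero optimized flux under a
#'   closure condition).
#' @param sources metabolite ids. For MCTs, the supplied substrates; for
#'   ROTs, substrates whose exchanges stay open under the closure.
#' @param targets metabolite ids to produce (MCT only, >= 1).
#' @param medium medium name (MCT only).
#' @param objective_reaction reaction id to optimize (ROT only).
#' @param condition `"aerobic"` or `"anaerobic"` (ROT only).
#' @param policy exchange-closure policy (ROT only).
#' @return an object of class `"functional_test"`.
#' @export
functional_test <- function(id, kind = c("MCT", "ROT"), sources = character(0),
                            targets = character(0), medium = NULL,
                            objective_reaction = NULL,
                            condition = c("aerobic", "anaerobic"),
                            policy = c("organic_only", "all")) {
  kind <- match.arg(kind)
  if (kind == "MCT") {
    stopifnot(length(sources) >= 1L, length(targets) >= 1L, !is.null(medium))
  } else {
    stopifnot(length(objective_reaction) == 1L)
  }
  structure(list(id = id, kind = kind, sources = sources, targets = targets,
                 medium = medium, objective_reaction = objective_reaction,
                 condition = match.arg(condition), policy = match.arg(policy)),
            class = "functional_test")
}

#' Read a functional-test battery from JSON
#'
#' @param path JSON file: an array of objects with fields `id`, `kind`,
#'   `sources`, `targets`, `medium`, `objective_reaction`, `condition`.
#' @return list of `"functional_test"` objects.
#' @export
read_test_battery <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(j, function(t)
    functional_test(id = t$id, kind = t$kind,
                    sources = as.character(unlist(t$sources)),
                    targets = as.character(unlist(t$targets)),
                    medium = t$medium %||% NULL,
                    objective_reaction = t$objective_reaction %||% NULL,
                    condition = t$condition %||% "aerobic",
                    policy = t$policy %||% "organic_only"))
}

#' Write a functional-test battery to JSON
#'
#' @param tests list of `"functional_test"` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_test_battery <- function(tests, path) {
  jsonlite::write_json(lapply(tests, unclass), path, auto_unbox = TRUE,
                       null = "null", digits = NA, pretty = TRUE)
  invisible(path)
}

test_result <- function(id, kind, status, failure_mode, objective_value) {
  structure(list(id = id, kind = kind, status = status,
                 failure_mode = failure_mode, objective_value = objective_value),
            class = "test_result")
}

# boundary reaction touching exactly this metabolite, if any
boundary_for <- function(model, met) {
  ex <- exchanges(model)
  hit <- ex[vapply(model$stoichiometry[ex],
                   function(s) identical(names(s), met), NA)]
  if (length(hit)) hit[1L] else NA_character_
}

#' Run a metabolite conversion test
#'
#' Applies the named medium, supplies each source metabolite through a
#' reversible sink (added only when no boundary reaction for it exists,
#' otherwise the existing one is opened), consumes each target through a
#' demand reaction, and maximizes total target demand. The test passes when
#' the aggregate optimum and every individual target demand exceed `tol`.
#' The input model is never mutated; all test scaffolding is local.
#'
#' @param model a `"metabolic_model"`.
#' @param test a `"functional_test"` of kind MCT.
#' @param media named list of `"medium"` objects (looked up by the test's
#'   medium name).
#' @param tol "almost zero" threshold.
#' @return a `"test_result"`.
#' @export
run_mct <- function(model, test, media, tol = 1e-6) {
  stopifnot(test$kind == "MCT")
  med <- media[[test$medium]]
  if (is.null(med)) stop("unknown medium name: ", test$medium)

  absent <- setdiff(c(test$sources, test$targets), model$metabolites$id)
  if (length(absent))
    return(test_result(test$id, "MCT", "fail", "missing_component", 0))

  m <- apply_medium(model, med, skip_missing = TRUE)
  for (s in test$sources) {
    b <- boundary_for(m, s)
    if (is.na(b)) m <- add_reaction(m, paste0("SK_", s, "__mct"),
                                    stats::setNames(-1, s), lb = -1000, ub = 1000)
    else m <- set_bounds(m, b, lb = -1000, ub = 1000)
  }
  dm <- character(0)
  for (t in test$targets) {
    b <- boundary_for(m, t)
    if (is.na(b)) {
      b <- paste0("DM_", t, "__mct")
      m <- add_reaction(m, b, stats::setNames(-1, t), lb = 0, ub = 1000)
    } else m <- set_bounds(m, b, ub = 1000)
    dm <- c(dm, b)
  }
  obj <- stats::setNames(rep(1, length(dm)), dm)
  sol <- fba(m, objective = obj)
  if (sol$status != "optimal")
    return(test_result(test$id, "MCT", "fail", "infeasible", 0))
  if (sol$objective_value <= tol)
    return(test_result(test$id, "MCT", "fail", "zero_objective", sol$objective_value))
  # each target must be individually producible, not just the aggregate
  for (b in dm) {
    s1 <- fba(m, objective = stats::setNames(1, b))
    if (s1$status != "optimal" || s1$objective_value <= tol)
      return(test_result(test$id, "MCT", "fail", "zero_objective", sol$objective_value))
  }
  test_result(test$id, "MCT", "pass", "none", sol$objective_value)
}

#' Run a reaction optimization test
#'
#' Closes exchanges per the test's policy (by default the uptake of every
#' organic exchange) except those of the test's source metabolites, which
#' are opened at a fixed substrate dose, opens the oxygen exchange only
#' under aerobic conditions, and maximizes the objective reaction. The fixed
#' dose makes the optimum a yield, so aerobic and anaerobic optima are
#' comparable instead of both saturating the objective's own bound.
#'
#' @param model a `"metabolic_model"`.
#' @param test a `"functional_test"` of kind ROT.
#' @param tol "almost zero" threshold.
#' @param oxygen_pattern regular expression identifying oxygen metabolite
#'   ids (matched against the id without compartment suffix).
#' @param dose substrate uptake allowance (mmol/gDW/h) for the source
#'   exchanges.
#' @return a `"test_result"`.
#' @export
run_rot <- function(model, test, tol = 1e-6, oxygen_pattern = "^o2$",
                    dose = 10) {
  stopifnot(test$kind == "ROT")
  if (!(test$objective_reaction %in% model$reactions$id))
    return(test_result(test$id, "ROT", "fail", "missing_component", 0))

  m <- model
  ex <- exchanges(m)
  met1 <- vapply(m$stoichiometry[ex], function(s) names(s)[1L], "")
  base <- sub("_[a-z0-9]+$", "", met1)
  is_o2 <- grepl(oxygen_pattern, base)
  keep_open <- met1 %in% test$sources
  to_close <- if (test$policy == "all") rep(TRUE, length(ex))
              else is_organic_met(m, met1)
  to_close <- (to_close | is_o2) & !keep_open
  if (any(to_close)) {
    idx <- match(ex[to_close], m$reactions$id)
    m$reactions$lb[idx] <- pmin(0, m$reactions$ub[idx])
  }
  if (any(keep_open))
    m <- set_bounds(m, ex[keep_open], lb = -abs(dose))
  if (test$condition == "aerobic" && any(is_o2))
    m <- set_bounds(m, ex[is_o2], lb = -1000)

  sol <- fba(m, objective = test$objective_reaction)
  if (sol$status != "optimal")
    return(test_result(test$id, "ROT", "fail", "infeasible", 0))
  if (sol$objective_value <= tol)
    return(test_result(test$id, "ROT", "fail", "zero_objective", sol$objective_value))
  test_result(test$id, "ROT", "pass", "none", sol$objective_value)
}

#' Run a battery of functional tests
#'
#' @param model a `"metabolic_model"`.
#' @param tests list of `"functional_test"` objects.
#' @param media named list of `"medium"` objects for MCTs.
#' @param tol "almost zero" threshold.
#' @return an object of class `"validation_summary"`: `results` (data.frame
#'   of per-test outcomes), `counts` (pass/fail by kind and failure mode)
#'   and `restricted` — the same tally limited to tests whose participating
#'   components (metabolites / objective reaction) are present in the model.
#' @export
run_suite <- function(model, tests, media = list(), tol = 1e-6) {
  rows <- lapply(tests, function(t) {
    r <- if (t$kind == "MCT") run_mct(model, t, media, tol) else run_rot(model, t, tol)
    present <- if (t$kind == "MCT")
      all(c(t$sources, t$targets) %in% model$metabolites$id)
    else t$objective_reaction %in% model$reactions$id
    data.frame(id = r$id, kind = r$kind, status = r$status,
               failure_mode = r$failure_mode, objective_value = r$objective_value,
               components_present = present, stringsAsFactors = FALSE)
  })
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), kind = character(0), status = character(0),
               failure_mode = character(0), objective_value = numeric(0),
               components_present = logical(0))
  tally <- function(df) {
    list(n = nrow(df), passed = sum(df$status == "pass"),
         failed_missing_component = sum(df$failure_mode == "missing_component"),
         failed_infeasible = sum(df$failure_mode == "infeasible"),
         failed_zero_objective = sum(df$failure_mode == "zero_objective"))
  }
  counts <- list(MCT = tally(results[results$kind == "MCT", , drop = FALSE]),
                 ROT = tally(results[results$kind == "ROT", , drop = FALSE]),
                 all = tally(results))
  restricted <- tally(results[results$components_present, , drop = FALSE])
  structure(list(results = results, counts = counts, restricted = restricted),
            class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat("Functional validation:", x$counts$all$passed, "of", x$counts$all$n,
      "tests passed\n")
  cat("  MCT:", x$counts$MCT$passed, "/", x$counts$MCT$n,
      " ROT:", x$counts$ROT$passed, "/", x$counts$ROT$n, "\n")
  cat("  restricted to tests with all components present:",
      x$restricted$passed, "/", x$restricted$n, "\n")
  invisible(x)
}

#' Write a validation summary as TSV
#'
#' @param x a `"validation_summary"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_validation <- function(x, path) {
  utils::write.table(x$results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
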