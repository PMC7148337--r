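# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately avoid the package's own evaluation / analysis code
# paths: Boolean truths go through R's own expression evaluator, LP truths
# through brute-force vertex enumeration of the flux polytope, and gap-fill
# truths through exhaustive subset enumeration over directly assembled LPs.

# ---- Boolean oracle ---------------------------------------------------------

# evaluate a GPR *string* with R's own parser/evaluator: genes become logical
# variables, "and"/"or" become &/| (R's & binds tighter than |, matching the
# grammar under test)
oracle_eval_string <- function(text, present, genes) {
  if (!nzchar(trimws(text))) return(TRUE)
  ex <- gsub("\\band\\b", "&", text, ignore.case = TRUE)
  ex <- gsub("\\bor\\b", "|", ex, ignore.case = TRUE)
  for (g in genes)  # backtick-quote gene tokens (ids may be numerals)
    ex <- gsub(paste0("(?<![A-Za-z0-9_])", g, "(?![A-Za-z0-9_])"),
               paste0("`", g, "`"), ex, perl = TRUE)
  env <- list2env(as.list(stats::setNames(genes %in% present, genes)),
                  parent = baseenv())
  isTRUE(eval(parse(text = ex), envir = env))
}

# random GPR string over the given genes
random_gpr_string <- function(genes, n_ops = 3) {
  pick <- function() sample(genes, 1)
  s <- pick()
  for (i in seq_len(n_ops)) {
    op <- sample(c("and", "or"), 1)
    nxt <- pick()
    s <- if (stats::runif(1) < 0.4) sprintf("(%s) %s %s", s, op, nxt)
         else sprintf("%s %s %s", s, op, nxt)
  }
  s
}

# ---- LP oracle --------------------------------------------------------------

# brute-force LP over the bounded polytope {Ax = b, lb <= x <= ub}: enumerate
# every basic solution (m basic columns, nonbasic at each bound combination).
# Requires A to have full row rank; returns NULL objective when infeasible.
brute_lp <- function(A, b, cost, lb, ub, maximize) {
  m <- nrow(A); n <- ncol(A)
  best <- NULL
  combs <- utils::combn(n, m)
  for (k in seq_len(ncol(combs))) {
    B <- combs[, k]
    AB <- A[, B, drop = FALSE]
    if (abs(det(AB)) < 1e-10) next
    N <- setdiff(seq_len(n), B)
    nn <- length(N)
    for (mask in seq_len(2^nn) - 1L) {
      xN <- numeric(nn)
      for (i in seq_len(nn))
        xN[i] <- if (bitwAnd(mask, bitwShiftL(1L, i - 1L)) > 0) ub[N[i]] else lb[N[i]]
      rhs <- b - if (nn) A[, N, drop = FALSE] %*% xN else 0
      xB <- solve(AB, rhs)
      if (any(xB < lb[B] - 1e-7) || any(xB > ub[B] + 1e-7)) next
      v <- sum(cost[B] * xB) + if (nn) sum(cost[N] * xN) else 0
      if (is.null(best) || (maximize && v > best) || (!maximize && v < best))
        best <- v
    }
  }
  best
}

brute_fba <- function(model, maximize = TRUE, objective = model$objective) {
  S <- stoichiometry_matrix(model)
  cost <- numeric(ncol(S))
  cost[match(objective, colnames(S))] <- 1
  brute_lp(S, rep(0, nrow(S)), cost, model$reactions$lb, model$reactions$ub,
           maximize)
}

# ---- fixture models ---------------------------------------------------------

# linear chain: EX_A (uptake up to `uptake`) -> A -> ... -> obj sink
chain_model <- function(len = 2, uptake = 10) {
  mets <- data.frame(id = paste0("m", seq_len(len), "_c"), formula = "CH2O")
  st <- list(EX_A = stats::setNames(-1, "m1_c"))
  rx <- data.frame(id = "EX_A", lb = -uptake, ub = 0)
  for (k in seq_len(len - 1)) {
    id <- paste0("R", k)
    rx <- rbind(rx, data.frame(id = id, lb = 0, ub = 1000))
    st[[id]] <- stats::setNames(c(-1, 1), c(paste0("m", k, "_c"),
                                            paste0("m", k + 1, "_c")))
  }
  rx <- rbind(rx, data.frame(id = "OBJ", lb = 0, ub = 1000))
  st[["OBJ"]] <- stats::setNames(-1, paste0("m", len, "_c"))
  metabolic_model(id = "chain", metabolites = mets, reactions = rx,
                  stoichiometry = st, objective = "OBJ")
}

# branched fixture: one uptake feeding two alternative routes to the
# objective plus a side branch to a secretion
branched_model <- function() {
  mets <- data.frame(id = c("a_c", "b_c", "c_c", "d_c", "e_c"),
                     formula = "CH2O")
  rx <- data.frame(id = c("EX_A", "R1", "R2a", "R2b", "R3", "R4", "EX_E", "OBJ"),
                   lb = c(-10, 0, 0, 0, 0, 0, 0, 0),
                   ub = c(0, 1000, 1000, 1000, 1000, 1000, 1000, 1000))
  st <- list(EX_A = c(a_c = -1),
             R1 = c(a_c = -1, b_c = 1),
             R2a = c(b_c = -1, c_c = 1),
             R2b = c(b_c = -1, c_c = 1),
             R3 = c(c_c = -1, d_c = 1),
             R4 = c(b_c = -1, e_c = 1),
             EX_E = c(e_c = -1),
             OBJ = c(d_c = -1))
  metabolic_model(id = "branched", metabolites = mets, reactions = rx,
                  stoichiometry = st,
                  gpr = list(R1 = "g1", R2a = "g2 or g3", R2b = "g3",
                             R3 = "g4 and g5", R4 = "g6"),
                  objective = "OBJ")
}

# random small network with full-row-rank S (so the vertex oracle is exact);
# deterministic in `seed`
random_lp_model <- function(seed, n = 8, m = 5) {
  set.seed(seed)
  repeat {
    S <- matrix(0, m, n)
    for (j in seq_len(n)) {
      rows <- sample(m, sample(1:2, 1))
      S[rows, j] <- sample(c(-1, 1), length(rows), replace = TRUE)
    }
    if (qr(S)$rank == m) break
  }
  mets <- data.frame(id = paste0("x", seq_len(m), "_c"))
  rx <- data.frame(id = paste0("v", seq_len(n)),
                   lb = ifelse(stats::runif(n) < 0.5, -10, 0), ub = 10)
  st <- lapply(seq_len(n), function(j) {
    s <- S[, j]; stats::setNames(s[s != 0], mets$id[s != 0])
  })
  names(st) <- rx$id
  metabolic_model(id = paste0("rand", seed), metabolites = mets,
                  reactions = rx, stoichiometry = st, objective = "v1")
}

# ---- gap-fill oracle --------------------------------------------------------

# can every core reaction individually carry |flux| >= eps in the network
# restricted to core+subset with exchanges open? LP assembled directly.
cert_direct <- function(model, keep, core, eps) {
  sub <- model$reactions$id %in% keep
  rxns <- model$reactions$id[sub]
  mets <- unique(unlist(lapply(model$stoichiometry[rxns], names)))
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (r in rxns) S[names(model$stoichiometry[[r]]), r] <- model$stoichiometry[[r]]
  lb <- model$reactions$lb[sub]; ub <- model$reactions$ub[sub]
  nmet <- vapply(model$stoichiometry[rxns], length, 0L)
  lb[nmet == 1L] <- -1000; ub[nmet == 1L] <- 1000
  for (r in intersect(core, rxns)) {
    cost <- numeric(length(rxns)); cost[match(r, rxns)] <- 1
    hi <- gemrecon:::.lp_solve_dense(S, rep(0, nrow(S)), cost, lb, ub, TRUE)
    if (hi$status == 0L && hi$objective >= eps) next
    lo <- gemrecon:::.lp_solve_dense(S, rep(0, nrow(S)), cost, lb, ub, FALSE)
    if (!(lo$status == 0L && lo$objective <= -eps)) return(FALSE)
  }
  all(core %in% rxns)
}

# exhaustive minimum-cardinality gap-fill by subset enumeration in
# increasing cardinality
brute_gapfill_min <- function(model, core, candidates, eps) {
  for (k in 0:length(candidates)) {
    sets <- if (k == 0) list(character(0)) else
      utils::combn(candidates, k, simplify = FALSE)
    for (s in sets)
      if (cert_direct(model, c(core, s), core, eps)) return(k)
  }
  NA_integer_
}

# seeded gap-fill instance: a linear backbone with some interior reactions
# missing from the core (the true fill), plus decoy candidates
gapfill_instance <- function(seed, len = 6, n_decoys = 8) {
  set.seed(seed)
  mets <- data.frame(id = paste0("g", seq_len(len), "_c"))
  rx <- data.frame(id = c("EX_in", "EX_out"), lb = c(-10, 0), ub = c(0, 1000))
  st <- list(EX_in = stats::setNames(-1, "g1_c"),
             EX_out = stats::setNames(-1, paste0("g", len, "_c")))
  backbone <- character(0)
  for (k in seq_len(len - 1)) {
    id <- paste0("B", k)
    rx <- rbind(rx, data.frame(id = id, lb = 0, ub = 1000))
    st[[id]] <- stats::setNames(c(-1, 1), paste0("g", c(k, k + 1), "_c"))
    backbone <- c(backbone, id)
  }
  n_gaps <- sample(1:3, 1)
  gaps <- sample(backbone, n_gaps)
  decoys <- character(0)
  for (d in seq_len(n_decoys)) {
    id <- paste0("D", d)
    kind <- sample(c("parallel", "dead", "cross"), 1)
    if (kind == "parallel") {
      tpl <- sample(backbone, 1)
      st[[id]] <- st[[tpl]]
    } else if (kind == "dead") {
      nm <- paste0("dead", d, "_c")
      mets <- rbind(mets, data.frame(id = nm))
      st[[id]] <- stats::setNames(c(-1, 1), c(sample(mets$id[seq_len(len)], 1), nm))
    } else {
      pair <- sample(len, 2)
      st[[id]] <- stats::setNames(c(-1, 1), paste0("g", pair, "_c"))
    }
    rx <- rbind(rx, data.frame(id = id, lb = 0, ub = 1000))
    decoys <- c(decoys, id)
  }
  model <- metabolic_model(id = paste0("gf", seed), metabolites = mets,
                           reactions = rx, stoichiometry = st,
                           objective = NA_character_)
  list(model = model,
       core = c("EX_in", "EX_out", setdiff(backbone, gaps)),
       candidates = c(gaps, decoys),
       planted = sort(gaps))
}

# media list for the synthetic reference namespace
synthetic_media <- function() list(HAM = example_medium("HAM"),
                                   RPMI1640 = example_medium("RPMI1640"))

# direct FBA: assembles the LP straight from the stoichiometry table and
# calls the low-level solver, bypassing fba()/model_lp()
brute_direct_fba <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (r in rxns) S[names(model$stoichiometry[[r]]), r] <- model$stoichiometry[[r]]
  cost <- numeric(length(rxns))
  cost[match(model$objective, rxns)] <- 1
  res <- gemrecon:::.lp_solve_dense(S, rep(0, length(mets)), cost,
                                    model$reactions$lb, model$reactions$ub, TRUE)
  if (res$status != 0L) 0 else res$objective
}
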