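# FBA / FVA / blocked reactions / media / knockouts

test_that("FBA solves hand-computable fixtures", {
  m <- chain_model(3, uptake = 10)
  sol <- fba(m)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)
  # steady state holds at the optimum
  S <- stoichiometry_matrix(m)
  expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
  # all exchanges closed -> optimum 0
  closed <- set_bounds(m, "EX_A", lb = 0, ub = 0)
  expect_equal(fba(closed)$objective_value, 0)
  # min sense
  expect_equal(fba(m, sense = "min")$objective_value, 0)
})

test_that("FBA matches brute-force vertex enumeration on random networks", {
  for (seed in 1:12) {
    m <- random_lp_model(seed)
    sol <- fba(m)
    expect_identical(sol$status, "optimal")
    expect_equal(sol$objective_value,
                 brute_fba(m, maximize = TRUE), tolerance = 1e-7,
                 info = paste("seed", seed))
    S <- stoichiometry_matrix(m)
    expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
  }
})

test_that("FBA optimum is invariant under reaction and metabolite reordering", {
  m <- branched_model()
  v0 <- fba(m)$objective_value
  set.seed(3)
  perm <- sample(nrow(m$reactions))
  m2 <- m
  m2$reactions <- m2$reactions[perm, ]
  m2$stoichiometry <- m2$stoichiometry[m2$reactions$id]
  m2$gpr <- m2$gpr[m2$reactions$id]
  m2$metabolites <- m2$metabolites[sample(nrow(m2$metabolites)), ]
  expect_equal(fba(m2)$objective_value, v0)
})

test_that("FVA equals per-reaction FBA pairs and respects fixed bounds", {
  m <- branched_model()
  fv <- fva(m, objective_fraction = 0)
  for (k in seq_len(nrow(fv))) {
    r <- fv$reaction[k]
    expect_equal(fv$min[k], fba(m, "min", objective = r)$objective_value,
                 tolerance = 1e-7, info = r)
    expect_equal(fv$max[k], fba(m, "max", objective = r)$objective_value,
                 tolerance = 1e-7, info = r)
  }
  expect_true(all(fv$min <= fv$max + 1e-9))
  # a pinned reaction has a degenerate range
  m2 <- set_bounds(chain_model(3), "R1", lb = 5, ub = 5)
  fv2 <- fva(m2, reactions = "R1")
  expect_equal(unlist(fv2[, c("min", "max")]), c(min = 5, max = 5))
  # chain at fraction 0: every reaction spans (0, 10) in absolute value
  fv3 <- fva(chain_model(3))
  expect_equal(fv3$max[fv3$reaction == "OBJ"], 10)
})

test_that("FVA at objective fraction 1 pins the optimum; feasible points stay in range", {
  m <- branched_model()
  opt <- fba(m)$objective_value
  fv <- fva(m, reactions = "OBJ", objective_fraction = 1)
  expect_equal(fv$min, opt, tolerance = 1e-6)
  expect_equal(fv$max, opt, tolerance = 1e-6)
  # sampled feasible flux vectors fall inside fraction-0 FVA ranges
  fv0 <- fva(m)
  set.seed(5)
  for (i in 1:50) {
    w <- stats::setNames(stats::runif(nrow(m$reactions), -1, 1), m$reactions$id)
    v <- fba(m, objective = w)$fluxes
    expect_true(all(v >= fv0$min - 1e-6 & v <= fv0$max + 1e-6))
  }
})

test_that("blocked reactions and dead-end metabolites are detected", {
  # orphan branch: produced, never consumed
  m <- branched_model()
  m <- add_reaction(m, "R5", c(b_c = -1, f_c = 1), lb = 0, ub = 1000,
                    new_metabolites = data.frame(id = "f_c"))
  bd <- blocked_and_deadends(m)
  expect_identical(bd$blocked, "R5")
  expect_identical(bd$deadends, "f_c")
  # fully consistent chain: both empty
  bd2 <- blocked_and_deadends(chain_model(4))
  expect_length(bd2$blocked, 0L)
  expect_length(bd2$deadends, 0L)
  # planted orphans in random synthetic models are recovered exactly
  ref <- make_reference_model(synthetic_config(seed = 5))
  for (k in 1:3) {
    plant <- paste0("orph", k, "_c")
    ref2 <- add_reaction(ref, paste0("ORPH", k),
                         stats::setNames(c(-1, 1), c("pyr_c", plant)),
                         lb = 0, ub = 1000,
                         new_metabolites = data.frame(id = plant))
    bd3 <- blocked_and_deadends(ref2)
    expect_identical(bd3$blocked, paste0("ORPH", k))
    expect_identical(bd3$deadends, plant)
    # blocked set only grows when bounds are tightened
    tight <- set_bounds(ref2, "LDH", lb = 0, ub = 0)
    expect_true(all(bd3$blocked %in% blocked_and_deadends(tight)$blocked))
  }
})

test_that("media application closes non-medium uptake per policy, idempotently", {
  m <- make_reference_model(synthetic_config(seed = 1))
  ham <- example_medium("HAM")
  m1 <- apply_medium(m, ham)
  # organics closed, inorganic non-medium exchanges untouched
  expect_equal(m1$reactions$lb[m1$reactions$id == "EX_lac__L_e"], 0)
  expect_equal(m1$reactions$lb[m1$reactions$id == "EX_glc__D_e"], -1000)
  m2 <- apply_medium(m1, ham)
  expect_identical(m1, m2)
  # policy "all" closes everything not listed / always-open
  m3 <- apply_medium(m, ham, policy = "all")
  ex <- exchanges(m3)
  closed <- setdiff(ex, c(ham$bounds$exchange_id, ham$always_open))
  expect_true(all(m3$reactions$lb[match(closed, m3$reactions$id)] == 0))
  expect_error(apply_medium(chain_model(2), ham), "not in model")
  expect_gt(fba(m1)$objective_value, 0)  # fixture grows on HAM
})

test_that("gene knockouts constrain exactly the GPR-falsified reactions", {
  m <- branched_model()
  ko <- knockout_bounds(m, "g2")   # isozyme: R2b rescues
  expect_length(attr(ko, "disabled_reactions"), 0L)
  expect_equal(fba(ko)$objective_value, fba(m)$objective_value)
  ko2 <- knockout_bounds(m, "g4")  # complex subunit: R3 breaks
  expect_identical(attr(ko2, "disabled_reactions"), "R3")
  expect_equal(ko2$reactions$ub[ko2$reactions$id == "R3"], 0)
  expect_equal(fba(ko2)$objective_value, 0)
  expect_error(knockout_bounds(m, "nope"), "unknown gene")
  # deleting both isozymes kills the route
  ko3 <- knockout_bounds(m, c("g2", "g3"))
  expect_setequal(attr(ko3, "disabled_reactions"), c("R2a", "R2b"))
})

test_that("knocked-out reaction sets match per-reaction truth-table evaluation", {
  set.seed(9)
  models <- lapply(1:5, function(s) make_reference_model(synthetic_config(seed = s)))
  for (rep in 1:30) {
    m <- models[[rep %% 5 + 1]]
    genes <- model_genes(m)
    g <- sample(genes, 1)
    ko <- knockout_bounds(m, g)
    expected <- character(0)
    for (r in m$reactions$id) {
      txt <- as.character(m$gpr[[r]])
      if (!nzchar(txt)) next
      gs <- gpr_genes(m$gpr[[r]])
      if (oracle_eval_string(txt, gs, gs) &&
          !oracle_eval_string(txt, setdiff(gs, g), gs))
        expected <- c(expected, r)
    }
    expect_setequal(attr(ko, "disabled_reactions"), expected)
  }
  # a gene in no GPR leaves the optimum bit-identical
  m <- branched_model()
  ko <- knockout_bounds(m, "g6")    # only on the side branch
  expect_identical(fba(ko)$objective_value, fba(m)$objective_value)
})
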