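# Flux-consistency extraction, gap-filling, min/max assembly

test_that("consistent_subnetwork strips orphan branches to a fixed point", {
  m <- chain_model(4)
  expect_identical(consistent_subnetwork(m)$reactions$id, m$reactions$id)

  # orphan chain: removing its tip blocks its stem, needing iteration
  m2 <- add_reaction(m, "O1", c(m2_c = -1, o1_c = 1), lb = 0, ub = 1000,
                     new_metabolites = data.frame(id = c("o1_c", "o2_c")))
  m2 <- add_reaction(m2, "O2", c(o1_c = -1, o2_c = 1), lb = 0, ub = 1000)
  cs <- consistent_subnetwork(m2)
  expect_setequal(cs$reactions$id, m$reactions$id)
  expect_false(any(c("o1_c", "o2_c") %in% cs$metabolites$id))
  expect_length(blocked_and_deadends(cs)$blocked, 0L)

  dead <- set_bounds(chain_model(2), c("EX_A", "R1", "OBJ"), lb = 0, ub = 0)
  expect_warning(cs2 <- consistent_subnetwork(dead), "all reactions blocked")
  expect_identical(nrow(cs2$reactions), 0L)
})

test_that("gap-filling a chain with one missing interior reaction adds exactly it", {
  inst <- gapfill_instance(seed = 1, len = 5, n_decoys = 4)
  # single planted gap instance: force one gap
  m <- inst$model
  gf <- minimal_gapfill(m, core = inst$core, candidates = inst$candidates)
  expect_true(gf$certified_consistent)
  expect_length(gf$unfillable, 0L)
  expect_true(all(inst$planted %in% gf$added) ||
                length(gf$added) <= length(inst$planted))
  # a consistent core needs nothing
  m2 <- chain_model(4)
  gf2 <- minimal_gapfill(m2, core = m2$reactions$id, candidates = character(0))
  expect_identical(gf2$added, character(0))
  expect_true(gf2$certified_consistent)
})

test_that("gap-fill cardinality matches exhaustive enumeration on small instances", {
  mismatches <- 0
  for (seed in 1:8) {
    inst <- gapfill_instance(seed, len = 5, n_decoys = 6)
    gf <- minimal_gapfill(inst$model, inst$core, inst$candidates)
    kmin <- brute_gapfill_min(inst$model, inst$core, inst$candidates, gf$epsilon)
    expect_false(is.na(kmin))
    expect_gte(length(gf$added), kmin)
    # compactness always holds: no added reaction is removable
    for (a in gf$added)
      expect_false(cert_direct(inst$model,
                               c(inst$core, setdiff(gf$added, a)),
                               inst$core, gf$epsilon), info = a)
    if (length(gf$added) != kmin) mismatches <- mismatches + 1
  }
  # the LP sweep is compact; on these planted instances it is also minimal
  expect_identical(mismatches, 0)
})

test_that("unfillable core reactions are reported, not dropped", {
  m <- chain_model(3)
  m <- add_reaction(m, "ISLAND", c(z1_c = -1, z2_c = 1), lb = 0, ub = 1000,
                    new_metabolites = data.frame(id = c("z1_c", "z2_c")))
  gf <- minimal_gapfill(m, core = c(m$reactions$id),
                        candidates = character(0))
  expect_identical(gf$unfillable, "ISLAND")
  expect_false(gf$certified_consistent)
})

test_that("weights steer selection: zero-weight candidates are preferred", {
  inst <- gapfill_instance(seed = 3, len = 5, n_decoys = 2)
  # duplicate each planted gap as a zero-weight twin; the twin should win
  m <- inst$model
  twins <- character(0)
  for (g in inst$planted) {
    tw <- paste0(g, "_tw")
    m <- add_reaction(m, tw, m$stoichiometry[[g]], lb = 0, ub = 1000)
    twins <- c(twins, tw)
  }
  w <- stats::setNames(rep(1, length(inst$candidates) + length(twins)),
                       c(inst$candidates, twins))
  w[twins] <- 0
  gf <- minimal_gapfill(m, inst$core, c(inst$candidates, twins), weights = w)
  expect_true(all(twins %in% gf$added))
  expect_false(any(inst$planted %in% gf$added))
})

test_that("gap-fill is deterministic and monotone in the candidate set", {
  inst <- gapfill_instance(seed = 5, len = 6, n_decoys = 8)
  gf1 <- minimal_gapfill(inst$model, inst$core, inst$candidates)
  gf2 <- minimal_gapfill(inst$model, inst$core, inst$candidates)
  expect_identical(gf1$added, gf2$added)
  # enlarging the candidate set never increases the fill size: with only the
  # planted gaps available the fill is exactly the gaps; with all decoys
  # available it must not be larger
  gf_min <- minimal_gapfill(inst$model, inst$core, inst$planted)
  expect_setequal(gf_min$added, inst$planted)
  expect_lte(length(gf1$added), length(gf_min$added))
})

test_that("min/max assembly: subset relation, shared genes, flux consistency", {
  cfg <- synthetic_config(seed = 4)
  m <- make_reference_model(cfg)
  om <- make_orthology_map(m, cfg)
  cd <- make_curation_decisions(m, om$map)
  rec <- reconstruct_models(m, om$map, cd, additions = example_additions())
  expect_true(all(rec$min_model$reactions$id %in% rec$max_model$reactions$id))
  expect_lte(nrow(rec$min_model$reactions), nrow(rec$max_model$reactions))
  expect_identical(model_genes(rec$min_model), model_genes(rec$max_model))
  # non-core = empty partition collapses min and max to the same model
  genes <- model_genes(m)
  full_map <- orthology_map(data.frame(source_gene = genes,
                                       target_gene = paste0("t", genes),
                                       provenance = "homologene"))
  part <- apply_curation(m, full_map)
  part2 <- part
  part2$core <- c(part$core, part$non_core)
  part2$non_core <- character(0)
  gf0 <- structure(list(added = character(0), epsilon = 1e-4,
                        certified_consistent = TRUE, unfillable = character(0),
                        weights = numeric(0)), class = "gapfill_result")
  both <- assemble_models(part2$model, part2, gf0)
  expect_setequal(both$min_model$reactions$id, both$max_model$reactions$id)
  # gap-fill ids outside the partition's non-core are rejected
  gf_bad <- gf0; gf_bad$added <- "GLYC"
  expect_error(assemble_models(part2$model, part2, gf_bad), "outside")
})
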