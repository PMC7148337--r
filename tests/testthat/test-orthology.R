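# GPR translation through an orthology map, reaction triage, curation

simple_map <- function(...) {
  rows <- list(...)
  orthology_map(do.call(rbind, lapply(rows, function(r)
    data.frame(source_gene = r[1], target_gene = r[2],
               provenance = if (length(r) > 2) r[3] else "homologene",
               stringsAsFactors = FALSE))))
}

test_that("translation expands one-to-many to OR and marks unmapped genes", {
  map <- simple_map(c("h1", "m1"), c("h2", "m2a"), c("h2", "m2b"))
  tr <- translate_gpr(parse_gpr("h1 and h2"), map)
  expect_true(gpr_equal(tr$translated, parse_gpr("m1 and (m2a or m2b)")))
  expect_length(tr$unmapped, 0L)

  tr2 <- translate_gpr(parse_gpr("h1 or h2"), simple_map(c("h2", "m2")))
  expect_identical(tr2$unmapped, "h1")
  # the FALSE marker stays in the tree: it still evaluates FALSE...
  expect_false(eval_gpr(tr2$translated, character(0)))
  # ...but the mapped arm rescues the OR
  expect_true(eval_gpr(tr2$translated, "m2"))
})

test_that("translated rules are truth-equivalent to source rules under the map image", {
  genes <- paste0("h", 1:5)
  set.seed(21)
  for (rep in 1:100) {
    txt <- random_gpr_string(genes, n_ops = sample(1:4, 1))
    rule <- parse_gpr(txt)
    # random map: each gene unmapped / 1:1 / 1:2
    rows <- list()
    for (g in genes) {
      u <- stats::runif(1)
      if (u < 0.3) next
      rows[[length(rows) + 1L]] <- data.frame(source_gene = g,
                                              target_gene = paste0("m_", g),
                                              provenance = "homologene")
      if (u > 0.8)
        rows[[length(rows) + 1L]] <- data.frame(source_gene = g,
                                                target_gene = paste0("m2_", g),
                                                provenance = "kegg_ko")
    }
    if (!length(rows)) next
    map <- orthology_map(do.call(rbind, rows))
    tr <- translate_gpr(rule, map)
    mapped_src <- mapped_genes(map)
    all_targets <- unique(map$entries$target_gene)
    # evaluating the translated tree with every orthologue present must equal
    # evaluating the source with exactly the mapped source genes present
    expect_identical(eval_gpr(tr$translated, all_targets),
                     oracle_eval_string(txt, intersect(genes, mapped_src), genes),
                     info = txt)
    expect_setequal(tr$unmapped, intersect(gpr_genes(rule), setdiff(genes, mapped_src)))
  }
})

test_that("reactions classify into NGA / GAHM / GAH by orthology support", {
  m <- branched_model()
  map <- simple_map(c("g1", "mg1"), c("g2", "mg2"), c("g4", "mg4"), c("g6", "mg6"))
  cls <- classify_reactions(m, map)
  expect_identical(unname(cls[c("EX_A", "OBJ")]), c("NGA", "NGA"))
  expect_identical(unname(cls["R1"]), "GAHM")
  expect_identical(unname(cls["R2a"]), "GAHM")  # isozyme g2 mapped
  expect_identical(unname(cls["R2b"]), "GAH")   # g3 unmapped
  expect_identical(unname(cls["R3"]), "GAH")    # complex needs g4 AND g5
  expect_identical(sum(cls == "GAHM") + sum(cls == "GAH") + sum(cls == "NGA"),
                   nrow(m$reactions))
})

test_that("a pseudogene-style association flips GAH -> GAHM after GPR correction", {
  # reaction tied to a gene with no orthologue (pseudogene); correcting the
  # rule to the functional gene and re-mapping keeps the reaction
  m <- chain_model(2)
  m$gpr[["R1"]] <- parse_gpr("26062")
  map <- simple_map(c("26061", "56794"))
  expect_identical(classify_reaction("R1", map, m), "GAH")
  corrected <- parse_gpr("26061")
  expect_identical(classify_reaction(corrected, map), "GAHM")
  tr <- translate_gpr(corrected, map)
  expect_true(gpr_equal(tr$translated, parse_gpr("56794")))
})

test_that("curation triage assembles core and non-core sets", {
  m <- branched_model()
  m <- add_reaction(m, "ATPM", c(b_c = -1), lb = 0, ub = 1000)  # artificial
  map <- simple_map(c("g1", "mg1"), c("g2", "mg2"), c("g4", "mg4"),
                    c("g5", "mg5"), c("g6", "mg6"))
  # R2b (g3 unmapped, GAH): without a decision -> error naming it
  expect_error(apply_curation(m, map), "R2b")

  dec <- curation_decisions(data.frame(
    reaction_id = "R2b", action = "remove", category = "GAH2",
    rationale = "consistent after removal"))
  part <- apply_curation(m, map, dec)
  expect_identical(part$removed, "R2b")
  expect_false("R2b" %in% part$model$reactions$id)
  expect_setequal(part$core, c("R1", "R2a", "R3", "R4", "OBJ", "ATPM"))
  expect_setequal(part$non_core, c("EX_A", "EX_E"))
  # core GPRs translated, markers pruned: R2a had "g2 or g3" with g3 unmapped
  expect_true(gpr_equal(part$model$gpr[["R2a"]], parse_gpr("mg2")))
  expect_true(gpr_equal(part$model$gpr[["R3"]], parse_gpr("mg4 and mg5")))

  # GAH3-style demotion keeps the reaction, empties its GPR, keeps bounds
  dec3 <- curation_decisions(data.frame(
    reaction_id = "R2b", action = "demote_to_non_gene", category = "GAH3"))
  part3 <- apply_curation(m, map, dec3)
  expect_true("R2b" %in% part3$non_core)
  expect_identical(part3$model$gpr[["R2b"]]$type, "empty")
  expect_identical(part3$model$reactions$ub[part3$model$reactions$id == "R2b"],
                   m$reactions$ub[m$reactions$id == "R2b"])

  # GAH1-style keep with a corrected, re-mapped rule
  dec1 <- curation_decisions(data.frame(
    reaction_id = "R2b", action = "keep_with_gpr", corrected_gpr = "g2",
    category = "GAH1"))
  part1 <- apply_curation(m, map, dec1)
  expect_true("R2b" %in% part1$core)
  expect_true(gpr_equal(part1$model$gpr[["R2b"]], parse_gpr("mg2")))

  # applying the same inputs twice gives identical partitions (pure function)
  expect_identical(apply_curation(m, map, dec), part)
})

test_that("an unmapped gene inside an AND complex cannot be silently pruned", {
  m <- chain_model(2)
  m$gpr[["R1"]] <- parse_gpr("h1 and h2")
  map <- simple_map(c("h1", "m1"))
  # GAH: needs a decision; a keep decision with the same broken rule errors
  dec <- curation_decisions(data.frame(
    reaction_id = "R1", action = "keep_with_gpr", corrected_gpr = "h1 and h2",
    category = "GAH1"))
  expect_error(apply_curation(m, map, dec), "unmapped")
})

test_that("a complete 1:1 map is a pure renaming: classes and FVA ranges unchanged", {
  m <- make_reference_model(synthetic_config(seed = 2))
  genes <- model_genes(m)
  map <- orthology_map(data.frame(source_gene = genes,
                                  target_gene = paste0("t", genes),
                                  provenance = "homologene"))
  cls <- classify_reactions(m, map)
  expect_true(all(cls[!vapply(m$gpr, function(g) g$type == "empty", NA)] == "GAHM"))
  part <- apply_curation(m, map)
  expect_length(part$removed, 0L)
  expect_identical(model_genes(part$model), sort(paste0("t", genes)))
  fv1 <- fva(m, reactions = m$reactions$id[1:10])
  fv2 <- fva(part$model, reactions = m$reactions$id[1:10])
  expect_equal(fv2$min, fv1$min, tolerance = 1e-6)
  expect_equal(fv2$max, fv1$max, tolerance = 1e-6)
})

test_that("curated additions insert reactions, auto-sinks and no new dead ends", {
  m <- make_reference_model(synthetic_config(seed = 1))
  m2 <- add_curated_reactions(m, example_additions())
  added <- attr(m2, "curated_additions")
  expect_setequal(setdiff(added, grep("^SK_", added, value = TRUE)),
                  c("R10053", "R01465", "R01803", "R01115"))
  expect_gte(sum(startsWith(added, "SK_")), 1L)
  expect_true(all(c("cmpglna_c", "HC01115_c", "ficytb5_c", "focytb5_c")
                  %in% m2$metabolites$id))
  bd <- blocked_and_deadends(m2)
  expect_length(bd$deadends, 0L)
  expect_length(bd$blocked, 0L)

  # empty additions: identity
  m3 <- add_curated_reactions(m, list())
  expect_identical(m3$reactions, m$reactions)
  # id collision and unknown metabolite errors
  expect_error(add_curated_reactions(m, list(list(id = "GLYC",
    stoichiometry = list(pyr_c = 1), lb = 0, ub = 10))), "already in model")
  expect_error(add_curated_reactions(m, list(list(id = "NEW1",
    stoichiometry = list(nothere_c = 1), lb = 0, ub = 10))),
    "neither in the model")
})

test_that("orthology map IO round trips and rejects bad provenance", {
  map <- simple_map(c("h1", "m1", "kegg_ko"), c("h2", "m2"))
  tf <- tempfile(fileext = ".tsv")
  utils::write.table(map$entries, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  map2 <- read_orthology_map(tf)
  expect_identical(map2$entries, map$entries)
  expect_error(orthology_map(data.frame(source_gene = "a", target_gene = "b",
                                        provenance = "guesswork")),
               "provenance")
})
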