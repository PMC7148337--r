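# MCT / ROT functional tests and the three-mode failure taxonomy

test_that("glucose-to-precursor conversions pass on the synthetic glycolysis", {
  m <- make_reference_model(synthetic_config(seed = 1))
  media <- synthetic_media()
  t1 <- functional_test("glc_to_pyr", "MCT", sources = "glc__D_e",
                        targets = "pyr_c", medium = "RPMI1640")
  r1 <- run_mct(m, t1, media)
  expect_identical(r1$status, "pass")
  expect_identical(r1$failure_mode, "none")
  expect_gt(r1$objective_value, 0)

  # a target absent from the model is a missing-component failure
  t2 <- functional_test("glc_to_ghost", "MCT", sources = "glc__D_e",
                        targets = "ghost_c", medium = "RPMI1640")
  expect_identical(run_mct(m, t2, media)$failure_mode, "missing_component")

  # a target only reachable through a blocked branch: zero objective
  m3 <- add_reaction(m, "BROKEN", c(stranded_c = -1, stranded2_c = 1),
                     lb = 0, ub = 1000,
                     new_metabolites = data.frame(id = c("stranded_c",
                                                         "stranded2_c")))
  t3 <- functional_test("glc_to_stranded", "MCT", sources = "glc__D_e",
                        targets = "stranded2_c", medium = "RPMI1640")
  r3 <- run_mct(m3, t3, media)
  expect_identical(r3$status, "fail")
  expect_identical(r3$failure_mode, "zero_objective")

  expect_error(run_mct(m, functional_test("x", "MCT", sources = "glc__D_e",
                                          targets = "pyr_c", medium = "DMEM"),
                       media), "unknown medium")
})

test_that("run_mct never mutates the input model", {
  m <- make_reference_model(synthetic_config(seed = 1))
  snap <- m
  t1 <- functional_test("glc_to_aa", "MCT", sources = "glc__D_e",
                        targets = "aa_c", medium = "RPMI1640")
  invisible(run_mct(m, t1, synthetic_media()))
  expect_identical(m, snap)
})

test_that("multi-target conversions require each target individually", {
  m <- make_reference_model(synthetic_config(seed = 1))
  media <- synthetic_media()
  ok <- functional_test("multi_ok", "MCT", sources = "glc__D_e",
                        targets = c("pyr_c", "aa_c"), medium = "RPMI1640")
  expect_identical(run_mct(m, ok, media)$status, "pass")
  # second target is stranded -> the aggregate may flow but the test fails
  m2 <- add_reaction(m, "STR", c(str1_c = -1, str2_c = 1), lb = 0, ub = 1000,
                     new_metabolites = data.frame(id = c("str1_c", "str2_c")))
  mixed <- functional_test("multi_mixed", "MCT", sources = "glc__D_e",
                           targets = c("pyr_c", "str2_c"), medium = "RPMI1640")
  r <- run_mct(m2, mixed, media)
  expect_identical(r$status, "fail")
  expect_identical(r$failure_mode, "zero_objective")
})

test_that("ATP-maintenance optimization passes aerobically, shrinks anaerobically", {
  m <- make_reference_model(synthetic_config(seed = 1))
  aero <- run_rot(m, functional_test("rot_aero", "ROT", sources = "glc__D_e",
                                     objective_reaction = "ATPM",
                                     condition = "aerobic"))
  anaero <- run_rot(m, functional_test("rot_anaero", "ROT", sources = "glc__D_e",
                                       objective_reaction = "ATPM",
                                       condition = "anaerobic"))
  expect_identical(aero$status, "pass")
  expect_identical(anaero$status, "pass")
  expect_lt(anaero$objective_value, aero$objective_value)

  # missing objective reaction
  r <- run_rot(remove_reactions(m, "ATPM"),
               functional_test("rot_gone", "ROT", sources = "glc__D_e",
                               objective_reaction = "ATPM"))
  expect_identical(r$failure_mode, "missing_component")

  # no substrate at all: zero objective
  r2 <- run_rot(m, functional_test("rot_starved", "ROT", sources = character(0),
                                   objective_reaction = "ATPM",
                                   condition = "anaerobic", policy = "all"))
  expect_identical(r2$failure_mode, "zero_objective")
})

test_that("suite summaries count by kind, mode and component presence", {
  m <- make_reference_model(synthetic_config(seed = 1))
  media <- synthetic_media()
  empty <- run_suite(m, list(), media)
  expect_identical(empty$counts$all$n, 0L)

  tt <- make_truth_and_tests(m)
  sm <- run_suite(m, tt$tests, media)
  expect_identical(sm$counts$all$passed, sm$counts$all$n)  # generator contract

  # deleting amino-acid synthesis fails exactly the conversions crossing it
  m2 <- remove_reactions(m, "AASYN")
  sm2 <- run_suite(m2, tt$tests, media)
  res <- sm2$results
  failed <- res$id[res$status == "fail"]
  expect_setequal(failed, c("mct_glc_to_aa_c", "mct_glc_to_nuc_c"))
  expect_true(all(res$failure_mode[res$id %in% failed] == "zero_objective"))
  # the restricted tally only counts tests whose components are present
  m3 <- remove_reactions(m2, "ATPM")  # drops the ROT objective reaction
  sm3 <- run_suite(m3, tt$tests, media)
  expect_identical(sm3$restricted$n,
                   sum(sm3$results$components_present))
  expect_gt(sm3$counts$all$n, sm3$restricted$n)
})

test_that("battery JSON round trips", {
  m <- make_reference_model(synthetic_config(seed = 1))
  tt <- make_truth_and_tests(m)
  tf <- tempfile(fileext = ".json")
  write_test_battery(tt$tests, tf)
  back <- read_test_battery(tf)
  expect_identical(length(back), length(tt$tests))
  expect_identical(vapply(back, `[[`, "", "id"),
                   vapply(tt$tests, `[[`, "", "id"))
  sm <- run_suite(m, back, synthetic_media())
  expect_identical(sm$counts$all$passed, sm$counts$all$n)
})
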