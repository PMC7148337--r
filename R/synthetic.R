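# Synthetic-data generators: a flux-consistent toy reference model with
# AND/OR GPRs across compartments, an orthology map with tunable unmapped
# and one-to-many fractions, binarized expression calls with planted
# tissue-active genes and planted outlier samples, curation decisions, and
# lethal/viable gene labels derived by exhaustive per-gene knockout.
#
# Every generator is a pure function of its configuration (seed included).
# Ground truths are derived by independent code paths: Boolean truths by an
# inline recursive evaluator, knockout truths by an LP assembled directly
# from the stoichiometry table (not via the analysis functions under test).

#' Synthetic-data generator configuration
#'
#' @param seed RNG seed (mandatory; generators have no hidden entropy).
#' @param n_pathways number of random peripheral pathways grafted onto the
#'   fixed central skeleton.
#' @param pathway_length reactions per peripheral pathway.
#' @param n_isozyme_genes number of pathway reactions carrying an OR pair of
#'   isozyme genes.
#' @param n_complex_genes number of pathway reactions carrying an AND pair
#'   of complex-subunit genes.
#' @param n_compartments 2 (cytosol + extracellular) or 3 (adds a
#'   mitochondrion-like compartment with transporters).
#' @param noncore_fraction fraction of gene-associated reactions stripped of
#'   their GPR (emulating non-gene-associated reference reactions).
#' @param unmapped_fraction probability that a reference gene has no
#'   orthologue.
#' @param one2many_fraction probability that a mapped gene has two
#'   orthologues.
#' @param n_samples number of expression samples (>= 3).
#' @param outlier_count planted decorrelated samples among `n_samples`.
#' @param tissue_active_fraction fraction of genes active in the simulated
#'   tissue.
#' @return an object of class `"generator_config"`.
#' @export
synthetic_config <- function(seed, n_pathways = 4, pathway_length = 3,
                             n_isozyme_genes = 3, n_complex_genes = 3,
                             n_compartments = 3, noncore_fraction = 0.25,
                             unmapped_fraction = 0.08, one2many_fraction = 0.15,
                             n_samples = 12, outlier_count = 1,
                             tissue_active_fraction = 0.6) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed),
            n_compartments %in% 2:3, n_samples >= 3,
            outlier_count >= 0, outlier_count < n_samples)
  for (f in c(noncore_fraction, unmapped_fraction, one2many_fraction,
              tissue_active_fraction))
    stopifnot(f >= 0, f <= 1)
  structure(list(seed = as.integer(seed), n_pathways = n_pathways,
                 pathway_length = pathway_length,
                 n_isozyme_genes = n_isozyme_genes,
                 n_complex_genes = n_complex_genes,
                 n_compartments = n_compartments,
                 noncore_fraction = noncore_fraction,
                 unmapped_fraction = unmapped_fraction,
                 one2many_fraction = one2many_fraction,
                 n_samples = n_samples, outlier_count = outlier_count,
                 tissue_active_fraction = tissue_active_fraction),
            class = "generator_config")
}

# run expr with a local RNG state so generators do not disturb the caller's
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# independent Boolean evaluator for ground-truth derivation (kept separate
# from eval_gpr on purpose: the oracle must not share the code under test)
truth_eval <- function(nd, present) {
  switch(nd$type,
    empty = TRUE,
    false = FALSE,
    leaf  = nd$gene %in% present,
    and   = all(vapply(nd$children, truth_eval, NA, present = present)),
    or    = any(vapply(nd$children, truth_eval, NA, present = present)))
}

#' Bundled synthetic growth media
#'
#' Reads one of the media definitions shipped with the package (HAM and
#' RPMI1640, over the synthetic reference model's exchange namespace).
#'
#' @param name `"HAM"` or `"RPMI1640"`.
#' @return a `"medium"`.
#' @export
example_medium <- function(name = c("HAM", "RPMI1640")) {
  name <- match.arg(name)
  read_medium(system.file("extdata", paste0(name, ".tsv"), package = "gemrecon"),
              name = name)
}

# fixed central skeleton: lumped glycolysis, fermentation, respiration with
# a NAD/NADH cycle, biomass precursor synthesis, ATP maintenance, and host
# routes for the substrates/products of the curated organism-specific
# additions (gulonolactone, ascorbate, threonine, aminoketobutyrate,
# neuraminate metabolites)
skeleton_model <- function(three_compartments = TRUE) {
  M <- function(id, formula) data.frame(id = id, formula = formula,
                                        stringsAsFactors = FALSE)
  mets <- rbind(
    M("glc__D_e", "C6H12O6"), M("glc__D_c", "C6H12O6"),
    M("pyr_c", "C3H3O3"), M("lac__L_c", "C3H5O3"), M("lac__L_e", "C3H5O3"),
    M("atp_c", "C10H12N5O13P3"), M("adp_c", "C10H12N5O10P2"),
    M("pi_e", "HO4P"), M("pi_c", "HO4P"),
    M("nh4_e", "H4N"), M("nh4_c", "H4N"),
    M("o2_e", "O2"), M("o2_c", "O2"),
    M("co2_e", "CO2"), M("co2_c", "CO2"),
    M("h2o_e", "H2O"), M("h2o_c", "H2O"),
    M("h_e", "H"), M("h_c", "H"),
    M("nad_c", "C21H26N7O14P2"), M("nadh_c", "C21H27N7O14P2"),
    M("aa_c", "C5H9NO4"), M("nuc_c", "C10H12N5O7P"), M("lip_c", "C18H34O2"),
    M("guln_c", "C6H10O6"), M("guln_e", "C6H10O6"),
    M("ascb_c", "C6H8O6"), M("ascb_e", "C6H8O6"),
    M("thr__L_c", "C4H9NO3"), M("thr__L_e", "C4H9NO3"),
    M("2aobut_c", "C4H7NO3"), M("2aobut_e", "C4H7NO3"),
    M("acnam_c", "C11H19NO9"), M("acnam_e", "C11H19NO9"),
    M("cmpacna_c", "C20H31N4O16P"), M("cmpacna_e", "C20H31N4O16P"))

  rx <- list(); st <- list(); gp <- list()
  R <- function(id, stoich, lb, ub, gpr = "", subsystem = "") {
    rx[[length(rx) + 1L]] <<- data.frame(id = id, lb = lb, ub = ub,
                                         subsystem = subsystem,
                                         stringsAsFactors = FALSE)
    st[[id]] <<- stoich
    gp[[id]] <<- gpr
  }
  v <- function(...) {
    x <- c(...)
    stats::setNames(as.numeric(x), names(x))
  }

  for (m in c("glc__D_e", "lac__L_e", "pi_e", "nh4_e", "o2_e", "co2_e",
              "h2o_e", "h_e", "guln_e", "ascb_e", "thr__L_e", "2aobut_e",
              "acnam_e", "cmpacna_e"))
    R(paste0("EX_", m), v(stats::setNames(-1, m)), -1000, 1000,
      subsystem = "Exchange")

  R("GLCt", v(glc__D_e = -1, glc__D_c = 1), 0, 1000, "2001", "Transport")
  R("LACt", v(lac__L_c = -1, lac__L_e = 1), -1000, 1000, "2002", "Transport")
  R("PIt", v(pi_e = -1, pi_c = 1), -1000, 1000, "2003", "Transport")
  R("NH4t", v(nh4_e = -1, nh4_c = 1), 0, 1000, "2004", "Transport")
  R("O2t", v(o2_e = -1, o2_c = 1), 0, 1000, "2005", "Transport")
  R("CO2t", v(co2_c = -1, co2_e = 1), 0, 1000, "2040", "Transport")
  R("H2Ot", v(h2o_c = -1, h2o_e = 1), -1000, 1000, "2041", "Transport")
  R("Ht", v(h_c = -1, h_e = 1), -1000, 1000, "2042", "Transport")
  R("GULt", v(guln_c = -1, guln_e = 1), -1000, 1000, "2006", "Transport")
  R("ASCt", v(ascb_c = -1, ascb_e = 1), -1000, 1000, "2007", "Transport")
  R("THRt", v(thr__L_c = -1, thr__L_e = 1), -1000, 1000, "2008", "Transport")
  R("AOBt", v(`2aobut_c` = -1, `2aobut_e` = 1), -1000, 1000, "2043", "Transport")
  R("ACNAMt", v(acnam_c = -1, acnam_e = 1), -1000, 1000, "2009", "Transport")
  R("CMPACNAt", v(cmpacna_c = -1, cmpacna_e = 1), -1000, 1000, "2044", "Transport")

  R("GLYC", v(glc__D_c = -1, adp_c = -2, pi_c = -2, nad_c = -2,
              pyr_c = 2, atp_c = 2, nadh_c = 2, h2o_c = 2),
    0, 1000, "2010 and 2011", "Glycolysis")
  R("LDH", v(pyr_c = -1, nadh_c = -1, lac__L_c = 1, nad_c = 1),
    -1000, 1000, "2012 or 2013", "Fermentation")
  if (three_compartments) {
    mets <- rbind(mets,
      M("pyr_m", "C3H3O3"), M("nad_m", "C21H26N7O14P2"),
      M("nadh_m", "C21H27N7O14P2"), M("atp_m", "C10H12N5O13P3"),
      M("adp_m", "C10H12N5O10P2"), M("pi_m", "HO4P"), M("co2_m", "CO2"),
      M("o2_m", "O2"), M("h2o_m", "H2O"))
    R("PYRtm", v(pyr_c = -1, pyr_m = 1), -1000, 1000, "2030", "Transport")
    R("O2tm", v(o2_c = -1, o2_m = 1), 0, 1000, "2032", "Transport")
    R("PItm", v(pi_c = -1, pi_m = 1), -1000, 1000, "2033", "Transport")
    R("CO2tm", v(co2_m = -1, co2_c = 1), 0, 1000, "2045", "Transport")
    R("H2Otm", v(h2o_m = -1, h2o_c = 1), -1000, 1000, "2046", "Transport")
    R("ANT", v(atp_m = -1, adp_c = -1, atp_c = 1, adp_m = 1),
      -1000, 1000, "2031", "Transport")
    # redox shuttle: without it cytosolic NADH could only be reoxidized by
    # fermentation, which consumes the pyruvate needed for biosynthesis
    R("NADHSH", v(nadh_c = -1, nad_m = -1, nad_c = 1, nadh_m = 1),
      0, 1000, "2034", "Transport")
    R("TCA", v(pyr_m = -1, nad_m = -4, adp_m = -1, pi_m = -1,
               co2_m = 3, nadh_m = 4, atp_m = 1),
      0, 1000, "2014 and 2015", "Citric acid cycle")
    R("ETC", v(nadh_m = -1, o2_m = -0.5, adp_m = -2, pi_m = -2,
               nad_m = 1, atp_m = 2, h2o_m = 3),
      0, 1000, "2016 or 2017", "Oxidative phosphorylation")
  } else {
    R("TCA", v(pyr_c = -1, nad_c = -4, adp_c = -1, pi_c = -1,
               co2_c = 3, nadh_c = 4, atp_c = 1),
      0, 1000, "2014 and 2015", "Citric acid cycle")
    R("ETC", v(nadh_c = -1, o2_c = -0.5, adp_c = -2, pi_c = -2,
               nad_c = 1, atp_c = 2, h2o_c = 3),
      0, 1000, "2016 or 2017", "Oxidative phosphorylation")
  }
  R("AASYN", v(pyr_c = -1, nh4_c = -1, atp_c = -1,
               aa_c = 1, adp_c = 1, pi_c = 1),
    0, 1000, "2018", "Amino acid metabolism")
  # one phosphate is incorporated into the nucleotide pool (only one of the
  # two hydrolysed phosphates is released), giving the cell a net Pi demand
  R("NUCSYN", v(aa_c = -1, atp_c = -2, nuc_c = 1, adp_c = 2, pi_c = 1),
    0, 1000, "2019 and 2020", "Nucleotide metabolism")
  R("LIPSYN", v(pyr_c = -2, atp_c = -1, nadh_c = -1,
                lip_c = 1, adp_c = 1, pi_c = 1, nad_c = 1),
    0, 1000, "2021 or 2022", "Lipid metabolism")
  R("GULSYN", v(glc__D_c = -1, atp_c = -1, guln_c = 1, adp_c = 1, pi_c = 1),
    0, 1000, "2023", "Ascorbate metabolism")
  R("ASCDEG", v(ascb_c = -1, nadh_c = -1, guln_c = 1, nad_c = 1),
    0, 1000, "2027", "Ascorbate metabolism")
  R("THRSYN", v(aa_c = -1, atp_c = -1, thr__L_c = 1, adp_c = 1, pi_c = 1),
    0, 1000, "2026", "Amino acid metabolism")
  R("AOBDEG", v(`2aobut_c` = -1, pyr_c = 1, nh4_c = 1),
    0, 1000, "2028", "Amino acid metabolism")
  R("ANSYN", v(aa_c = -1, pyr_c = -1, acnam_c = 1),
    0, 1000, "2024", "Aminosugar metabolism")
  R("CMPSYN", v(acnam_c = -1, atp_c = -1, cmpacna_c = 1, adp_c = 1, pi_c = 1),
    0, 1000, "2025", "Aminosugar metabolism")
  R("ATPM", v(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
    0, 1000, "", "Artificial")
  R("BIOMASS", v(aa_c = -1, nuc_c = -1, lip_c = -1, atp_c = -2, h2o_c = -2,
                 adp_c = 2, pi_c = 2, h_c = 2),
    0, 1000, "", "Artificial")

  list(metabolites = mets, reactions = do.call(rbind, rx),
       stoichiometry = st, gpr = gp)
}

#' Generate a synthetic flux-consistent reference model
#'
#' A fixed central skeleton (glucose uptake, lumped glycolysis,
#' fermentation, respiration with a NAD/NADH cycle, biomass precursor
#' synthesis, ATP maintenance, biomass) is decorated with seeded random
#' peripheral pathways carrying isozyme (OR) and complex (AND) GPRs, then a
#' fraction of gene associations is stripped to emulate non-gene-associated
#' reference reactions. The generator self-checks that the result is
#' flux-consistent (no blocked reactions, no dead-end metabolites) and grows
#' under the bundled HAM medium, and errors otherwise.
#'
#' @param config a `"generator_config"`.
#' @return a `"metabolic_model"`.
#' @export
make_reference_model <- function(config) {
  with_seed(config$seed * 13L + 1L, {
    sk <- skeleton_model(config$n_compartments >= 3)
    mets <- sk$metabolites
    rx <- sk$reactions
    st <- sk$stoichiometry
    gp <- sk$gpr

    starts <- c("pyr_c", "aa_c", "lip_c", "nuc_c")
    next_gene <- 3001L
    shapes <- character(0)
    n_rx <- config$n_pathways * config$pathway_length
    if (n_rx > 0) {
      shapes <- rep("single", n_rx)
      pool <- sample(seq_len(n_rx))
      k_iso <- min(config$n_isozyme_genes, n_rx)
      shapes[pool[seq_len(k_iso)]] <- "iso"
      k_cpl <- min(config$n_complex_genes, n_rx - k_iso)
      if (k_cpl > 0) shapes[pool[k_iso + seq_len(k_cpl)]] <- "complex"
    }
    slot <- 0L
    for (p in seq_len(config$n_pathways)) {
      prev <- sample(starts, 1)
      for (k in seq_len(config$pathway_length)) {
        slot <- slot + 1L
        mid <- sprintf("pw%d_%d_c", p, k)
        mets <- rbind(mets, data.frame(id = mid, formula = "C5H8O4",
                                       stringsAsFactors = FALSE))
        s <- stats::setNames(c(-1, 1), c(prev, mid))
        if (stats::runif(1) < 0.4) {   # ATP-coupled step
          s <- c(s, stats::setNames(c(-1, 1, 1), c("atp_c", "adp_c", "pi_c")))
        }
        g1 <- next_gene
        g <- switch(shapes[slot],
          single  = { next_gene <- next_gene + 1L; as.character(g1) },
          iso     = { next_gene <- next_gene + 2L; paste(g1, "or", g1 + 1L) },
          complex = { next_gene <- next_gene + 2L; paste(g1, "and", g1 + 1L) })
        rid <- sprintf("PW%dR%d", p, k)
        rx <- rbind(rx, data.frame(id = rid, lb = 0, ub = 1000,
                                   subsystem = sprintf("Pathway %d", p),
                                   stringsAsFactors = FALSE))
        st[[rid]] <- s
        gp[[rid]] <- g
        prev <- mid
      }
      eid <- sprintf("pw%d_e", p)
      mets <- rbind(mets, data.frame(id = eid, formula = "C5H8O4",
                                     stringsAsFactors = FALSE))
      tid <- sprintf("PW%dT", p)
      rx <- rbind(rx, data.frame(id = tid, lb = 0, ub = 1000,
                                 subsystem = sprintf("Pathway %d", p),
                                 stringsAsFactors = FALSE))
      st[[tid]] <- stats::setNames(c(-1, 1), c(prev, eid))
      gp[[tid]] <- as.character(next_gene)
      next_gene <- next_gene + 1L
      exid <- paste0("EX_", eid)
      rx <- rbind(rx, data.frame(id = exid, lb = -1000, ub = 1000,
                                 subsystem = "Exchange", stringsAsFactors = FALSE))
      st[[exid]] <- stats::setNames(-1, eid)
      gp[[exid]] <- ""
    }

    # strip GPRs from a fraction of gene-associated reactions
    ga <- rx$id[vapply(gp[rx$id], nzchar, NA)]
    n_strip <- round(config$noncore_fraction * length(ga))
    if (n_strip > 0) for (r in sample(ga, n_strip)) gp[[r]] <- ""

    model <- metabolic_model(
      id = sprintf("synthref_seed%d", config$seed),
      metabolites = mets, reactions = rx, stoichiometry = st, gpr = gp,
      objective = "BIOMASS")

    bd <- blocked_and_deadends(model)
    if (length(bd$blocked) || length(bd$deadends))
      stop("generated model is not flux-consistent (seed ", config$seed,
           "); regenerate with a different seed")
    ham <- example_medium("HAM")
    g <- fba(apply_medium(model, ham))
    if (g$status != "optimal" || g$objective_value <= 1e-6)
      stop("generated model does not grow under HAM (seed ", config$seed,
           "); regenerate with a different seed")
    model
  })
}

#' Generate an orthology map with planted coverage gaps
#'
#' Each reference gene is unmapped with probability `unmapped_fraction`,
#' mapped to two orthologues with probability `one2many_fraction`, and 1:1
#' otherwise. The analytically expected reaction classification (NGA / GAHM
#' / GAH), derived by an independent Boolean evaluation of each GPR against
#' the mapped gene set, is returned as ground truth.
#'
#' @param model the reference model.
#' @param config a `"generator_config"`.
#' @return list with `map` (an `"orthology_map"`) and `expected_classes`
#'   (named character vector, reaction id -> class).
#' @export
make_orthology_map <- function(model, config) {
  genes <- model_genes(model)
  with_seed(config$seed * 13L + 2L, {
    rows <- list()
    for (g in genes) {
      u <- stats::runif(1)
      if (u < config$unmapped_fraction) next
      base <- suppressWarnings(as.integer(g))
      if (is.na(base)) base <- 7000L + length(rows)
      prov <- sample(c("homologene", "gene_record", "kegg_ko", "ensembl"),
                     1, prob = c(0.7, 0.15, 0.1, 0.05))
      if (u < config$unmapped_fraction + config$one2many_fraction) {
        rows[[length(rows) + 1L]] <- data.frame(
          source_gene = g, target_gene = as.character(base + 90000L),
          provenance = prov, stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          source_gene = g, target_gene = as.character(base + 95000L),
          provenance = "homologene", stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          source_gene = g, target_gene = as.character(base + 90000L),
          provenance = prov, stringsAsFactors = FALSE)
      }
    }
    entries <- if (length(rows)) do.call(rbind, rows) else
      data.frame(source_gene = character(0), target_gene = character(0),
                 provenance = character(0))
    map <- orthology_map(entries)
    mapped <- unique(entries$source_gene)
    expected <- vapply(stats::setNames(model$reactions$id, model$reactions$id),
                       function(r) {
                         g <- model$gpr[[r]]
                         if (g$type == "empty") "NGA"
                         else if (truth_eval(g, mapped)) "GAHM" else "GAH"
                       }, "")
    list(map = map, expected_classes = expected)
  })
}

#' Generate curation decisions for the GAH reactions of a synthetic model
#'
#' Emulates the manual triage: a GAH reaction whose removal leaves every
#' other reaction unblocked is removed (GAH2-style); one whose removal
#' breaks consistency is demoted to a non-gene-associated reaction
#' (GAH3-style).
#'
#' @param model the reference model.
#' @param map an `"orthology_map"`.
#' @return a `"curation_decisions"` table (possibly empty).
#' @export
make_curation_decisions <- function(model, map) {
  cls <- classify_reactions(model, map)
  gah <- names(cls)[cls == "GAH"]
  if (length(gah) == 0L)
    return(curation_decisions(data.frame(reaction_id = character(0),
                                         action = character(0))))
  before <- blocked_and_deadends(model)$blocked
  rows <- lapply(gah, function(r) {
    after <- blocked_and_deadends(remove_reactions(model, r))$blocked
    if (length(setdiff(after, before)) == 0L)
      data.frame(reaction_id = r, action = "remove", corrected_gpr = "",
                 category = "GAH2",
                 rationale = "removal keeps the network consistent",
                 stringsAsFactors = FALSE)
    else
      data.frame(reaction_id = r, action = "demote_to_non_gene",
                 corrected_gpr = "", category = "GAH3",
                 rationale = "needed for consistency; kept without gene association",
                 stringsAsFactors = FALSE)
  })
  curation_decisions(do.call(rbind, rows))
}

#' Generate expression values and P/M/A calls with planted structure
#'
#' Clean samples share a common per-probe baseline profile and split into
#' two array-quality batches (low / high technical noise), keeping their
#' mean-correlation spread well inside the outlier cutoff. Planted outlier
#' samples draw
#' their own independent baseline, decorrelating them from the rest. Calls
#' are P with probability 0.9 for tissue-active genes and 0.1 for inactive
#' genes (M has probability 0.05 in both); planted outliers call P at random
#' (probability 0.5). Each gene is measured by 1-3 probes.
#'
#' @param model the reference model (its genes are simulated).
#' @param config a `"generator_config"`.
#' @return list with `values` (probes x samples), `calls` (probes x samples,
#'   P/M/A), `probe_map`, `active_genes`, `outlier_samples`.
#' @export
make_expression_calls <- function(model, config) {
  genes <- model_genes(model)
  with_seed(config$seed * 13L + 3L, {
    n_active <- round(config$tissue_active_fraction * length(genes))
    active <- sort(sample(genes, n_active))
    nprobe <- sample(1:3, length(genes), replace = TRUE)
    probe_map <- data.frame(
      probe = unlist(mapply(function(g, k) sprintf("p%s_%d", g, seq_len(k)),
                            genes, nprobe, SIMPLIFY = FALSE), use.names = FALSE),
      gene = rep(genes, nprobe), stringsAsFactors = FALSE)
    np <- nrow(probe_map)
    ns <- config$n_samples
    samples <- sprintf("s%02d", seq_len(ns))
    outliers <- if (config$outlier_count > 0)
      sort(sample(samples, config$outlier_count)) else character(0)
    clean <- setdiff(samples, outliers)

    baseline <- stats::runif(np, 4, 12)
    # clean samples fall into two array-quality batches (low / high technical
    # noise). A two-level design keeps every clean sample's mean-correlation
    # z-score near +/-1 — far inside the |z| >= 2 outlier cutoff even after
    # per-sample variance jitter — while planted decorrelated outliers score
    # far outside it, so the planted truth is exactly recoverable
    n_cl <- length(clean)
    noise_sd <- rep(c(0.2, 1.0), c(ceiling(n_cl / 2), floor(n_cl / 2)))
    values <- matrix(NA_real_, np, ns, dimnames = list(probe_map$probe, samples))
    for (i in seq_len(n_cl))
      values[, clean[i]] <- baseline + stats::rnorm(np, 0, noise_sd[i])
    for (s in outliers)
      values[, s] <- stats::runif(np, 4, 12) + stats::rnorm(np, 0, 0.5)

    p_active <- ifelse(probe_map$gene %in% active, 0.9, 0.1)
    calls <- matrix("A", np, ns, dimnames = list(probe_map$probe, samples))
    for (s in clean) {
      u <- stats::runif(np)
      calls[, s] <- ifelse(u < p_active, "P", ifelse(u < p_active + 0.05, "M", "A"))
    }
    for (s in outliers) {
      u <- stats::runif(np)
      calls[, s] <- ifelse(u < 0.5, "P", "A")
    }
    list(values = values, calls = calls, probe_map = probe_map,
         active_genes = active, outlier_samples = outliers)
  })
}

# independently constructed knockout LP: builds the stoichiometric matrix,
# HAM-style bounds and gene-deletion constraints directly from the model's
# tables and calls the low-level solver (not fba/knockout_bounds)
truth_knockout_objective <- function(model, med, gene = NULL) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (j in seq_along(rxns)) {
    s <- model$stoichiometry[[rxns[j]]]
    S[names(s), j] <- s
  }
  lb <- model$reactions$lb; ub <- model$reactions$ub
  names(lb) <- names(ub) <- rxns
  is_ex <- model$reactions$is_exchange
  listed <- med$bounds$exchange_id
  for (j in which(is_ex)) {
    r <- rxns[j]
    if (r %in% listed) {
      i <- match(r, listed)
      lb[r] <- med$bounds$lb[i]; ub[r] <- med$bounds$ub[i]
    } else if (!(r %in% med$always_open)) {
      metj <- names(model$stoichiometry[[r]])[1L]
      f <- model$metabolites$formula[match(metj, mets)]
      organic <- !is.na(f) && grepl("C(?![a-z])", f, perl = TRUE)
      if (organic) lb[r] <- min(0, ub[r])
    }
  }
  if (!is.null(gene)) {
    allg <- model_genes(model)
    rest <- setdiff(allg, gene)
    for (r in rxns) {
      g <- model$gpr[[r]]
      if (g$type == "empty") next
      if (truth_eval(g, allg) && !truth_eval(g, rest)) { lb[r] <- 0; ub[r] <- 0 }
    }
  }
  cost <- numeric(length(rxns))
  cost[match(model$objective, rxns)] <- 1
  res <- .lp_solve_dense(S, rep(0, length(mets)), cost, unname(lb), unname(ub), TRUE)
  if (res$status != 0L) 0 else res$objective
}

#' Generate ground-truth essentiality labels and a functional-test battery
#'
#' Labels come from exhaustive per-gene knockout FBA under the HAM medium,
#' computed through an independently assembled LP (growth ratio < `threshold`
#' -> lethal). The battery holds one metabolite conversion test per
#' non-currency biomass precursor (glucose -> precursor under RPMI1640),
#' pyruvate and lactate conversions, and aerobic/anaerobic ATP-maintenance
#' optimization tests; the generator verifies the battery passes on the
#' generating model and errors otherwise.
#'
#' @param model the reference model.
#' @param threshold essentiality growth-ratio cutoff.
#' @return list with `labels` (data.frame `gene_id`, `label`), `tests`
#'   (list of `"functional_test"`), `wild_type_objective`.
#' @export
make_truth_and_tests <- function(model, threshold = 0.30) {
  ham <- example_medium("HAM")
  rpmi <- example_medium("RPMI1640")
  wt <- truth_knockout_objective(model, ham, gene = NULL)
  if (wt <= 1e-6) stop("model does not grow under HAM; no truth derivable")
  genes <- model_genes(model)
  ratios <- vapply(genes, function(g)
    truth_knockout_objective(model, ham, gene = g) / wt, 0)
  labels <- data.frame(gene_id = genes,
                       label = ifelse(ratios < threshold, "lethal", "viable"),
                       growth_ratio = unname(ratios), stringsAsFactors = FALSE)

  currency <- c("atp_c", "adp_c", "pi_c", "h2o_c", "h_c", "nad_c", "nadh_c")
  bm <- model$stoichiometry[[model$objective]]
  precursors <- setdiff(names(bm)[bm < 0], currency)
  tests <- list()
  for (p in precursors)
    tests[[length(tests) + 1L]] <- functional_test(
      id = paste0("mct_glc_to_", p), kind = "MCT", sources = "glc__D_e",
      targets = p, medium = "RPMI1640")
  for (p in intersect(c("pyr_c", "lac__L_c"), model$metabolites$id))
    tests[[length(tests) + 1L]] <- functional_test(
      id = paste0("mct_glc_to_", p), kind = "MCT", sources = "glc__D_e",
      targets = p, medium = "RPMI1640")
  tests[[length(tests) + 1L]] <- functional_test(
    id = "rot_atpm_aerobic", kind = "ROT", sources = "glc__D_e",
    objective_reaction = "ATPM", condition = "aerobic")
  tests[[length(tests) + 1L]] <- functional_test(
    id = "rot_atpm_anaerobic", kind = "ROT", sources = "glc__D_e",
    objective_reaction = "ATPM", condition = "anaerobic")

  chk <- run_suite(model, tests, media = list(HAM = ham, RPMI1640 = rpmi))
  if (chk$counts$all$passed != chk$counts$all$n)
    stop("generated battery does not pass on the generating model")
  list(labels = labels, tests = tests, wild_type_objective = wt)
}

#' Write a complete synthetic workspace to disk
#'
#' Emits every input the reconstruction pipeline consumes: the reference
#' model (JSON and SBML), orthology map, curation decisions, expression
#' values/calls/probe map, lethal-viable labels, the functional-test battery
#' and the two bundled media definitions.
#'
#' @param config a `"generator_config"`.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
simulate_workspace <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  model <- make_reference_model(config)
  om <- make_orthology_map(model, config)
  cd <- make_curation_decisions(model, om$map)
  ec <- make_expression_calls(model, config)
  tt <- make_truth_and_tests(model)

  paths <- c(model_json = file.path(dir, "reference_model.json"),
             model_sbml = file.path(dir, "reference_model.xml"),
             orthology = file.path(dir, "orthology.tsv"),
             curation = file.path(dir, "curation.tsv"),
             values = file.path(dir, "expression_values.tsv"),
             calls = file.path(dir, "expression_calls.tsv"),
             probe_map = file.path(dir, "probe_map.tsv"),
             labels = file.path(dir, "labels.tsv"),
             tests = file.path(dir, "tests.json"),
             ham = file.path(dir, "HAM.tsv"),
             rpmi = file.path(dir, "RPMI1640.tsv"))
  write_model(model, paths[["model_json"]], "json")
  write_model(model, paths[["model_sbml"]], "sbml")
  utils::write.table(om$map$entries, paths[["orthology"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(cd), paths[["curation"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  wtab <- function(m, p) utils::write.table(
    data.frame(probe = rownames(m), m, check.names = FALSE), p,
    sep = "\t", quote = FALSE, row.names = FALSE)
  wtab(ec$values, paths[["values"]])
  wtab(ec$calls, paths[["calls"]])
  utils::write.table(ec$probe_map, paths[["probe_map"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tt$labels[, c("gene_id", "label")], paths[["labels"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_test_battery(tt$tests, paths[["tests"]])
  for (nm in c("HAM", "RPMI1640"))
    file.copy(system.file("extdata", paste0(nm, ".tsv"), package = "gemrecon"),
              file.path(dir, paste0(nm, ".tsv")), overwrite = TRUE)
  invisible(paths)
}
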