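---
title: "Orthology-based GSM reconstruction: models, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthology-based GSM reconstruction: models, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemrecon)
```

This vignette is the package's account of the science it implements: the
constraint-based model and its assumptions, the orthology-translation and
triage rules, the numerical machinery underneath, the choices made where the
design was genuinely open, and what the synthetic test bed does and does not
establish about real reconstructions.

## The constraint-based model

A metabolic model is a stoichiometric matrix $S$ (metabolites × reactions),
flux bounds $lb \le v \le ub$ (mmol·gDW⁻¹·h⁻¹ by convention, ±1000 for
effectively unconstrained reactions), a Boolean gene-protein-reaction (GPR)
rule per reaction, and an objective reaction (biomass). Flux balance analysis
(FBA) assumes steady state and solves

$$\max_v\; c^\top v \quad \text{s.t.}\quad S v = 0,\;\; lb \le v \le ub .$$

The steady-state assumption means only flux *balance* matters: pool sizes of
conserved moieties (ATP/ADP, NAD/NADH) never appear, which is why a model can
"run" respiration without ever synthesizing its cofactors. GPR rules encode
enzyme complexes as AND (every subunit required) and isozymes as OR (any one
suffices); a reaction without a rule is not gene-constrained at all, and in
particular survives every knockout and every orthology mapping.

### Exchange conventions

Boundary (exchange/sink/demand) reactions touch exactly one metabolite and
are written in export direction: negative flux is uptake, so "the medium
provides glucose" means the glucose exchange has a negative lower bound. A
growth medium is a table of exchange bounds plus an `always_open` set (water,
protons, CO₂) that medium application never touches. Closing a model to a
medium sets the uptake bound of every *other* exchange to zero — either all
of them, or only the organic (carbon-containing) ones. Organic status is read
from the metabolite formula when present (any `C` element token; `Ca`, `Cl`
etc. do not match), falling back to a user-supplied list otherwise — the
field has no single convention here, so the rule is explicit and overridable.

## Orthology translation and triage

Reference-model GPRs are translated leaf by leaf through an orthology table
(source gene → target gene(s), with a provenance tag per pair):

* one orthologue → plain leaf;
* several orthologues → an OR over all of them. This is the permissive
  standard for orthology-transferred rules: paralogues are assumed
  functionally redundant until curated otherwise. A curator can narrow the
  set simply by editing the map, so no separate "resolved" mechanism is
  needed.
* no orthologue → a FALSE-marker leaf that records the failed source gene.
  Markers are deliberately kept in the tree rather than silently dropped:
  the whole point of the triage stage is to *see* which genes broke which
  rules.

Evaluating the source rule with "has an orthologue" as truth value splits
reactions into NGA (no rule), GAHM (rule still true — supported in both
organisms) and GAH (rule falsified — reference-only evidence). Every GAH
reaction must receive an explicit curation decision; `apply_curation()`
errors on uncovered GAH reactions rather than guessing, mirroring the manual
triage obligation of a real reconstruction. The three decision actions map to
the three curation outcomes seen in practice: `keep_with_gpr` (the rule was
wrong, e.g. a pseudogene stood in for the functional gene — the corrected
rule is re-translated and must map cleanly), `remove` (the reaction is an
artifact whose removal keeps the network consistent), and
`demote_to_non_gene` (the reaction lacks gene evidence in the target but is
needed for consistency; it keeps its original bounds — demotion changes
evidence status, not thermodynamics).

The core set is then GAHM ∪ curated keeps ∪ organism-specific additions ∪
designated artificial reactions (biomass, ATP maintenance — identified by id,
since they are modelling devices rather than gene products). The non-core set
is NGA ∪ demoted. FALSE markers are pruned only now: a marker under OR drops
that arm; a marker under AND would falsify a core reaction and raises an
error instead, because that case must go back to curation.

Organism-specific additions are records carrying their own stoichiometry,
bounds, target-space GPR and any new metabolites. After insertion, any new
metabolite that cannot be both produced and consumed gets an automatic
reversible sink, keeping the additions flux-consistent without manual
plumbing. The bundled additions file is a synthetic stand-in expressed over
the synthetic model's namespace (and is named accordingly); the curated
chemistry of a real reconstruction would replace it.

## The LP core

All analyses reduce to linear programs over the flux polytope. The package
ships its own bounded-variable two-phase primal simplex (C++, dense): Dantzig
pricing with smallest-index tie-breaks, a ratio test preferring the
largest-magnitude pivot among ties, automatic switch to Bland's rule after a
long run of degenerate pivots (guaranteeing termination), periodic basis
refactorization for numerical hygiene, and single-threaded deterministic
execution. Identical inputs therefore give bit-identical solutions; where the
optimum is degenerate, the returned vertex is arbitrary but reproducible.
Only objective values are contractual — downstream code never relies on a
particular optimal flux vector, except linear MOMA, which *fixes* the
recorded wild-type vector precisely so that its results are reproducible.

Tolerances: reduced-cost and pivot tolerances are 1e-9; phase-1 feasibility
is accepted below 1e-7; "almost zero" flux — blocked reactions, zero
objectives in functional tests — is 1e-6 throughout, the community convention
on ±1000-bounded networks. Infinite user bounds are clamped to ±1e6 at solve
time. Infeasibility and unboundedness are reported in the solution status,
never raised as errors: a knocked-out model that cannot grow is a result, not
a failure.

`fva()` computes per-reaction flux ranges as 2n individual solves, optionally
subject to the objective staying at or above a fraction of its optimum
(implemented as one extra equality row with a slack). Blocked-reaction
detection runs the fraction-0 sweep — pure flux-carrying capability — with
every exchange fully open; the open-exchange, fraction-0 convention is the
natural reading of consistency checking (a reaction is "blocked" if no
environment whatsoever lets it run), and each discovered flux vector is
cached so that most reactions are certified by earlier solves rather than
their own LPs. Dead-end metabolites are those that cannot be both produced
and consumed across non-blocked reactions, counting reversible reactions in
both directions; metabolites touched only by blocked reactions are dead ends
too.

## Gap filling and assembly

The minimal model must let every core reaction carry flux of at least
$\varepsilon$ (default 1e-4 — comfortably above the 1e-6 noise floor, far
below physiological fluxes) using as few non-core reactions as possible. The
implementation is a FASTCORE-style LP sweep: for each unsupported core
reaction, minimize the weighted L1 norm of candidate fluxes subject to that
reaction carrying $\pm\varepsilon$ (absolute values via split variables,
both directions tried for reversible cores), and add the candidates that
carry flux. A compaction pass then retries removing each added reaction
(most expensive first, ties lexicographic) while all cores stay fillable.

The result is guaranteed *inclusion-compact* — no added reaction is
redundant — but not globally minimum-cardinality: L1 relaxations of set-cover
problems are not exact, and the published LP-based gap-fillers share this
property despite the stronger language sometimes used for them. The test
suite quantifies the gap by exhaustive subset enumeration on instances with
≤ 14 candidates and logs the disagreement count rather than asserting
minimality as a theorem. Candidates demoted for consistency reasons get
weight 0: they are always admissible, which encodes their established role
in keeping the reference network consistent. Cores that cannot reach
$\varepsilon$ even with every candidate are reported as unfillable, never
silently dropped.

`assemble_models()` then builds the minimal (core + fill) and maximal
(core + all non-core) models. Since non-core reactions carry no gene
associations, the two models have identical gene sets by construction — a
structural invariant the tests assert.

## Functional validation

A metabolite conversion test (MCT) asks whether source metabolites can be
turned into target metabolites under a named medium: sources are supplied
through reversible sinks (±1000), targets drained through demand reactions
(0–1000) — existing boundary reactions are reused and opened rather than
duplicated — and the summed target demand is maximized. A reaction
optimization test (ROT) asks whether a named reaction can carry non-zero
optimized flux under an exchange-closure condition: organic uptakes are
closed except the test's substrates, which are opened at a fixed dose
(default 10 mmol·gDW⁻¹·h⁻¹), and oxygen uptake is allowed only aerobically.
The fixed dose makes the optimum a *yield*, so aerobic and anaerobic optima
are comparable instead of both saturating the objective's own upper bound.

Failures are classified exhaustively and mutually exclusively:
`missing_component` (a participating metabolite, or the ROT's objective
reaction, is absent from the model), `infeasible` (no optimal solution), and
`zero_objective` (optimum ≤ 1e-6). Multi-target MCTs additionally require
each target to be individually producible — a deliberate strengthening where
the aggregate objective alone could hide one dead target behind another's
flux; the semantics of multi-target conversions are not standardized, and
the stricter reading is the one that catches broken pathways. Test
scaffolding is strictly local: `run_mct()` never mutates its input model.
Suite summaries report pass/fail counts by kind and failure mode, plus the
tally restricted to tests whose components exist in the model — the fair
comparison when models differ in metabolite coverage.

## Expression processing

Sample QC follows the iterative correlation z-score procedure: per round,
compute all pairwise Pearson correlations, summarize each sample by its mean
correlation to the others, z-score those means (n−1 denominator), remove
every sample with |z| ≥ 2 — read inclusively, "two and more standard
deviations" — and repeat until no removals. Constant-profile samples, whose
correlation is undefined, are removed with their own reason code. The full
audit trail (per-round mean correlations, z-scores and removals) is
returned, because iterated outlier removal is exactly the kind of
preprocessing that must be auditable. Correlation is computed on the values
as given, with an optional log2 transform flag for raw-scale intensities.

Binarization maps Present → 1 and both Marginal and Absent → 0; a gene
measured by several probe sets takes the per-sample maximum over its probes
(a gene is expressed if any probe says so). Unmapped probes are dropped with
a count. Gene ubiquity is the row mean of the resulting call matrix — the
fraction of retained samples in which the gene is expressed — with genes
absent from the platform scored 0 under a warning. QC precedes binarization
in the pipeline: array-level artifacts should be caught on the raw
correlation structure, not after thresholding has flattened it.

## Tissue extraction

Reactions are scored two ways: the expression score propagates gene ubiquity
through the GPR with AND → min and OR → max (a complex is only as expressed
as its scarcest subunit; any isozyme suffices), and the connectivity score is
the mean expression score of the reactions sharing at least one non-currency
metabolite. The currency list (protons, water, ATP/ADP, phosphate, NAD/NADH
by default) exists because cofactors connect nearly everything to nearly
everything; without the exclusion the adjacency graph is degenerate and the
connectivity score uninformative.

Reactions scoring at or above the core threshold (inclusive) are protected;
the rest are attacked in order of ascending expression score, ties by
ascending connectivity, remaining ties lexicographic — weakest evidence
first, and fully deterministic. Confidence scores play no role in the
ranking. Each tentative removal must pass three guards or be rolled back:

1. **function** — every configured key metabolite stays producible from the
   source metabolite (glucose) under the pruning medium, checked as a
   per-metabolite conversion test;
2. **consistency** — no core reaction becomes blocked (checked with open
   exchanges, cached fluxes making the common case one or two LPs);
3. **biomass** — the biomass optimum under the medium stays at or above 80%
   of the parent genome-scale model's optimum. The biomass reaction itself
   is trivially retained.

The key-metabolite list is configuration, not doctrine: the biomass
precursors are the natural default and what the examples use, but the right
list is tissue- and project-specific. The original mCADRE's salvage-pathway
rescue rules and its zero-expression removal precondition are intentionally
not implemented — the pruning loop here is the threshold/rank/guard cycle
plus the biomass floor, nothing more.

Raising the core threshold shrinks the protected set and should shrink the
final model; the tests assert this monotonicity at thresholds 0.5 / 0.7 /
0.9 on the synthetic suite, and the 80% biomass floor post hoc.

## Gene essentiality

`single_gene_deletion()` constrains to zero every reaction whose GPR is true
with all genes but false without the deleted gene, then either re-maximizes
biomass (FBA — the cell instantly re-optimizes) or solves linear MOMA:

$$\min_{v_d}\; \sum_i |v_{w,i} - v_{d,i}| \quad \text{s.t.}\quad
S v_d = 0,\;\; lb_d \le v_d \le ub_d ,$$

with the knockout biomass read off $v_d$ — the cell stays as close as
possible to its old flux state rather than re-optimizing, which is why lMOMA
knockout growth can never exceed the FBA knockout optimum (a property the
tests check). The wild-type vector $v_w$ is the FBA optimum recorded by the
deterministic solver; optimal vertices can be degenerate, so fixing the
solver and storing $v_w$ in the output is what makes lMOMA results
reproducible and auditable. An infeasible knockout model scores objective 0
by convention. A gene is essential when its growth ratio falls strictly
below 0.30 of the wild-type optimum ("less than" is read literally), and
genes absent from a model are reported as skipped and excluded from its
confusion matrix, with the evaluated count attached so both raw and
coverage-adjusted denominators are available. Sensitivity is TP/(TP+FN) over
lethal-labelled genes, specificity TN/(TN+FP) over viable-labelled ones,
reported as proportions and as nearest-integer percentages (the convention
knockout screens are tabulated in). Quadratic MOMA is out of scope.

## The synthetic test bed

The generators exist so that every stage has small, fully characterized
inputs with known ground truth. All are pure functions of a seeded
configuration.

**Reference model.** A fixed central skeleton — glucose uptake, lumped
glycolysis with an NAD/NADH couple, fermentation, a mitochondrion-like
compartment with a TCA/ETC pair, an explicit redox shuttle, biomass
precursor synthesis (amino-acid, nucleotide and lipid pools; one phosphate is
incorporated per nucleotide so the network has a genuine net Pi demand), ATP
maintenance and a ≥3-precursor biomass — decorated with seeded peripheral
pathways carrying single-gene, isozyme-pair (OR) and complex-pair (AND)
rules, plus host routes for the substrates of the bundled curated additions.
A configurable fraction of gene associations is stripped to emulate
non-gene-associated reference reactions. The generator self-checks flux
consistency and growth on the bundled HAM-style medium and refuses to return
a model that fails either. Default scale (~60–80 reactions, ~45–60 genes) is
chosen so exhaustive oracles — truth tables over GPRs, subset enumeration
for gap-fills, per-gene brute-force knockouts — stay cheap while leaving
room for nontrivial gap-filling and pruning.

**Orthology map.** Each gene is unmapped with probability
`unmapped_fraction` (default 0.08, a coverage in the spirit of real
mammalian orthology searches), one-to-two with probability
`one2many_fraction` (0.15), else one-to-one. The expected NGA/GAHM/GAH
classification is computed by an independent inline Boolean evaluator and
returned as ground truth. Synthetic curation decisions are derived by
actually testing removability: a GAH reaction whose removal blocks nothing
is removed, one that breaks consistency is demoted.

**Expression calls.** Clean samples share a per-probe baseline and split
into two array-quality batches (noise sd 0.2 vs 1.0). The two-level design
is deliberate: each clean sample's mean-correlation z-score then sits near
±1, far from the |z| ≥ 2 cutoff, while a planted outlier — an independent
baseline draw, hence decorrelated — lands near the theoretical z extreme.
This makes "the planted outliers and nothing else" a well-defined QC truth
across seeds. A graded ladder of noise levels was tried first and rejected
at design time: per-sample variance jitter pushed the noisiest clean array
across the cutoff in a nontrivial fraction of seeds, leaving the planted
truth ill-defined. Calls are P with probability 0.9 for tissue-active genes
and 0.1 for inactive ones (M 0.05 each), random for outlier arrays; genes
carry 1–3 probes.

**Ground truth and battery.** Lethal/viable labels come from exhaustive
per-gene knockout FBA under the HAM-style medium, computed through an LP
assembled directly from the stoichiometry tables and an independent GPR
evaluator — not through the analysis functions under test. The functional
battery holds one glucose→precursor MCT per non-currency biomass precursor,
glucose→pyruvate and glucose→lactate conversions, and aerobic/anaerobic ATP
maintenance ROTs, all verified satisfiable on the generating model.

**What passing does and does not show.** The synthetic networks are small,
fully flux-consistent, and free of real-world pathologies: no compartment
ambiguity, no mass-imbalanced legacy reactions, no thermodynamically
infeasible loops (so loopless analyses are not needed and not implemented),
no probe cross-hybridization, no batch effects beyond the planted structure.
Green tests establish that the algorithms are implemented correctly — GPR
logic matches truth tables, FVA matches its definition, gap-fills are
compact and (on these instances) minimal, pruning respects its guards,
essentiality matches brute force. They do not establish that a real
reconstruction built with this package is biologically right; that still
takes curation.

## Known limitations

* Dense LP: fine into the low thousands of reactions, not engineered for
  genome-scale FVA throughput (no warm starts across solves, no parallel
  sweep).
* SBML support targets Level 3 + FBC v2 as written by this package and the
  common COBRA-style exporters; exotic SBML constructs (initial assignments,
  rule-defined bounds) are out of scope. Identifiers are round-trip-exact
  for the `[A-Za-z0-9_]` alphabet; other characters are sanitized on write.
* Gap-filling is inclusion-compact, not provably minimum-cardinality (see
  above).
* The mCADRE variant implements exactly the ranking and guards described
  here; confidence scores and salvage rescues are omitted by design.
* MAS5 call generation, CEL parsing and expression preprocessing beyond the
  QC/binarization steps are out of scope — the pipeline consumes calls, it
  does not produce them.
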