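{
  "comment": "Mouse-specific curated additions over the synthetic reference model namespace: the four KEGG reactions absent from the human reference (L-gulonolactone oxidase, L-threonine 3-dehydrogenase, and the two CMP-N-acetylneuraminate hydroxylase reactions) with their four new metabolites. Substrates/products other than the four new metabolites are hosted by the synthetic reference model; this file is a synthetic stand-in for the curated addition table, not the curated chemistry itself.",
  "reactions": [
    {
      "id": "R10053",
      "name": "L-gulono-1,4-lactone:oxygen 3-oxidoreductase",
      "stoichiometry": {"guln_c": -1, "o2_c": -1, "ascb_c": 1, "h2o_c": 1},
      "lb": 0, "ub": 1000,
      "gpr": "268756",
      "subsystem": "Ascorbate metabolism",
      "metabolites": []
    },
    {
      "id": "R01465",
      "name": "L-threonine:NAD+ oxidoreductase",
      "stoichiometry": {"thr__L_c": -1, "nad_c": -1, "2aobut_c": 1, "nadh_c": 1, "h_c": 1},
      "lb": 0, "ub": 1000,
      "gpr": "58865",
      "subsystem": "Amino acid metabolism",
      "metabolites": []
    },
    {
      "id": "R01803",
      "name": "N-acetylneuraminate,ferrocytochrome-b5:oxygen oxidoreductase",
      "stoichiometry": {"acnam_c": -1, "focytb5_c": -2, "o2_c": -1, "HC01115_c": 1, "ficytb5_c": 2, "h2o_c": 1},
      "lb": 0, "ub": 1000,
      "gpr": "12763",
      "subsystem": "Aminosugar metabolism",
      "metabolites": [
        {"id": "HC01115_c", "name": "N-glycoloylneuraminate", "formula": "C11H19NO10"},
        {"id": "ficytb5_c", "name": "ferricytochrome b5", "formula": "C34H31FeN4O4"},
        {"id": "focytb5_c", "name": "ferrocytochrome b5", "formula": "C34H32FeN4O4"}
      ]
    },
    {
      "id": "R01115",
      "name": "CMP-N-acetylneuraminate,ferrocytochrome-b5:oxygen oxidoreductase",
      "stoichiometry": {"cmpacna_c": -1, "focytb5_c": -2, "o2_c": -1, "cmpglna_c": 1, "ficytb5_c": 2, "h2o_c": 1},
      "lb": 0, "ub": 1000,
      "gpr": "12763",
      "subsystem": "Aminosugar metabolism",
      "metabolites": [
        {"id": "cmpglna_c", "name": "CMP-N-glycoloylneuraminate", "formula": "C20H31N4O17P"}
      ]
    }
  ]
}
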