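Package: gepnetcea
Title: Cost-Effectiveness of Immediate Versus Delayed Somatostatin
    Analogues in Metastatic GEP-NETs
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Markov cohort state-transition model comparing immediate
    initiation of somatostatin analogues (SSAs) at diagnosis of metastatic
    gastroenteropancreatic neuroendocrine tumors (GEP-NETs) against delaying
    SSAs until disease progression, with peptide receptor radionuclide
    therapy (PRRT) after progression in both arms. Provides a generic
    time-inhomogeneous cohort engine with competing-risk transition
    assembly, half-cycle correction, discounting and an individual-level
    microsimulation oracle; period life-table utilities including a
    synthetic Gompertz-Makeham generator; base-case cost-effectiveness
    outcomes (costs, life-years, QALYs, ICER, net monetary benefit);
    one-way deterministic sensitivity analysis (tornado), threshold price
    analysis, and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
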