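Package: npccea
Title: Markov Cohort Cost-Effectiveness Model for Induction Chemotherapy
    in Nasopharyngeal Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state (disease-free survival, progressed disease,
    death) Markov cohort model comparing gemcitabine-cisplatin (GP) against
    docetaxel-cisplatin-fluorouracil (TPF) induction chemotherapy for
    locoregionally advanced nasopharyngeal carcinoma, from the Chinese
    healthcare-system perspective.  Provides parametric (Weibull and
    exponential) survival laws and per-cycle transition probabilities,
    pseudo individual-patient-data reconstruction from digitized
    Kaplan-Meier curves with parametric refitting, cycle-indexed cost and
    utility accrual with discounting, incremental cost-effectiveness ratios
    with dominance classification, one-way (tornado) and probabilistic
    (Monte Carlo) sensitivity analysis with cost-effectiveness
    acceptability curves, a single-use-vial drug-wastage scenario, and a
    synthetic-data module that generates every input the pipeline needs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    flexsurv,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
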