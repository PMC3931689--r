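Package: betamyo
Title: Compartmentalized Beta1-Adrenergic Signaling in Mouse Ventricular
    Myocytes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic simulation of the beta1-adrenergic signaling
    cascade of mouse ventricular myocytes with three functional signaling
    compartments (caveolae, extracaveolae, cytosol), coupled to a whole-cell
    action-potential and calcium-dynamics model. Includes Markov gating
    models with paired non-phosphorylated/phosphorylated sub-diagrams for
    the two L-type calcium channel populations, the fast sodium channel and
    the ryanodine receptor; receptor, G-protein, adenylyl cyclase,
    phosphodiesterase, protein kinase A and phosphatase/inhibitor-1 modules;
    a protocol engine for pacing, voltage-clamp and timed drug events; and
    analysis utilities for action-potential, calcium-transient and flux
    metrics. All rate constants flow from a machine-readable parameter
    ledger with per-entry provenance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
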