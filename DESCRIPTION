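Package: qtddi
Title: Virtual Clinical Trials of Drug-Drug Interaction Effects on the QT Interval
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the electrophysiological consequences of drug-drug
    interactions (DDI) on ventricular repolarization. Per-channel Hill-equation
    block of IKr, IKs, INa and ICaL is combined across two co-administered drugs
    under three interaction models (capped arithmetic sum, Bliss independence,
    Loewe additivity), applied as conductance scaling to the ten Tusscher-Panfilov
    2006 human ventricular myocyte model, and propagated through a heterogeneous
    1D transmural strand to yield pseudo-ECG signals, QT intervals and
    Bazett-corrected QTcB. A synthetic pharmacokinetic generator produces
    heart-tissue concentration profiles with log-normal inter-individual
    variability and inhibitor-driven exposure increases, so that replicate virtual
    QT trials can be run and compared against observed clinical values with a
    triplet distance metric, Welch t tests and a 5-ms regulatory-threshold
    model-flip analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
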