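Package: oligopk
Title: Preclinical-to-Human Pharmacokinetic Translation for Oligonucleotide Therapeutics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-compartmental analysis of intravenous-bolus plasma
    concentration-time profiles (terminal slope, half-life, back-extrapolated
    C0, trapezoidal AUC, clearance, terminal volume), ultrafiltration
    plasma-protein-binding arithmetic with non-specific-binding correction,
    interspecies allometric scaling of total and unbound clearance by
    two-species log-log regression, the fixed-exponent Tang rule and
    single-species weight-ratio scaling, and first-in-human dose translation
    (human equivalent dose, pharmacodynamically active dose, maximum
    recommended starting dose) with exposure prediction. Ships the
    LNA-i-miR-221 preclinical reference dataset and a simulation module for
    multi-exponential bolus kinetics and binding assays with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
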