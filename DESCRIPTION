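Package: n2okie
Title: Bulk and Position-Specific Kinetic Isotope Effects of N2O from
    Closed-System Rayleigh Fractionation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving bulk and position-specific nitrogen
    kinetic isotope effects (KIEs), enrichment factors and N2O site
    preference from closed-system enzymatic reaction time series, as
    measured by trace-gas isotope ratio mass spectrometry. Implements
    delta-notation arithmetic and isotope-atom accounting, reaction
    progress bookkeeping for the 2 NO -> N2O stoichiometry, the
    Mariotti linearisation of the Rayleigh equation for bulk 15N and
    18O trends, the Expanded Rayleigh model (nonlinear estimation of
    the 15N-alpha share rho and averaging of the 14N-alpha share tau)
    for position-specific fractionation factors, Grubbs one-outlier
    screening of regression residuals, bootstrap uncertainty for KIE
    and RMSE statistics, and a forward simulator of closed-system
    position-specific fractionation for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
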