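Package: chemosc
Title: Oscillation Analysis for Continuous Glycerol Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spontaneous metabolic oscillations of
    Clostridium butyricum in glycerol-fed chemostat culture producing
    1,3-propanediol. Computes specific rates (growth, substrate uptake,
    product and gas formation) from concentration time series via chemostat
    mass balances with local-polynomial derivative estimation; detects
    oscillations, segments cycles into rising/falling stages, extracts
    per-cycle extrema, phase positions and inter-channel lags, and
    classifies sustained, damped and non-oscillatory regimes; quantifies
    NAD+/NADH pools from enzymatic-cycling assay slopes by linear
    calibration and formate dehydrogenase activity from absorbance slopes;
    quantifies gene expression as transcripts per million with trimmed-mean
    normalization, fold changes, a differential-expression filter and
    oscillation-phase pattern calls; and summarizes genome assemblies
    (scaffold count, total length, N50, GC content). A mass-balance
    consistent synthetic data generator emulates the bioreactor study
    conditions with retained ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
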