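Package: ratechase
Title: mRNA Decay Kinetics and Regulation Analysis from Transcription-Arrest Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-gene mRNA degradation rate constants and half-lives
    from rifampicin-chase (transcription-arrest) intensity time courses,
    decomposes mRNA-level changes between growth conditions into
    transcriptional and degradational regulation coefficients (rho_T, rho_D),
    models half-life determinants with an AIC-selected covariance (ANCOVA)
    model over computed sequence features (CAI, tAI, GC content, upstream
    folding energy, motif counts), and clusters half-life profiles across
    growth rates with Ward's method. Includes a synthetic-data generator with
    known per-gene ground truth so every stage of the pipeline can be
    validated end to end.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
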