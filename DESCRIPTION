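Package: incretinbias
Title: Operational-Model Bias Analysis for Glucagon-Family Receptor Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy analysis pipeline for plate-reader pharmacology of the
    glucagon-family receptors (GLP-1R, GIPR, GCGR): kinetic trace
    normalization for NanoBiT, BRET and DERET assays, trapezoidal AUC and
    half-time summaries, three- and four-parameter logistic
    concentration-response fitting with per-replicate-block summaries,
    Black-Leff operational-model fitting with shared system parameters,
    transduction-coefficient biased-agonism statistics
    (delta-delta-log(tau/KA) with between-assay 95% confidence intervals
    and anti-logged bias factors), and Mesna-cleavage receptor
    internalization quantification. A synthetic-data generator emulates the
    randomized-block assay designs so every stage of the pipeline can be
    exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
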