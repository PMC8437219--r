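Package: crcscreen
Title: Multistate Cohort Simulation of Colorectal Cancer Screening and
    Longitudinal Adherence Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic multistate (Markov) cohort simulation of the
    colorectal adenoma-carcinoma sequence, with screening by fecal
    immunochemical testing (FIT) or colonoscopy interrupting the natural
    history through adenoma removal and early detection of preclinical
    cancer. Implements selective adherence (a fixed fraction of the
    population attends every offered screen) and sporadic adherence (the
    whole population attends a subset of offered rounds), computes
    cumulative colorectal cancer cases, deaths and years of potential life
    lost over a multi-decade horizon, percentage reductions against a
    no-screening baseline, and sporadic-versus-selective ratios of
    prevented outcomes at matched overall adherence levels. Includes a
    validated plain-text parameter format with confidence-interval
    variants for sensitivity analysis, and a seeded synthetic parameter
    generator emulating the structure of screening-registry derived
    inputs.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
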