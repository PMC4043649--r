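Package: cytovar
Title: Simulation and Variability Analysis of Murine Myeloid Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying biological and technical variability of circulating
    murine myeloid cell subsets measured by bead-based flow cytometry. Provides a
    synthetic whole-blood listmode generator (log-normal population templates,
    TruCount-style counting beads, between-animal cohort variability, duplicate-level
    technical noise, and post-surgery longitudinal kinetics), spillover estimation and
    compensation, a bi-exponential display transform, a deterministic sequential gating
    hierarchy for classical, intermediate and non-classical monocytes, neutrophils,
    eosinophils and activated monocytes/macrophages, bead-based absolute quantification,
    and the downstream variability analytics: cohort summaries, duplicate inter-assay
    coefficients of variation, baseline-delta kinetics, and inter-group versus
    intra-group CV time courses. Includes a minimal FCS 3.1 reader and writer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
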