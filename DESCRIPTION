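Package: coalesceR
Title: Oral-Stool Microbial Community Coalescence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Longitudinal analysis of oral and intestinal microbiome community
    coalescence in patients undergoing induction chemotherapy. Provides alpha-
    and beta-diversity metrics (Shannon, observed OTUs, Bray-Curtis, unweighted
    and weighted-normalized UniFrac), principal coordinates analysis, PERMANOVA,
    confidence-ellipse overlap and hierarchical clustering of distance matrices,
    a bottom-quartile minimum-distance coalescence classifier with shared-to-
    unique OTU and domination-event validations, random-intercept linear mixed
    models of diversity trajectories, time-varying Cox proportional hazards
    models of per-day antibiotic exposure on the coalescence hazard, infection
    outcome association statistics, and a fully synthetic longitudinal two-site
    cohort generator with known ground truth for calibration and testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    phangorn,
    survival,
    withr
Config/testthat/edition: 3
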