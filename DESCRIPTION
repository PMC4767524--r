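Package: preyswarm
Title: Visual-Attention Collective Motion of Social Prey and Predator Targeting Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates self-propelled groups of social prey whose coordination
    emerges from motion-guided visual attention: each individual weights its
    neighbours' movements by apparent (optic-flow) motion, attends only to
    those exceeding a Weber-law threshold relative to the mean flow, and
    regulates its speed around an energetic optimum. Includes the full
    experiment machinery around the model: factorial scenario design with
    seed-replayed veiled/visible trial pairs, a scripted surrogate predator
    with capture latency and accuracy scoring (including edge-effect
    correction), per-trial kinetic metrics (tortuosity, polarization, Voronoi
    polygon area, nearest-neighbour distance), and the analysis-side data
    preparation pipeline (threshold transforms, standardization, collinearity
    screening with sequential residualization and variance inflation factors).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
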