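Package: zebratrax
Title: Zebrafish Behavioral Phenotyping from Tracking Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for zebrafish neurobehavioral assays starting
    from per-frame 2-D tracking coordinates: locomotor activity binned per
    30 s, light/dark visual motor response, open-field thigmotaxis, juvenile
    and adult social preference indices, and shoaling cohesion (mean
    inter-individual distance), together with the group-comparison scheme
    used in behavioral phenotyping (Student's t / ANOVA-Dunnett for normal
    data, Mann-Whitney / Kruskal-Wallis-Dunn otherwise). Includes a seeded
    correlated-random-walk trajectory simulator with genotype presets so the
    full pipeline can be exercised and validated without raw video
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    jsonlite,
    yaml,
    multcomp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
Config/testthat/edition: 3
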