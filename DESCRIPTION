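Package: vhpotools
Title: Discovery and Stress-Expression Analytics for Vanadium-Dependent
    Haloperoxidases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A proteo-transcriptomic toolkit for vanadium-dependent
    haloperoxidases (vHPOs) in marine algae. Extracts six-frame open
    reading frames from assembled transcriptome contigs, assigns
    candidates to the three structural vHPO groups by Smith-Waterman
    local alignment against reference enzymes, curates the three
    vanadate-binding motifs (including the catalytically essential
    covalent histidine), and computes sequence features (average
    molecular mass, Bjellqvist isoelectric point, Kozak start context).
    Companion wet-lab analytics cover bromoperoxidase activity from
    thymol-blue absorbance kinetics (Beer-Lambert unit conversion),
    RT-qPCR relative expression by the 2^-ddCq method under two
    calibrator schemes with reference-gene evaluation, Dunnett
    many-to-one testing via a seeded Monte-Carlo max-|t| reference
    distribution, and control-corrected Fv/Fm photosystem-II damage
    metrics. A seeded synthetic-data generator provides ground-truth
    transcriptomes, kinetic traces, Cq tables and Fv/Fm trajectories for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    multcomp,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
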