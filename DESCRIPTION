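Package: scatgen
Title: Noninvasive Microsatellite Genotyping Validation and Individual
    Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for validating codominant microsatellite marker panels
    on noninvasively collected samples (scat, hair) against high-quality
    reference samples (blood, tissue).  Implements paired blood-versus-scat
    genotyping-error assessment (missing data, allelic dropout, false
    alleles), multiple-tubes consensus calling, per-locus informativeness
    statistics (observed/expected heterozygosity, polymorphic information
    content, rarefied allelic richness, EM null-allele frequency,
    exact-conditional Hardy-Weinberg tests), identity and parentage-exclusion
    power (P_ID, P_IDsib, P_E2) with PIC-ranked minimal panel selection,
    and reference-anchored individual identification of field genotypes
    tolerating missing loci, plus a calibrated synthetic-data generator
    emulating the scat observation process with ground truth retained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
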