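Package: methylscreen
Title: Quality Control Screening for Infinium DNA Methylation Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extended quality control for Illumina Infinium DNA methylation
    BeadChips (450K/EPIC). Computes the 17 BeadArray control metrics and
    flags samples against manufacturer-style thresholds, infers donor sex
    from normalized X/Y total intensities with robust Hodges-Lehmann
    cutoffs, fingerprints sample identity via a four-component mixture
    model (three Beta genotype clusters plus a uniform outlier component)
    fitted to SNP-probe beta-values, quantifies per-sample contamination
    with a single foreign DNA source through a generative model estimated
    by Metropolis-within-Gibbs sampling, and summarises outlier burden as
    an average log-odds score. Ships a fully parameterised synthetic-data
    generator with known ground truth so every check is testable offline,
    plus a command-line entry point chaining the checks into one QC run.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
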