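Package: scnatime
Title: Timing Macro-Evolutionary Events in Tumor Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the macro-evolutionary history of tumor genomes from
    allele-specific integer copy-number segments and somatic SNV multiplicities.
    Detects whole-genome doubling (WGD) by a Monte Carlo test on the
    major-allele genome fraction, times WGD against copy-number losses via
    two-copy genotype proportions (AB versus AA/BB), classifies focal copy
    number alterations as pre- or post-doubling by copy-number parity rules,
    estimates molecular times of duplication events (arm gains, copy-neutral
    LOH, WGD) from clonal mutation multiplicity counts under a Poisson
    mutation clock, partitions copy-neutral LOH into doubling-derived and
    intrinsic mechanisms, deconstructs arm profiles into telomere-bounded
    copy-number steps, and computes genome-instability metrics such as the
    weighted genome instability index. A simulator of tumor genomes with
    planted, ordered event histories and lineage-consistent mutation
    multiplicities supports end-to-end validation of every estimator.
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
    withr,
    knitr
Config/testthat/edition: 3
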