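Package: ydegen
Title: Y-Chromosome Gene-Loss Estimation from Combined BAC and RNA-seq
    Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating gene loss from young plant sex
    chromosomes by combining BAC-located sex-linked genes with sex-linkage
    calls from RNA-seq studies. Implements tabular BLAST-hit filtering,
    merging of per-study contig classifications into per-gene categories,
    gene-density comparisons normalised by genome and chromosome size, and
    a false-negative-rate-corrected estimator of the proportion of
    X-hemizygous (Y-copy-lost) genes, with a synthetic-data generator for
    validating the estimator's ascertainment-bias correction by parameter
    recovery.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
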