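Package: baseditr
Title: Guide Design and Outcome Quantification for Bacterial Base Editing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and auditing CRISPR base-editor interventions in
    bacterial genomes. Enumerates NGG protospacers and designs inactivating guides
    (premature stop codons with cytosine base editors, start-codon disruption with
    adenine base editors), scans genomes for candidate off-target protospacers under
    positional mismatch constraints, converts aligned reads into per-position
    nucleotide pileups and read-mismatch frequencies, profiles editing windows to
    quantify on-target and bystander edit fractions, compares treated and control
    samples genome-wide, estimates genotype ratios from dual-channel digital droplet
    PCR partition counts via Poisson statistics, converts selective plate counts to
    edited fractions, and fits single-hit delivery dose-response models. A synthetic
    data generator produces genomes with planted protospacer decoys, per-molecule
    edited reads with sequencing error, droplet partitions and plate counts for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
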