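Package: popaf
Title: Population-Aware Allele Frequency Annotation for Variant Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Haplotype-based matching of candidate variant alleles against a
    population reference panel, robust to representation differences
    (left-alignment shifts, padding bases, MNP decomposition).  Computes
    population-stratified allele frequencies from multi-sample panel VCFs
    with missing genotypes filled as homozygous reference, encodes matched
    frequencies as a log-transformed pileup-image channel, and provides
    single-sample evaluation (common/rare stratification, model-specific
    error analysis) and cohort-level rare-variant quality metrics
    (frequency-binned homozygote counts, Ti:Tv ratios, frameshift-indel
    counts).  Includes a seeded synthetic-data generator producing every
    input format the toolkit consumes, with ground-truth ledgers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    vcfR,
    Biostrings,
    Rsamtools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
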