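Package: fnmut
Title: De Novo Variant Isolation and Mutational Spectrum Analysis for
    Mutagenized Inbred Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for contrasting induced mutations in mutagenized
    inbred lines (e.g. fast-neutron irradiated soybean) with standing
    variation in a diversity panel. Implements a filter chain that
    isolates homozygous singleton de novo variants from multi-sample
    VCFs by subtracting parental and panel variants, masking
    ascertainment-blind regions, and applying quality and carrier
    rules; strand-collapsed six-class mutational spectra with Ts/Tv
    summaries; flanking-nucleotide context profiles scored by relative
    entropy against a resampled same-base null; indel length spectra
    and a minimal gene-model-based consequence classifier (frameshift,
    missense, synonymous and related labels); pairwise nucleotide
    diversity and spontaneous-mutation expectations; and a fully
    seeded synthetic-data generator with planted truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
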