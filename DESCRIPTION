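Package: proteotyper
Title: Bacterial Proteotyping by FDR-Free Peptide-Spectrum-Match Counting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies bacterial species and strains from bottom-up
    proteomics data by counting peptide-spectrum matches (PSMs) against an
    in-silico digested reference peptidome, without false-discovery-rate
    filtering. Implements the two-iteration species-then-strain workflow
    (with genus alias merging and an alternate-kingdom fallback database),
    reference database construction from NCBI-style taxonomy and assembly
    metadata, tryptic digestion with I/L collapsing, chunked-search merging,
    Jaccard peptidome similarity and unique-peptide fractions, iBAQ
    abundance normalizations, orthogroup conservation classification via
    taxon-specific conservation arrays and hamming distance, and a synthetic
    proteome/PSM simulator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    xml2,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
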