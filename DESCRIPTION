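Package: maveinfo
Title: Information Content Scoring for Clinical Variant Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies clinical variant-classification evidence in bits of
    information. Converts probabilities of pathogenicity to binary Shannon
    entropy and information content, combines ACMG/AMP evidence codes as
    odds of pathogenicity under the Bayesian points framework, scores the
    total information yield of multiplexed assays of variant effect (MAVEs)
    including variants that are not reclassified, computes the total possible
    missense information of a gene by enumerating single-nucleotide
    substitutions over the genetic code, and audits the apparent information
    effect of classification-guideline rule changes across the range of
    prior probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
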