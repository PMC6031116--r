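Package: sipscope
Title: Stable Isotope Probing Density Gradients and Genome Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of DNA stable isotope probing (SIP)
    experiments on CsCl buoyant density gradients. Converts between GC
    content, 13C atom-fraction excess, refractive index and buoyant
    density; bins gradient fractions into light/middle/heavy classes
    against an unlabeled control; normalizes per-fraction genome coverage
    and estimates isotope enrichment of a recovered genome; validates a
    circularized genome by GC skew and predicts the replication origin and
    terminus; and computes comparative genome statistics tables. Includes
    a synthetic-data generator for gradients and skewed genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
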