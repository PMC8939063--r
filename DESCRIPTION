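Package: nabsel
Title: Divergent Mass Selection for Natural-Antibody Titers with a Major
    Dominant Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying divergent mass selection on keyhole limpet
    hemocyanin (KLH) binding natural-antibody titers in layer chickens when a
    single near-fully dominant major locus segregates alongside a polygenic
    background. Provides pedigree validation, the numerator relationship
    matrix, its sparse inverse and inbreeding summaries; a forward-in-time
    simulator of a two-line breeding design with truncation selection,
    maternal environmental effects, ELISA plate effects and a biallelic major
    gene; restricted maximum likelihood (REML) estimation and best linear
    unbiased prediction (BLUP) for animal models with maternal effects,
    including bivariate fits, likelihood-ratio tests, genotype contrasts and
    genetic trends; and deterministic selection theory for selection
    intensity, expected response, major-gene allele-frequency trajectories
    and decomposition of response into major-locus and polygenic parts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
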