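Package: bdmgamete
Title: Two-Locus Gametophytic Incompatibility Models for Segregation
    Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of transmission ratio distortion caused by two-locus
    Bateson-Dobzhansky-Muller incompatibilities acting on the male
    gametophyte, as arises from reciprocal loss of duplicated genes in
    interspecific rice crosses.  Computes expected genotype and
    pollen-fertility-class distributions for selfing and backcross designs
    under haplotype-specific gametic selection; fits candidate selection
    models to per-plant genotype and pollen-count data by maximum
    likelihood; models transgene rescue of sterile pollen and estimates
    transgene copy number from T1 segregation; provides exact and
    chi-square segregation tests, map-function conversions and
    distortion-aware two-point linkage estimation; and includes a seeded
    population simulator so every stage can be exercised without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
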