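Package: exsituaudit
Title: Auditing Ex Situ Conservation of Genetic and Ecogeographic Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how well living ex situ collections (botanic gardens,
    arboreta) represent the wild diversity of a plant species. Reads diploid
    microsatellite genotypes in GENEPOP format, builds pooled in situ allele
    catalogs with frequency classes, and computes allele-capture percentages
    overall, per region, and per garden; estimates minimum sample sizes for a
    target capture threshold by simulated subsampling (with an exact
    hypergeometric oracle); contrasts gardens against wild regions with
    Weir-Cockerham F_ST; and measures geographic and ecoregion coverage of
    collection source localities with buffered occurrence points in an
    equal-area projection. A synthetic-data generator emulating a two-region
    metapopulation with half-sib garden families supports testing and power
    exploration without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
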