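Package: cpcapture
Title: Testing Chloroplast Capture Against Incomplete Lineage Sorting
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Distinguishes chloroplast capture from incomplete lineage
    sorting (ILS) as explanations of cytonuclear discordance. Simulates
    plastome gene trees under the multispecies coalescent contained within
    a ploidy-rescaled species tree, scores discordance with the
    information-based generalized Robinson-Foulds distance (mutual
    clustering information variant), and tests an empirical plastome tree
    against the resulting ILS null distribution with both a one-sample
    t-test and a rank-based empirical p-value. Also provides a synthetic
    data generator with controllable plastome-capture events, plastid CDS
    pseudogene classification (intact, premature stop, large deletion),
    gap-fraction alignment column filtering, and supermatrix
    concatenation with partition tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    phangorn,
    withr
Config/testthat/edition: 3
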