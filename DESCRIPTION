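Package: mtlineage
Title: Mitochondrial HVSI Haplotype Analysis for Recovering Extinct
    Matrilineages from Extant Populations
Version: 0.1.0
Authors@R: person("Queixadinha", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for mitochondrial DNA control-region (HVSI) haplotype
    studies in admixed populations: rCRS-anchored variant and motif calling,
    ancient-DNA two-fragment consensus with strand-concordance filtering of
    phantom mutations, multi-tier haplogroup classification (HVSI motifs,
    RFLP marker panel, coding-region minisequencing panel), matrilineal
    deduplication from three-generation pedigrees, Nei gene and nucleotide
    diversity with sampling variances, Monte-Carlo chi-square and exact
    tests of population differentiation, median-joining haplotype networks,
    exact haplotype matching against reference panels, and a seeded
    synthetic-data generator emulating haplogroup-structured matrilineal
    drift with bottlenecks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
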