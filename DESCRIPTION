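Package: wzkit
Title: Copy-Number, Association and Expression Toolkit for WZ/ZZ
    Sex-Determination Candidate Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping female-heterogametic (WZ/ZZ) sex-determination
    candidate genes from copy-number variation of gene duplicates, as applied
    to the banf2/banf2w locus of cichlid fish. Implements mixture
    decomposition of composite Sanger chromatograms by non-negative least
    squares, integer copy-ratio model inference, exact (Fisher and
    Freeman-Halton) marker-sex association tests, Hardy-Weinberg and
    constrained inheritance-model goodness-of-fit, gene-structure validation
    with GT-AG splice-site checks, windowed sequence divergence, and exact
    32-mer probe quantification of haplotype-specific expression (FPKM). A
    seeded synthetic-data generator produces haplotype sets, composite
    chromatograms, case-control cohorts and read libraries with planted probe
    occurrences, so the whole inference chain is testable without external
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    pracma,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
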