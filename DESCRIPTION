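Package: xlscreen
Title: Reporter-Ion Delta-Mass Screening for Residue-Specific
    Protein-Metabolite Cross-Links
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of small-molecule ligands covalently cross-linked to a
    specific residue of a carrier peptide from bottom-up LC-MS/MS data.
    Implements exact monoisotopic mass arithmetic, in silico proteolysis and
    reporter-peptide selection, mzML/MGF ingestion, a reporter-ion based
    delta-mass screen with retention-time and mass-window criteria,
    error-propagation-aware annotation of delta-masses against a local
    compound table, extracted-ion-chromatogram quantification of
    cross-linking yields, and a deterministic synthetic-run generator for
    end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    mzR,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
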