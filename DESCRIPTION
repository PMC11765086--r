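Package: crossphos
Title: Cross-Species Conservation Screening of Phosphosite Antibody Epitopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts which phospho-specific antibodies raised against human,
    mouse or rat phosphoproteins are likely to cross-react with orthologous
    proteins in a second species. Anchors each catalogued epitope (a 15-mer
    flank peptide centred on a phosphorylated S/T/Y) onto a current reference
    proteome, maps genes to orthologs through a confidence-ranked ortholog
    table, globally aligns the source protein against every isoform of each
    ortholog, and scores conservation of the phosphosite neighbourhood: the
    longest contiguous identical run through the site and qualification of
    sliding windows of 6-11 residues allowing at most one non-adjacent
    conservative replacement. Includes a deterministic synthetic-fixture
    generator with planted conservation structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
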