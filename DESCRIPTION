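Package: nanolibkit
Title: Germline-Conditional Nanobody Library Construction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building synthetic nanobody (VHH) libraries from
    germline-consistent sequence repertoires. Curates repertoires by global
    alignment against germline V-gene references, transfers IMGT numbering by
    anchor alignment and delimits framework and CDR regions, trains a small
    decoder-only autoregressive amino-acid language model with low-rank (LoRA)
    adapters for germline-conditional sequence generation, scans sequences for
    post-translational-modification liability motifs, computes length-stratified
    positional amino-acid frequency matrices, and synthesizes framework-grafted
    libraries. Includes a synthetic-repertoire simulator so the full pipeline is
    exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    digest,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
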