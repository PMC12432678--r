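Package: depsero
Title: Serologic Epitope Residue Analysis for HLA Antigen Assignment
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for residue-level analysis of HLA serology. Models the
    amino-acid positions that determine serologic epitopes (DEPs) on HLA
    class I and HLA-DPB1 molecules, assigns alleles to WHO-recognised or
    Associated Antigens from their DEP signatures, and proposes new
    Associated Antigens when a newly validated DEP position splits an
    existing antigen group. Includes single-antigen-bead (SAB) panel
    analytics (positivity scoring at an MFI cutoff, pairwise regression
    between closely related beads, symmetric-outlier screening), flow
    crossmatch scoring, combinatorial search for residue conjunctions that
    separate reactive from non-reactive beads with self-tolerance
    filtering, and a synthetic-panel generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
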