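Package: nickmut
Title: UMI-Consensus Amplicon Profiling of Mutagenic Repair at Targeted DNA Nicks and Breaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantifying mutagenic repair outcomes at
    CRISPR-targeted single-strand nicks and double-strand breaks from paired-end
    amplicon deep sequencing with unique molecular identifiers (UMIs). Raw read
    pairs are collapsed into single-strand consensus sequences (SSCS) per UMI
    family, aligned to the amplicon reference with a bespoke semi-global
    affine-gap aligner, and converted into left-normalized per-molecule
    deletion, insertion and SNV calls with dual-strand confirmation. The
    package reports background-subtracted category frequencies, per-position
    fractional base-loss maps and SNV spectra, indel length distributions,
    insertion composition, an asymmetry index for resection signatures,
    dual-site event partitioning and sequencing coverage. A synthetic read
    generator emulates the mutational structure of nick and DSB repair
    (asymmetric deletion zones, predominately 1 bp insertions at the cut,
    configurable transversion fractions, donor-templated edits) with PCR and
    sequencing error layers, so the whole pipeline is exercisable and testable
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
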