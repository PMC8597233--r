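Package: promforest
Title: Random-Forest Recognition of Bacterial Sigma-70 Promoters
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains random-forest classifiers that recognise bacterial
    promoters from the 40 bp of sequence immediately upstream of a
    transcription start site (TSS), using either a positional one-hot
    encoding or tetra-nucleotide frequency features. Builds labelled
    training sets from TSS coordinates (BED) and genome FASTA, scans
    whole genomes on both strands with a sliding 40-nt window to produce
    promoter probability tracks, evaluates predictions with
    overlap-based, cluster-based (within 100 nt) and balanced-set
    schemes (AUPRC, AUROC, MCC), and interprets fitted models through
    impurity- and permutation-based feature importance, including
    per-position nucleotide profiles that recover the Pribnow box. A
    synthetic-genome simulator with planted degenerate TATAAT motifs
    provides ground-truthed data for testing and calibration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ranger,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
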