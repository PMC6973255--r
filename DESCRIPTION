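Package: mnrmsi
Title: Microsatellite Instability Classification from smMIP Sequencing of
    Short Mononucleotide Repeats
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-free analysis of single-molecule molecular inversion
    probe (smMIP) sequencing of short (7-12 bp) mononucleotide repeats for
    tumor microsatellite instability (MSI) testing. Read pairs are assigned
    to panel markers by probe-arm matching, molecular barcodes (UMIs) are
    extracted, and per-marker repeat-length histograms and linked-SNP allele
    counts are tabulated from pair-consensus base calls. A naive Bayes
    classifier combines per-marker deletion frequency and allelic-bias
    (Fisher exact) traits into a decadic log-odds MSI-H/MSS score.
    Includes backward-forward stepwise marker selection, UMI-based quality
    control, BRAF c.1799 variant-allele-frequency calling with optional
    barcode consensus error reduction, in-silico read-mixture and
    UMI-resampling detection-limit experiments, and a synthetic paired-FASTQ
    cohort generator that provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
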