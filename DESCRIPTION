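Package: codingpot
Title: Coding-Potential Classification of Prokaryotic Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies prokaryotic nucleotide sequences as protein coding or
    noncoding from sequence-intrinsic features alone. Computes a panel of
    classic coding-potential features (GC content, Fickett TESTCODE statistic,
    codon adaptation index, hexamer usage bias, peptide isoelectric point and
    open-reading-frame structure), feeds them to a small feed-forward neural
    network trained with length-varied examples so that predictions are robust
    to imprecise transcript boundaries, and explains each prediction with
    exact Shapley feature attributions. Includes a synthetic multi-genome
    benchmark generator with per-genome codon bias, four sequence classes and
    genome-level holdout, plus ROC/AUC, per-class accuracy and
    boundary-sensitivity evaluation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
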