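# codingpot

Classify prokaryotic nucleotide sequences as **protein coding or
noncoding** from the sequence alone.

Prokaryotic RNA-seq experiments surface many small transcripts that match
no annotated gene. The hardest of them to interpret are short: sORFs
encoding small proteins (≤ 50 amino acids) and small regulatory RNAs look
alike, are often not conserved, and their observed boundaries are imprecise
— transcripts may be truncated or extend past the gene. `codingpot` is for
microbial genomicists triaging such transcripts: it scores each sequence
with a probability of being protein coding, without homology or
conservation information, and stays usable when the transcript boundary is
wrong.

## Method

Eight sequence-intrinsic features are computed per transcript — GC
content, the Fickett TESTCODE statistic, the codon adaptation index
(CAI = geometric mean of relative adaptiveness *w(c) = f(c)/max f* within
synonymous codon families), hexamer usage bias
(max-over-frames mean of *ln F_coding(h)/F_noncoding(h)*), the isoelectric
point of the longest-ORF peptide (Henderson–Hasselbalch, EMBOSS pKa set),
log length, ORF coverage and ORF presence — standardized, and integrated by
a small rectifier network (8 → 32 → 16 → 1, logistic output) trained with
inverse-frequency-weighted cross-entropy, Adam, and early stopping.
Robustness to imprecise boundaries comes from training on *length-varied*
examples: each training sequence is paired with a variant truncated to a
random 50–100% window and/or extended with up to 60 nt of genomic
background per side. Predictions are explained by **exact** Shapley
attributions (full coalition enumeration, efficiency to 1e-9).

A synthetic benchmark generator emulates a multi-genus evaluation: each
simulated genome has its own GC content and Dirichlet-sampled codon-usage
bias; four sequence classes (long coding, sORF, ncRNA, intergenic) are
drawn per genome; whole genomes are held out of training.

## Worked example

Simulate a small four-genome benchmark (one genome held out), train, and
score the held-out sequences:

```r
library(codingpot)

bm   <- generate_benchmark(n_genomes = 4, holdout_genomes = 1,
                           n_per_class = 60, seed = 42)
tr    <- bm$train
exact <- tr[tr$variant == "exact", ]
refs  <- reference_tables(exact$seq[exact$is_coding],
                          exact$seq[!exact$is_coding])
fit   <- train_classifier(setNames(tr$seq, tr$id), tr$is_coding,
                          refs = refs, seed = 42)
fit
#> Coding-potential classifier (feed-forward network)
#>   architecture: 8 -> 32 -> 16 -> 1 (rectifier hidden, logistic output)
#>   features:     gc_content, fickett, cai, hexamer_bias, isoelectric_point, log_length, orf_coverage, orf_presence
#>   threshold:    0.500   seed: 42   best epoch: 205

te    <- bm$test
preds <- predict(fit, setNames(te$seq[1:4], te$id[1:4]))
preds[, c("id", "length", "probability_coding", "call")]
#>                                      id length probability_coding   call
#> g02_long_coding_001 g02_long_coding_001   1053              0.509 coding
#> g02_long_coding_002 g02_long_coding_002   1071              0.845 coding
#> g02_long_coding_003 g02_long_coding_003    159              0.947 coding
#> g02_long_coding_004 g02_long_coding_004    984              0.949 coding

roc_auc(predict(fit, setNames(te$seq, te$id))$probability_coding,
        te$is_coding)
#> ROC curve: AUC = 0.9840 (240 positives, 240 negatives, 480 thresholds)
```

`probability_coding` is the network's coding probability; `call` applies
the stored threshold (0.5). The AUC is the probability that a random coding
sequence outscores a random noncoding one on the held-out genome.

Which features drive the model? Exact Shapley importance over 20 held-out
sequences against a 50-row training background:

```r
set.seed(1)
bg <- feature_matrix(setNames(tr$seq[sample(nrow(tr), 50)], NULL), refs)
X  <- feature_matrix(setNames(te$seq[1:20], te$id[1:20]), refs)
feature_importance(fit, X, bg)
#>             feature importance
#> 1      hexamer_bias      0.192
#> 2      orf_coverage      0.163
#> 3        log_length      0.043
#> 4        gc_content      0.039
#> 5           fickett      0.029
#> 6 isoelectric_point      0.020
#> 7      orf_presence      0.014
#> 8               cai      0.014
```

Every workflow step is also a shell subcommand
(`inst/scripts/codingpot.R`): `simulate`, `train`, `predict`, `features`,
`explain`, `evaluate` — all file formats are FASTA, TSV or JSON.

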