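# Synthetic multi-genome benchmark: per-genome codon bias and GC, four
# sequence classes (long_coding, sorf, ncrna, intergenic), genome-level
# holdout and truncation/extension length variants.

# Bacterial-proteome-like amino-acid composition, slightly acid-skewed
# (D+E > K+R) so coding peptides tend toward low isoelectric points.
DEFAULT_AA_COMPOSITION <- local({
  x <- c(A = 0.095, R = 0.055, N = 0.040, D = 0.054, C = 0.012, E = 0.061,
    Q = 0.044, G = 0.074, H = 0.022, I = 0.060, L = 0.105, K = 0.044,
    M = 0.028, F = 0.039, P = 0.044, S = 0.058, T = 0.054, W = 0.014,
    Y = 0.029, V = 0.070)
  x / sum(x)
})

KLASSES <- c("long_coding", "sorf", "ncrna", "intergenic")
CODING_KLASSES <- c("long_coding", "sorf")

# class length models (peptide lengths in aa for coding classes, nt otherwise)
CLASS_LENGTHS <- list(
  sorf = c(10L, 50L), long_coding = c(51L, 400L),
  ncrna = c(50L, 500L), intergenic = c(200L, 2000L)
)

#' Generative parameters for one simulated genome
#'
#' @param genome_id Identifier string.
#' @param gc Target GC content, in (0.25, 0.75).
#' @param codon_bias_concentration Symmetric Dirichlet concentration per
#'   synonymous codon family; smaller values give stronger codon bias.
#' @param amino_acid_composition Named 20-vector of amino-acid frequencies
#'   (normalized internally).
#' @param class_counts Named integer vector: sequences per class.
#' @param seed Integer seed for everything this genome generates.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(genome_id, gc = 0.5, codon_bias_concentration = 0.5,
                        amino_acid_composition = DEFAULT_AA_COMPOSITION,
                        class_counts = c(long_coding = 10L, sorf = 10L,
                          ncrna = 10L, intergenic = 10L),
                        seed = 1L) {
  stopifnot(gc > 0.25, gc < 0.75, codon_bias_concentration > 0,
    all(class_counts >= 0L), all(KLASSES %in% names(class_counts)))
  aa <- amino_acid_composition / sum(amino_acid_composition)
  structure(list(genome_id = genome_id, gc = gc,
    codon_bias_concentration = codon_bias_concentration,
    amino_acid_composition = aa,
    class_counts = class_counts[KLASSES], seed = as.integer(seed)),
    class = "genome_spec")
}

codon_gc_factor <- function(codon, gc) {
  chars <- strsplit(codon, "", fixed = TRUE)[[1L]]
  prod(ifelse(chars %in% c("G", "C"), gc / 2, (1 - gc) / 2))
}

#' Sample a genome's codon-usage table from its generative spec
#'
#' Per synonymous family, frequencies are drawn from a symmetric Dirichlet
#' with the spec's concentration and tilted toward the spec's GC content by
#' reweighting each codon by its GC-dependent base probability. Deterministic
#' given the spec's seed.
#'
#' @param spec A `genome_spec`.
#' @return List mapping each amino acid to its codon-frequency vector
#'   (sums to 1 within each family), with attribute `codon_table` giving a
#'   `codon_table` object for the same frequencies.
#' @export
sample_codon_table <- function(spec) {
  set.seed(spec$seed)
  fams <- lapply(SYNONYMOUS_FAMILY, function(fam) {
    g <- stats::rgamma(length(fam), shape = spec$codon_bias_concentration)
    # rgamma can return all-zero draws for tiny concentrations
    if (sum(g) == 0) g <- rep(1, length(fam))
    tilt <- vapply(fam, codon_gc_factor, numeric(1L), gc = spec$gc)
    f <- g * tilt
    stats::setNames(f / sum(f), fam)
  })
  fams
}

sample_peptide <- function(n_aa, spec) {
  sample(names(spec$amino_acid_composition), n_aa, replace = TRUE,
    prob = spec$amino_acid_composition)
}

codons_for_peptide <- function(aa, fams) {
  vapply(aa, function(a) {
    f <- fams[[a]]
    sample(names(f), 1L, prob = f)
  }, character(1L), USE.NAMES = FALSE)
}

#' Generate one coding sequence for a simulated genome
#'
#' A peptide length is drawn from the class's length model, amino acids from
#' the genome's composition and codons per amino acid from the genome's
#' codon table; the sequence is `ATG` + codons + a stop codon, so its length
#' is `3 * n_aa + 6` nt. Uses the current RNG state.
#'
#' @param spec A `genome_spec`.
#' @param klass `"sorf"` or `"long_coding"`.
#' @param fams Codon-frequency table from [sample_codon_table()].
#' @return List with `seq`, `klass`, `is_coding = TRUE`, `n_aa`.
#' @export
generate_coding <- function(spec, klass, fams) {
  stopifnot(klass %in% CODING_KLASSES)
  rng <- CLASS_LENGTHS[[klass]]
  n_aa <- sample(rng[[1L]]:rng[[2L]], 1L)
  aa <- sample_peptide(n_aa, spec)
  codons <- codons_for_peptide(aa, fams)
  stop_codon <- sample(STOP_CODONS, 1L)
  list(seq = paste0("ATG", paste(codons, collapse = ""), stop_codon),
    klass = klass, is_coding = TRUE, n_aa = n_aa)
}

# uniform integers on [lo, hi], safe for degenerate ranges (unlike sample())
runif_int <- function(n, lo, hi) {
  lo + floor(stats::runif(n) * (hi - lo + 1L))
}

random_background <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
    prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)), collapse = "")
}

#' Generate one noncoding sequence for a simulated genome
#'
#' I.i.d. nucleotides at the genome's GC content with a class-specific
#' length model. Chance ORFs are kept by default (realistic contamination);
#' `purge_orfs` regenerates any record whose longest ORF exceeds that many
#' codons.
#'
#' @param spec A `genome_spec`.
#' @param klass `"ncrna"` or `"intergenic"`.
#' @param purge_orfs Optional integer; `NULL` keeps all records.
#' @return List with `seq`, `klass`, `is_coding = FALSE`.
#' @export
generate_noncoding <- function(spec, klass, purge_orfs = NULL) {
  stopifnot(klass %in% c("ncrna", "intergenic"))
  rng <- CLASS_LENGTHS[[klass]]
  repeat {
    n <- sample(rng[[1L]]:rng[[2L]], 1L)
    s <- random_background(n, spec$gc)
    if (is.null(purge_orfs)) break
    orfs <- find_orfs(s, min_codons = 2L)
    if (nrow(orfs) == 0L ||
        max(orfs$end - orfs$start) / 3L <= purge_orfs) break
  }
  list(seq = s, klass = klass, is_coding = FALSE)
}

#' Policy for truncating/extending sequences
#'
#' @param keep_fraction Length-2 numeric range; the kept contiguous window is
#'   `round(f * L)` nt for `f` drawn uniformly from this range.
#' @param extension Length-2 integer range; each side is extended by an
#'   independent uniform draw of background nucleotides.
#' @return List of class `varied_length_policy`.
#' @export
varied_length_policy <- function(keep_fraction = c(0.5, 1.0),
                                 extension = c(0L, 60L)) {
  stopifnot(length(keep_fraction) == 2L, keep_fraction[[1L]] <= keep_fraction[[2L]],
    keep_fraction[[1L]] > 0, keep_fraction[[2L]] <= 1,
    length(extension) == 2L, extension[[1L]] >= 0L)
  list(keep_fraction = keep_fraction, extension = as.integer(extension))
}

#' Truncate and/or extend a sequence, emulating imprecise boundaries
#'
#' Keeps a contiguous window of `round(f * L)` nucleotides at a uniformly
#' chosen offset, then prepends/appends independently drawn background
#' nucleotides at the given GC content. The class label of a varied sequence
#' is unchanged. Uses the current RNG state.
#'
#' @param seq Sequence string (>= 10 nt).
#' @param policy A `varied_length_policy`.
#' @param gc Background GC content for the extensions.
#' @return The varied sequence string.
#' @export
vary_length <- function(seq, policy = varied_length_policy(), gc = 0.5) {
  L <- nchar(seq)
  stopifnot(L >= 10L)
  f <- stats::runif(1L, policy$keep_fraction[[1L]], policy$keep_fraction[[2L]])
  keep <- max(1L, round(f * L))
  offset <- runif_int(1L, 0L, L - keep)
  core <- substr(seq, offset + 1L, offset + keep)
  e <- runif_int(2L, policy$extension[[1L]], policy$extension[[2L]])
  left <- if (e[[1L]] > 0L) random_background(e[[1L]], gc) else ""
  right <- if (e[[2L]] > 0L) random_background(e[[2L]], gc) else ""
  paste0(left, core, right)
}

generate_genome_sequences <- function(spec) {
  fams <- sample_codon_table(spec)  # also seeds the stream for this genome
  rows <- list()
  for (klass in KLASSES) {
    n <- spec$class_counts[[klass]]
    if (n == 0L) next
    for (i in seq_len(n)) {
      rec <- if (klass %in% CODING_KLASSES) {
        generate_coding(spec, klass, fams)
      } else {
        generate_noncoding(spec, klass)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s_%s_%03d", spec$genome_id, klass, i),
        genome_id = spec$genome_id, klass = klass,
        is_coding = rec$is_coding, variant = "exact", seq = rec$seq,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

add_varied_variants <- function(df, gc, policy) {
  varied <- df
  varied$id <- paste0(df$id, "_v")
  varied$variant <- "varied"
  varied$seq <- vapply(df$seq, vary_length, character(1L),
    policy = policy, gc = gc, USE.NAMES = FALSE)
  rbind(df, varied)
}

split_counts <- function(total, n_genomes) {
  base <- total %/% n_genomes
  extra <- total %% n_genomes
  base + (seq_len(n_genomes) <= extra)
}

#' Generate a labeled multi-genome benchmark with genome-level holdout
#'
#' Samples `n_genomes` genome specs (GC uniform on `gc_range`, Dirichlet
#' concentration uniform on `concentration_range`, distinct sub-seeds),
#' generates the four sequence classes for each, and emits both exact and
#' length-varied variants. All sequences of `holdout_genomes` randomly chosen
#' genomes go only to the test corpus, so train and test share no generative
#' parameters — a stand-in for holding out whole genera. Fully reproducible
#' from `seed`.
#'
#' @param n_genomes Number of simulated genomes.
#' @param holdout_genomes Number of genomes reserved for testing.
#' @param n_per_class Total sequences per class across each corpus side
#'   (split as evenly as possible across that side's genomes).
#' @param gc_range,concentration_range Uniform sampling ranges for the
#'   per-genome generative parameters.
#' @param policy Varied-length policy applied to every sequence.
#' @param seed Integer seed.
#' @return List with data.frames `train` and `test`, columns `id`,
#'   `genome_id`, `klass`, `is_coding`, `variant` (`exact` or `varied`) and
#'   `seq`.
#' @export
generate_benchmark <- function(n_genomes = 12L, holdout_genomes = 2L,
                               n_per_class = 500L,
                               gc_range = c(0.3, 0.7),
                               concentration_range = c(0.2, 0.8),
                               policy = varied_length_policy(),
                               seed = 1L) {
  stopifnot(holdout_genomes >= 1L, n_genomes > holdout_genomes)
  set.seed(as.integer(seed))
  gcs <- stats::runif(n_genomes, gc_range[[1L]], gc_range[[2L]])
  concs <- stats::runif(n_genomes, concentration_range[[1L]],
    concentration_range[[2L]])
  sub_seeds <- sample.int(2^31 - 1L, n_genomes)
  holdout <- sample.int(n_genomes, holdout_genomes)
  n_train_genomes <- n_genomes - holdout_genomes
  train_counts <- split_counts(n_per_class, n_train_genomes)
  test_counts <- split_counts(n_per_class, holdout_genomes)
  ti <- 0L; hi <- 0L
  corpora <- list(train = list(), test = list())
  for (g in seq_len(n_genomes)) {
    is_test <- g %in% holdout
    if (is_test) { hi <- hi + 1L; n_cls <- test_counts[[hi]] }
    else { ti <- ti + 1L; n_cls <- train_counts[[ti]] }
    spec <- genome_spec(sprintf("g%02d", g), gc = gcs[[g]],
      codon_bias_concentration = concs[[g]],
      class_counts = stats::setNames(rep(n_cls, 4L), KLASSES),
      seed = sub_seeds[[g]])
    df <- generate_genome_sequences(spec)
    df <- add_varied_variants(df, gc = spec$gc, policy = policy)
    side <- if (is_test) "test" else "train"
    corpora[[side]][[length(corpora[[side]]) + 1L]] <- df
  }
  list(train = do.call(rbind, corpora$train),
    test = do.call(rbind, corpora$test))
}
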