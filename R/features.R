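# --- Fickett TESTCODE statistic -------------------------------------------
# Probability lookup tables and weights from Fickett (1982), Nucleic Acids
# Res. 10:5303-5318. The statistic is defined by these constants.

FICKETT_POSITION_PARA <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
FICKETT_CONTENT_PARA <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0)

FICKETT_POSITION_PROB <- rbind(
  A = c(0.51, 0.55, 0.57, 0.52, 0.48, 0.58, 0.57, 0.54, 0.50, 0.36),
  C = c(0.29, 0.44, 0.55, 0.49, 0.52, 0.60, 0.60, 0.56, 0.51, 0.38),
  G = c(0.62, 0.67, 0.74, 0.65, 0.61, 0.62, 0.66, 0.60, 0.46, 0.35),
  T = c(0.51, 0.60, 0.69, 0.64, 0.53, 0.54, 0.44, 0.51, 0.40, 0.28)
)
FICKETT_CONTENT_PROB <- rbind(
  A = c(0.40, 0.55, 0.58, 0.58, 0.52, 0.48, 0.45, 0.45, 0.38, 0.19),
  C = c(0.50, 0.63, 0.59, 0.50, 0.41, 0.31, 0.24, 0.30, 0.33, 0.23),
  G = c(0.21, 0.40, 0.47, 0.46, 0.52, 0.58, 0.57, 0.52, 0.44, 0.22),
  T = c(0.30, 0.49, 0.56, 0.53, 0.48, 0.48, 0.34, 0.20, 0.32, 0.32)
)
FICKETT_POSITION_WEIGHT <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
FICKETT_CONTENT_WEIGHT <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)

# no-signal baseline used when a sequence is too short to score
FICKETT_NEUTRAL <- sum(apply(FICKETT_POSITION_PROB, 1L, min) * FICKETT_POSITION_WEIGHT) +
  sum(apply(FICKETT_CONTENT_PROB, 1L, min) * FICKETT_CONTENT_WEIGHT)

fickett_lookup <- function(value, para, prob) {
  prob[which(value >= para)[1L]]
}

#' Fickett TESTCODE statistic
#'
#' Combines, for each base, a codon-position asymmetry parameter
#' (`max(n1,n2,n3)/(min(n1,n2,n3)+1)` over the three codon positions) and a
#' content parameter (the base's frequency), each converted to a probability
#' through the published lookup tables and combined with the published
#' weights. Higher values indicate coding-like periodicity. `N` positions are
#' excluded from the counts.
#'
#' @param seq A sequence string over `ACGTN`.
#' @return The TESTCODE score; for sequences shorter than 6 nt, a fixed
#'   no-signal baseline computed from the lookup minima.
#' @export
fickett_score <- function(seq) {
  if (nchar(seq) < 6L) return(FICKETT_NEUTRAL)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- (seq_along(chars) - 1L) %% 3L
  keep <- chars != "N"
  chars <- chars[keep]; pos <- pos[keep]
  if (length(chars) == 0L) return(FICKETT_NEUTRAL)
  score <- 0
  total <- length(chars)
  for (b in c("A", "C", "G", "T")) {
    n <- vapply(0:2, function(p) sum(chars == b & pos == p), numeric(1L))
    posval <- max(n) / (min(n) + 1)
    content <- sum(n) / total
    score <- score +
      fickett_lookup(posval, FICKETT_POSITION_PARA, FICKETT_POSITION_PROB[b, ]) *
        FICKETT_POSITION_WEIGHT[[b]] +
      fickett_lookup(content, FICKETT_CONTENT_PARA, FICKETT_CONTENT_PROB[b, ]) *
        FICKETT_CONTENT_WEIGHT[[b]]
  }
  score
}

# --- Codon adaptation index ------------------------------------------------

#' Build a codon-usage reference table
#'
#' Counts in-frame codons over a corpus of coding sequences (each read in
#' frame 0 as a CDS), smooths with a pseudocount, and computes relative
#' adaptiveness `w(c) = freq(c) / max freq within c's synonymous family`.
#' Stop codons are excluded; single-codon families (ATG, TGG) get `w = 1`.
#'
#' @param coding Character vector of coding sequences (CDS, frame 0).
#' @param pseudocount Laplace smoothing constant added to every codon count.
#' @return An object of class `codon_table` with elements `counts` (named
#'   64-vector) and `w` (relative adaptiveness over the 61 sense codons).
#' @export
build_codon_table <- function(coding, pseudocount = 1) {
  if (length(coding) == 0L) {
    cp_stop("codingpot_config_error", "codon table needs a non-empty coding corpus")
  }
  counts <- structure(numeric(length(CODON_TABLE)), names = names(CODON_TABLE))
  for (s in coding) {
    codons <- frame_codons(s, 0L)
    codons <- codons[codons %in% names(counts)]
    if (length(codons)) {
      tab <- table(codons)
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
  }
  smoothed <- counts + pseudocount
  w <- structure(numeric(length(SENSE_CODONS)), names = SENSE_CODONS)
  for (fam in SYNONYMOUS_FAMILY) {
    w[fam] <- smoothed[fam] / max(smoothed[fam])
  }
  structure(list(counts = counts, w = w, pseudocount = pseudocount),
    class = "codon_table")
}

# geometric mean of w over a codon vector; stops and N codons skipped
cai_codons <- function(codons, table) {
  w <- table$w[codons]
  w <- w[!is.na(w)]
  if (length(w) == 0L) return(NA_real_)
  exp(mean(log(w)))
}

cai_neutral <- function(table) exp(mean(log(table$w)))

#' Codon adaptation index
#'
#' Geometric mean of relative adaptiveness over in-frame sense codons,
#' evaluated on the longest ORF (when one of at least `min_codons` codons
#' exists) and on the full sequence in each of the three frames; the maximum
#' of these readings is returned, so the index neither depends on knowing
#' the reading frame nor collapses when a boundary truncation leaves only a
#' spurious short ORF. Stop codons and codons containing `N` are skipped.
#'
#' @param seq A sequence string over `ACGTN`.
#' @param table A `codon_table` from [build_codon_table()].
#' @param min_codons Minimum ORF size (codons, stop included) for the
#'   longest-ORF path.
#' @param orfs Optional precomputed [find_orfs()] result for `seq`.
#' @return CAI in `(0, 1]`; if no complete codon is available, the table's
#'   neutral value (geometric mean of `w` over the whole table).
#' @export
cai <- function(seq, table, min_codons = 7L, orfs = NULL) {
  if (is.null(orfs)) orfs <- find_orfs(seq, min_codons = min_codons)
  cand <- vapply(0:2, function(f) cai_codons(frame_codons(seq, f), table),
    numeric(1L))
  if (nrow(orfs) > 0L) {
    o <- orfs[1L, ]
    codons <- frame_codons(substr(seq, o$start + 1L, o$end), 0L)
    cand <- c(cand, cai_codons(codons, table))
  }
  if (all(is.na(cand))) return(cai_neutral(table))
  max(cand, na.rm = TRUE)
}

# --- Hexamer usage bias ----------------------------------------------------

hexamer_counts <- function(seqs, step) {
  counts <- structure(numeric(4096L), names = ALL_HEXAMERS)
  for (s in seqs) {
    L <- nchar(s)
    if (L < 6L) next
    starts <- seq.int(1L, L - 5L, by = step)
    hx <- substring(s, starts, starts + 5L)
    hx <- hx[hx %in% ALL_HEXAMERS]  # drops N-containing hexamers
    if (length(hx)) {
      tab <- table(hx)
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
  }
  counts
}

#' Build a hexamer log-odds model
#'
#' In-frame (step 3, frame 0) hexamer frequencies of the coding corpus versus
#' all-position (step 1) hexamer frequencies of the noncoding corpus, both
#' Laplace-smoothed and normalized; the model stores
#' `log_odds(h) = ln(F_coding(h) / F_noncoding(h))` for all 4096 hexamers.
#'
#' @param coding,noncoding Character vectors of training sequences.
#' @param pseudocount Smoothing constant (> 0, guarantees finite log-odds).
#' @return An object of class `hexamer_model` with element `log_odds`
#'   (named 4096-vector).
#' @export
build_hexamer_model <- function(coding, noncoding, pseudocount = 1) {
  if (length(coding) == 0L || length(noncoding) == 0L) {
    cp_stop("codingpot_config_error", "hexamer model needs non-empty coding and noncoding corpora")
  }
  fc <- hexamer_counts(coding, step = 3L) + pseudocount
  fn <- hexamer_counts(noncoding, step = 1L) + pseudocount
  log_odds <- log(fc / sum(fc)) - log(fn / sum(fn))
  structure(list(log_odds = log_odds, pseudocount = pseudocount),
    class = "hexamer_model")
}

#' Hexamer usage bias score
#'
#' For each frame, the mean log-odds over in-frame hexamers (positions
#' `f, f+3, f+6, ...`); the score is the maximum over the three frames,
#' so it does not depend on knowing the reading frame. Hexamers containing
#' `N` are skipped.
#'
#' @param seq A sequence string over `ACGTN`.
#' @param model A `hexamer_model` from [build_hexamer_model()].
#' @return Max-over-frames mean log-odds; 0 when no valid hexamer exists.
#' @export
hexamer_score <- function(seq, model) {
  L <- nchar(seq)
  if (L < 6L) return(0)
  best <- -Inf
  for (f in 0:2) {
    if (f + 6L > L) next
    starts <- seq.int(f + 1L, L - 5L, by = 3L)
    hx <- substring(seq, starts, starts + 5L)
    lo <- model$log_odds[hx]
    lo <- lo[!is.na(lo)]
    if (length(lo)) best <- max(best, mean(lo))
  }
  if (is.finite(best)) best else 0
}

# --- Isoelectric point -----------------------------------------------------

# EMBOSS pKa convention
PKA_SET <- list(
  pka = c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
    H = 6.5, K = 10.8, R = 12.5, Y = 10.1),
  sign = c(Nterm = +1, Cterm = -1, C = -1, D = -1, E = -1,
    H = +1, K = +1, R = +1, Y = -1)
)

peptide_net_charge <- function(pH, counts, pka = PKA_SET) {
  q <- 0
  for (g in names(pka$pka)) {
    n <- counts[[g]]
    if (is.null(n) || n == 0) next
    if (pka$sign[[g]] > 0) {
      q <- q + n / (1 + 10^(pH - pka$pka[[g]]))
    } else {
      q <- q - n / (1 + 10^(pka$pka[[g]] - pH))
    }
  }
  q
}

ionizable_counts <- function(peptide) {
  chars <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  list(Nterm = 1, Cterm = 1,
    C = sum(chars == "C"), D = sum(chars == "D"), E = sum(chars == "E"),
    H = sum(chars == "H"), K = sum(chars == "K"), R = sum(chars == "R"),
    Y = sum(chars == "Y"))
}

#' Isoelectric point of a peptide
#'
#' The pH at which the Henderson-Hasselbalch net charge of the peptide's
#' ionizable groups (free termini and the side chains of C, D, E, H, K, R, Y,
#' EMBOSS pKa values) is zero, found by bisection on pH 0-14.
#'
#' @param peptide One-letter amino-acid string; `*` and `X` are removed
#'   before counting.
#' @param pka pKa convention, a list with `pka` and `sign` vectors.
#' @return The isoelectric point; 7.0 when the effective peptide is empty.
#' @export
isoelectric_point <- function(peptide, pka = PKA_SET) {
  peptide <- gsub("[*X]", "", peptide)
  if (!nzchar(peptide)) return(7.0)
  counts <- ionizable_counts(peptide)
  lo <- 0; hi <- 14
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (peptide_net_charge(mid, counts, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' GC content
#'
#' @param seq A sequence string over `ACGTN`; `N` is excluded from both
#'   numerator and denominator.
#' @return Fraction of G+C among unambiguous bases, in `[0, 1]`;
#'   0.5 for an all-`N` sequence.
#' @export
gc_content <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- sum(chars != "N")
  if (n == 0L) return(0.5)
  sum(chars == "G" | chars == "C") / n
}

# --- Feature vector --------------------------------------------------------

FEATURE_NAMES <- c("gc_content", "fickett", "cai", "hexamer_bias",
  "isoelectric_point", "log_length", "orf_coverage", "orf_presence")

#' Bundle the reference tables the feature panel requires
#'
#' @param coding,noncoding Training corpora (character vectors of sequences);
#'   the coding side is read in frame 0 as CDS for the codon table and the
#'   in-frame side of the hexamer model.
#' @param pseudocount Laplace smoothing for both tables.
#' @param min_codons Minimum ORF size (codons, stop included) used when
#'   extracting the longest ORF for the CAI and isoelectric-point features.
#' @return An object of class `reference_tables`.
#' @export
reference_tables <- function(coding, noncoding, pseudocount = 1, min_codons = 7L) {
  structure(list(
    codon_table = build_codon_table(coding, pseudocount),
    hexamer_model = build_hexamer_model(coding, noncoding, pseudocount),
    pka = PKA_SET,
    fickett_version = "fickett-1982",
    min_codons = as.integer(min_codons)
  ), class = "reference_tables")
}

#' Extract the coding-potential feature panel for one sequence
#'
#' Features, in canonical order: `gc_content`, `fickett`, `cai`,
#' `hexamer_bias`, `isoelectric_point` (of the longest-ORF peptide; 7.0 if no
#' ORF of at least `refs$min_codons` codons), `log_length` (natural log of
#' nucleotide length), `orf_coverage` (longest ORF length / sequence length)
#' and `orf_presence` (0/1).
#'
#' @param seq A sequence string over `ACGTN`.
#' @param refs A `reference_tables` bundle.
#' @return Named numeric vector in canonical feature order; all finite.
#' @export
extract_features <- function(seq, refs) {
  orfs <- find_orfs(seq, min_codons = refs$min_codons)
  has_orf <- nrow(orfs) > 0L
  if (has_orf) {
    pep <- orfs$peptide[[1L]]
    coverage <- (orfs$end[[1L]] - orfs$start[[1L]]) / nchar(seq)
    pi_val <- isoelectric_point(pep, refs$pka)
  } else {
    coverage <- 0
    pi_val <- 7.0
  }
  c(gc_content = gc_content(seq),
    fickett = fickett_score(seq),
    cai = cai(seq, refs$codon_table, min_codons = refs$min_codons, orfs = orfs),
    hexamer_bias = hexamer_score(seq, refs$hexamer_model),
    isoelectric_point = pi_val,
    log_length = log(nchar(seq)),
    orf_coverage = coverage,
    orf_presence = as.numeric(has_orf))
}

#' Feature matrix for a set of sequences
#'
#' @param seqs Named character vector of sequences.
#' @param refs A `reference_tables` bundle.
#' @return Numeric matrix, one row per sequence (rownames = ids), columns in
#'   canonical feature order.
#' @export
feature_matrix <- function(seqs, refs) {
  m <- t(vapply(seqs, extract_features, numeric(length(FEATURE_NAMES)),
    refs = refs))
  colnames(m) <- FEATURE_NAMES
  m
}
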