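#' Read nucleotide sequences from a FASTA file
#'
#' Sequences are normalized on input: lowercase is uppercased and RNA `U` is
#' converted to `T`. Only `A`, `C`, `G`, `T` and `N` are accepted after
#' normalization; IUPAC ambiguity codes other than `N` are rejected so that
#' data problems surface early rather than silently biasing features.
#'
#' @param path Path to a FASTA file (multi-record; wrapped or unwrapped lines).
#' @return Named character vector of sequences; names are record identifiers,
#'   in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    cp_stop("codingpot_input_error", "input file not found: %s", path)
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
    error = function(e) cp_stop("codingpot_format_error",
      "not a readable FASTA file: %s (%s)", path, conditionMessage(e)))
  if (length(set) == 0L) {
    cp_stop("codingpot_format_error", "empty FASTA file: %s", path)
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[[i]])) {
      cp_stop("codingpot_format_error", "record '%s' has an empty sequence", ids[[i]])
    }
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad > 0L) {
      ch <- substr(seqs[[i]], bad, bad)
      if (ch %in% IUPAC_EXTRA) {
        cp_stop("codingpot_format_error",
          "record '%s': IUPAC ambiguity code '%s' at offset %d (only N is accepted)",
          ids[[i]], ch, bad - 1L)
      }
      cp_stop("codingpot_format_error",
        "record '%s': invalid character '%s' at offset %d", ids[[i]], ch, bad - 1L)
    }
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path. Lines are wrapped at 70 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(unname(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Reverse complement
#'
#' `N` maps to `N`; applying twice returns the input.
#'
#' @param seq A sequence string (or vector of them) over `ACGTN`.
#' @return Reverse complement, names preserved.
#' @export
reverse_complement <- function(seq) {
  out <- vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
      collapse = "")
  }, character(1L), USE.NAMES = FALSE)
  names(out) <- names(seq)
  out
}

# in-frame codon vector for one frame (0-based); incomplete trailing codon dropped
frame_codons <- function(seq, frame) {
  L <- nchar(seq)
  starts <- seq.int(frame + 1L, by = 3L, length.out = (L - frame) %/% 3L)
  if (length(starts) == 0L) return(character(0L))
  substring(seq, starts, starts + 2L)
}

#' Find open reading frames on the given strand
#'
#' Scans all three frames for ORFs that begin at a start codon and end at the
#' first in-frame stop codon (the stop is included in the interval).
#' Coordinates are 0-based, half-open.
#'
#' @param seq A sequence string over `ACGTN`.
#' @param min_codons Minimum ORF length in codons, including the stop
#'   (must be >= 2).
#' @param start_codons Permitted start codons; `ATG` only by default, set to
#'   `c("ATG","GTG","TTG")` to allow the common alternative bacterial starts.
#' @return A data.frame with columns `start`, `end` (0-based half-open),
#'   `frame` (0, 1 or 2) and `peptide` (one-letter amino acids, stop not
#'   included), sorted by descending length then ascending start.
#' @export
find_orfs <- function(seq, min_codons = 2L, start_codons = "ATG") {
  stopifnot(min_codons >= 2L)
  res <- list()
  for (f in 0:2) {
    codons <- frame_codons(seq, f)
    if (length(codons) < min_codons) next
    starts <- which(codons %in% start_codons)
    stops <- which(codons %in% STOP_CODONS)
    if (length(starts) == 0L || length(stops) == 0L) next
    # first in-frame stop at or after each start
    idx <- findInterval(starts - 1L, stops) + 1L
    ok <- idx <= length(stops)
    starts <- starts[ok]
    ends <- stops[idx[ok]]
    ncod <- ends - starts + 1L
    keep <- ncod >= min_codons
    starts <- starts[keep]; ends <- ends[keep]
    if (length(starts) == 0L) next
    pep <- vapply(seq_along(starts), function(i) {
      translate_codons(codons[starts[i]:(ends[i] - 1L)])
    }, character(1L))
    res[[length(res) + 1L]] <- data.frame(
      start = f + (starts - 1L) * 3L,
      end = f + ends * 3L,
      frame = f,
      peptide = pep,
      stringsAsFactors = FALSE
    )
  }
  if (length(res) == 0L) {
    return(data.frame(start = integer(0L), end = integer(0L),
      frame = integer(0L), peptide = character(0L), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(-(out$end - out$start), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

translate_codons <- function(codons) {
  aa <- CODON_TABLE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Translate a nucleotide sequence
#'
#' Uses the bacterial genetic code (translation table 11 sense-codon
#' assignments). The trailing partial codon is ignored, stop codons are
#' rendered `*` and codons containing `N` are rendered `X`.
#'
#' @param seq A sequence string over `ACGTN`.
#' @param frame Reading frame offset, 0, 1 or 2.
#' @return Peptide string.
#' @export
translate <- function(seq, frame = 0L) {
  stopifnot(frame %in% 0:2)
  codons <- frame_codons(seq, as.integer(frame))
  if (length(codons) == 0L) return("")
  translate_codons(codons)
}
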