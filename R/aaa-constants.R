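# Shared constants and the condition helper; this file must load first.

#' @importFrom Biostrings readBStringSet writeXStringSet DNAStringSet GENETIC_CODE
NULL

# classed conditions so the CLI can map error families to exit codes
cp_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "codingpot_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = NULL)
  ))
}

IUPAC_EXTRA <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

STOP_CODONS <- c("TAA", "TAG", "TGA")

# sense-codon assignments of the bacterial code (identical to the standard
# code for sense codons); stops rendered '*', codons containing N rendered 'X'
CODON_TABLE <- local({
  tab <- Biostrings::GENETIC_CODE
  names(tab) <- chartr("U", "T", names(tab))
  tab
})

SENSE_CODONS <- names(CODON_TABLE)[CODON_TABLE != "*"]

# synonymous families of the standard/bacterial code, stop codons excluded
SYNONYMOUS_FAMILY <- split(SENSE_CODONS, CODON_TABLE[SENSE_CODONS])

ALL_HEXAMERS <- local({
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)[, 6:1]
  apply(g, 1L, paste, collapse = "")
})
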