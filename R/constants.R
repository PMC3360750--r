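#' @importFrom methods new validObject is slot
#' @importFrom stats setNames
#' @importFrom utils write.table read.delim
NULL

# 20 standard residues in the fixed tie-break order used for consensus calls:
# oxygen donors first, then Gly, then hydrophobics, aromatics, basics, C, P.
.AA_TIE_ORDER <- strsplit("DENQSTGAVLIMFWYHKRCP", "")[[1]]

# Alphabet accepted in input sequences (standard residues plus unknown X).
.AA_ALLOWED <- c(.AA_TIE_ORDER, "X")

.LOOP_LEN <- 12L   # residues in the Ca2+ coordination loop
.MOTIF_LEN <- 29L  # full helix-loop-helix unit
.LOOP_OFFSET <- 9L # loop position 1 sits at motif residue 10

# Qualitative binding-constant bounds attached to each affinity tier.
.KA_RANGES <- c(strong = "1e4-1e7", medium = "<1e4", low = "<1e2")

.TIER_LEVELS <- c("low", "medium", "strong")

.checkAlphabet <- function(seqs, allowed = .AA_ALLOWED) {
  vapply(seqs, function(s) {
    all(strsplit(s, "")[[1]] %in% allowed)
  }, logical(1), USE.NAMES = FALSE)
}
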