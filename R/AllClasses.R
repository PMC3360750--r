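#' Pattern configuration for the canonical EF-hand grammar
#'
#' Holds the residue constraints evaluated on every candidate 12-residue
#' coordination loop. Two kinds of checks exist: *required* checks, which any
#' reported hit must satisfy (by default loop position 1 must be one of
#' D/E/N/S and position 12 one of D/E, the side-chain carboxylate anchors of
#' calcium coordination), and *scored* checks, of which at least
#' `minScoredMatches` must hold (by default positions 3, 5 and 9 must be
#' oxygen-donor residues -- position 5 and 9 also admit Gly -- and motif
#' residue 15, i.e. loop position 6, must be the conserved Gly). Position 7
#' coordinates calcium through its backbone carbonyl and therefore carries no
#' residue constraint. An unknown residue `X` fails any check it is tested
#' against.
#'
#' @slot oxygenDonors character vector of oxygen-donor residues.
#' @slot requiredPositions named list: loop position (as character) ->
#'   allowed residue set; every reported hit satisfies all of these.
#' @slot scoredChecks named list: loop position -> allowed residue set;
#'   each satisfied check contributes 1 to the hit score.
#' @slot minScoredMatches integer, minimum number of satisfied scored checks.
#' @slot requireFullMotifWindow logical; if `TRUE` a loop is only considered
#'   when the full 29-residue helix-loop-helix window fits in the sequence
#'   (loop position 1 at motif residue 10).
#'
#' @seealso [PatternConfig()] for the user-facing constructor.
#' @export
setClass("PatternConfig",
  representation(
    oxygenDonors = "character",
    requiredPositions = "list",
    scoredChecks = "list",
    minScoredMatches = "integer",
    requireFullMotifWindow = "logical"
  )
)

setValidity("PatternConfig", function(object) {
  msg <- character(0)
  pos <- c(as.integer(names(object@requiredPositions)),
           as.integer(names(object@scoredChecks)))
  if (anyNA(pos) || any(pos < 1L | pos > .LOOP_LEN))
    msg <- c(msg, "all loop positions must be in 1..12")
  if (length(object@minScoredMatches) != 1L || is.na(object@minScoredMatches) ||
      object@minScoredMatches < 0L ||
      object@minScoredMatches > length(object@scoredChecks))
    msg <- c(msg, "minScoredMatches must be in 0..number of scored checks")
  allres <- unlist(c(object@oxygenDonors, object@requiredPositions,
                     object@scoredChecks))
  if (!all(allres %in% .AA_TIE_ORDER))
    msg <- c(msg, "residue sets may only contain the 20 standard residues")
  if (length(object@requireFullMotifWindow) != 1L ||
      is.na(object@requireFullMotifWindow))
    msg <- c(msg, "requireFullMotifWindow must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Consensus profile over aligned calcium-binding loops
#'
#' Column-wise residue frequencies over a gap-free alignment of 12-residue
#' loops, the per-column majority consensus string, and the set of critical
#' coordination positions used for affinity-tier calls.
#'
#' @slot frequencies 12 x 20 numeric matrix; rows are loop positions, columns
#'   the 20 standard residues (in the fixed tie-break order); each row sums
#'   to 1.
#' @slot consensus 12-residue majority consensus string.
#' @slot criticalPositions integer vector of loop positions (default
#'   1,3,5,7,9) compared when scoring identity to the consensus.
#' @slot nLoops number of reference loops the profile was built from.
#'
#' @seealso [buildConsensus()], [criticalIdentity()]
#' @export
setClass("ConsensusProfile",
  representation(
    frequencies = "matrix",
    consensus = "character",
    criticalPositions = "integer",
    nLoops = "integer"
  )
)

setValidity("ConsensusProfile", function(object) {
  msg <- character(0)
  f <- object@frequencies
  if (!is.numeric(f) || nrow(f) != .LOOP_LEN || ncol(f) != length(.AA_TIE_ORDER))
    msg <- c(msg, "frequencies must be a 12 x 20 numeric matrix")
  else {
    if (any(abs(rowSums(f) - 1) > 1e-9))
      msg <- c(msg, "each column of the alignment must have frequencies summing to 1")
    cons <- strsplit(object@consensus, "")[[1]]
    if (length(cons) != .LOOP_LEN)
      msg <- c(msg, "consensus must have length 12")
    else {
      top <- apply(f, 1L, max)
      got <- f[cbind(seq_len(.LOOP_LEN), match(cons, colnames(f)))]
      if (anyNA(got) || any(got < top - 1e-12))
        msg <- c(msg, "consensus residue must have maximal frequency in its column")
    }
  }
  if (any(object@criticalPositions < 1L | object@criticalPositions > .LOOP_LEN))
    msg <- c(msg, "criticalPositions must be in 1..12")
  if (length(msg)) msg else TRUE
})

#' Proteome survey report
#'
#' Result of [runSurvey()]: one row per detected EF-hand with its affinity
#' call, the per-protein EF-hand count histogram, pairing annotations, and
#' run metadata.
#'
#' @slot hits data.frame with scan and affinity columns joined (one row per
#'   reported EF-hand).
#' @slot iqHits data.frame of IQ motif matches.
#' @slot histogram data.frame with columns `n_ef_hands`, `n_proteins`.
#' @slot pairing data.frame of per-protein pairing annotations.
#' @slot nProteinsWithHits,nProteinsTotal integer totals.
#' @slot metadata list: input description, config digest, timestamp.
#'
#' @export
setClass("SurveyReport",
  representation(
    hits = "data.frame",
    iqHits = "data.frame",
    histogram = "data.frame",
    pairing = "data.frame",
    nProteinsWithHits = "integer",
    nProteinsTotal = "integer",
    metadata = "list"
  )
)

setValidity("SurveyReport", function(object) {
  msg <- character(0)
  if (sum(object@histogram$n_proteins) != object@nProteinsWithHits)
    msg <- c(msg, "histogram counts must sum to nProteinsWithHits")
  if (object@nProteinsWithHits > object@nProteinsTotal)
    msg <- c(msg, "nProteinsWithHits cannot exceed nProteinsTotal")
  if (nrow(object@histogram) &&
      sum(object@histogram$n_ef_hands * object@histogram$n_proteins) !=
        nrow(object@hits))
    msg <- c(msg, "histogram mass must equal the number of hit rows")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PatternConfig", function(object) {
  cat("PatternConfig\n")
  cat("  required:",
      paste(sprintf("pos%s in {%s}", names(object@requiredPositions),
                    vapply(object@requiredPositions, paste, "", collapse = ",")),
            collapse = "; "), "\n")
  cat("  scored:  ",
      paste(sprintf("pos%s in {%s}", names(object@scoredChecks),
                    vapply(object@scoredChecks, paste, "", collapse = ",")),
            collapse = "; "), "\n")
  cat("  min scored matches:", object@minScoredMatches,
      "| full 29-aa window required:", object@requireFullMotifWindow, "\n")
})

setMethod("show", "ConsensusProfile", function(object) {
  cat("ConsensusProfile over", object@nLoops, "loops\n")
  cat("  consensus:", object@consensus, "\n")
  cat("  critical positions:", paste(object@criticalPositions, collapse = ","),
      "\n")
})

setMethod("show", "SurveyReport", function(object) {
  cat("SurveyReport:", nrow(object@hits), "EF-hand hits in",
      object@nProteinsWithHits, "of", object@nProteinsTotal, "proteins;",
      nrow(object@iqHits), "IQ motif hits\n")
  if (nrow(object@histogram)) {
    cat("  EF-hands per protein:\n")
    print(object@histogram, row.names = FALSE)
  }
})
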