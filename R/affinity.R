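#' Build a consensus profile from reference calcium-binding loops
#'
#' Aligns fixed-length 12-residue loops column-wise (gap-free) and records
#' per-column residue frequencies plus the per-column majority consensus.
#' Frequency ties are broken by a fixed residue ordering
#' (`DENQSTGAVLIMFWYHKRCP`, first wins), which keeps the profile fully
#' deterministic.
#'
#' @param loops character vector of 12-residue loop sequences (at least 2),
#'   or a data.frame with a `loop` column (e.g. from [referenceLoops()]).
#' @param criticalPositions loop positions compared by [criticalIdentity()];
#'   default the five positions (1,3,5,7,9) linked to variation in
#'   calcium-binding constants. Position 12, though a coordinating position,
#'   is not critical by default but may be added.
#' @return A [ConsensusProfile-class].
#' @examples
#' prof <- buildConsensus(c("DKDGDGTITTKE", "DKDGDGYISAAE"))
#' consensus(prof)
#' @export
buildConsensus <- function(loops, criticalPositions = c(1L, 3L, 5L, 7L, 9L)) {
  if (is.data.frame(loops)) loops <- loops$loop
  loops <- toupper(as.character(loops))
  if (length(loops) < 2L)
    stop("validation error: at least 2 reference loops are required")
  bad <- nchar(loops) != .LOOP_LEN
  if (any(bad))
    stop("validation error: reference loop(s) not of length 12: ",
         paste(loops[bad], collapse = ", "))
  if (!all(.checkAlphabet(loops, .AA_TIE_ORDER)))
    stop("validation error: reference loops must use the 20 standard residues")
  mat <- do.call(rbind, strsplit(loops, ""))
  freq <- t(apply(mat, 2L, function(col) {
    tab <- table(factor(col, levels = .AA_TIE_ORDER))
    as.numeric(tab) / length(col)
  }))
  colnames(freq) <- .AA_TIE_ORDER
  rownames(freq) <- paste0("pos", seq_len(.LOOP_LEN))
  consensus <- .AA_TIE_ORDER[apply(freq, 1L, which.max)]
  new("ConsensusProfile",
      frequencies = freq,
      consensus = paste(consensus, collapse = ""),
      criticalPositions = sort(as.integer(criticalPositions)),
      nLoops = length(loops))
}

#' @describeIn buildConsensus majority consensus string of a profile.
#' @param profile a [ConsensusProfile-class].
#' @export
consensus <- function(profile) {
  stopifnot(is(profile, "ConsensusProfile"))
  profile@consensus
}

#' @describeIn buildConsensus 12 x 20 column-frequency matrix of a profile.
#' @export
loopFrequencies <- function(profile) {
  stopifnot(is(profile, "ConsensusProfile"))
  profile@frequencies
}

#' @describeIn buildConsensus critical loop positions of a profile.
#' @export
criticalPositions <- function(profile) {
  stopifnot(is(profile, "ConsensusProfile"))
  profile@criticalPositions
}

#' Packaged reference calmodulin loop set
#'
#' The four Ca2+-binding loops of the canonical vertebrate calmodulin,
#' listed for ten vertebrate species (the vertebrate calmodulin protein is
#' identical across vertebrates, so the loops repeat verbatim; 40 loops in
#' total). Shipped as a plain two-column TSV under `inst/extdata` and
#' user-replaceable: pass any data.frame with `label` and `loop` columns
#' (or a FASTA of 12-mers read via [readProteome()]) to [buildConsensus()].
#'
#' @param path optional path to an alternative reference TSV (columns
#'   `label`, `loop`).
#' @return data.frame with columns `label` and `loop`.
#' @examples
#' refs <- referenceLoops()
#' nrow(refs)
#' consensus(buildConsensus(refs))
#' @export
referenceLoops <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cam_reference_loops.tsv",
                        package = "efhandscan", mustWork = TRUE)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("label", "loop") %in% names(df)))
  df
}

#' Identity of a loop to the consensus at the critical positions
#'
#' Compares a 12-residue loop with the profile's majority consensus at the
#' critical coordination positions only.
#'
#' @param loop a 12-residue string.
#' @param profile a [ConsensusProfile-class].
#' @return list with `identity_fraction` (matches / number of critical
#'   positions) and `matched_positions` (integer vector of matching
#'   positions).
#' @examples
#' prof <- buildConsensus(c("DKDGDGTITTKE", "DKDGDGTITTKE"))
#' criticalIdentity("DKAGDGTITTKE", prof)
#' @export
criticalIdentity <- function(loop, profile) {
  stopifnot(is(profile, "ConsensusProfile"))
  loop <- toupper(loop)
  if (nchar(loop) != .LOOP_LEN)
    stop("validation error: loop must have length 12, got ", nchar(loop))
  lc <- strsplit(loop, "")[[1]]
  cc <- strsplit(profile@consensus, "")[[1]]
  cp <- profile@criticalPositions
  matched <- cp[lc[cp] == cc[cp]]
  list(identity_fraction = length(matched) / length(cp),
       matched_positions = matched)
}

#' Classify a critical-position identity fraction into an affinity tier
#'
#' Maps identity to the consensus at the critical loop positions onto the
#' three qualitative calcium-binding-affinity tiers: `strong` for exact
#' identity (fraction 1), `low` below 0.5, and `medium` for everything in
#' `[0.5, 1)`. The tier carries the associated qualitative binding-constant
#' range: strong `1e4-1e7`, medium `<1e4`, low `<1e2` (in M^-1); these are
#' approximate bounds, never point estimates.
#'
#' The literal published thresholds (100 percent / below 70 / below 50)
#' leave fractions such as 0.8 unassigned, since five critical positions
#' only yield multiples of 0.2; the partition used here (strong = 1 exactly,
#' low = below 0.5, medium otherwise) honours all three thresholds while
#' covering the whole domain. See the package vignette.
#'
#' @param identityFraction numeric vector of fractions in `[0, 1]`.
#' @return data.frame with columns `identity_fraction`, `tier` (factor with
#'   ordered levels low < medium < strong) and `ka_range`.
#' @examples
#' classifyAffinity(c(1, 0.8, 0.6, 0.4, 0.2, 0))
#' @export
classifyAffinity <- function(identityFraction) {
  f <- as.numeric(identityFraction)
  if (anyNA(f) || any(f < 0 | f > 1))
    stop("validation error: identity fraction must lie in [0, 1]")
  tier <- ifelse(f >= 1 - 1e-9, "strong", ifelse(f < 0.5, "low", "medium"))
  data.frame(identity_fraction = f,
             tier = factor(tier, levels = .TIER_LEVELS, ordered = TRUE),
             ka_range = unname(.KA_RANGES[tier]),
             stringsAsFactors = FALSE)
}

#' Affinity calls for the EF-hand hits of a protein (or a whole scan)
#'
#' Classifies each hit's coordination loop independently against the
#' consensus profile, preserving hit order.
#'
#' @param hits data.frame from [scanEFHands()].
#' @param profile a [ConsensusProfile-class].
#' @return `hits` with appended columns `identity_fraction`,
#'   `matched_positions` (comma-joined), `tier`, `ka_range`.
#' @export
affinityOfProtein <- function(hits, profile) {
  stopifnot(is(profile, "ConsensusProfile"))
  if (nrow(hits) == 0L) {
    out <- hits
    out$identity_fraction <- numeric(0)
    out$matched_positions <- character(0)
    out$tier <- factor(character(0), levels = .TIER_LEVELS, ordered = TRUE)
    out$ka_range <- character(0)
    return(out)
  }
  calls <- lapply(hits$loop_seq, criticalIdentity, profile = profile)
  frac <- vapply(calls, `[[`, numeric(1), "identity_fraction")
  cls <- classifyAffinity(frac)
  hits$identity_fraction <- frac
  hits$matched_positions <- vapply(calls, function(x)
    paste(x$matched_positions, collapse = ","), "")
  hits$tier <- cls$tier
  hits$ka_range <- cls$ka_range
  hits
}

#' Write affinity calls as TSV
#'
#' @param calls data.frame from [affinityOfProtein()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeAffinity <- function(calls, path) {
  out <- data.frame(protein_id = calls$protein_id,
                    loop_start_1based = calls$loop_start,
                    loop_seq = calls$loop_seq,
                    identity_fraction = calls$identity_fraction,
                    matched_positions = calls$matched_positions,
                    tier = as.character(calls$tier),
                    ka_range = calls$ka_range,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
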