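.emptyEFHits <- function() {
  data.frame(protein_id = character(0), motif_start = integer(0),
             loop_start = integer(0), loop_seq = character(0),
             score = integer(0), constraint_flags = character(0),
             stringsAsFactors = FALSE)
}

.emptyIQHits <- function() {
  data.frame(protein_id = character(0), start = integer(0),
             matched_seq = character(0), stringsAsFactors = FALSE)
}

# Evaluate the EF-hand grammar on one sequence. All coordinates 1-based.
.scanEFOne <- function(seq, id, config, allCandidates) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (config@requireFullMotifWindow) {
    if (n < .MOTIF_LEN) return(.emptyEFHits())
    # motif residue 1 may start at 1..n-28; loop position 1 = motif + 9
    loopStarts <- seq.int(1L + .LOOP_OFFSET, n - .MOTIF_LEN + 1L + .LOOP_OFFSET)
  } else {
    if (n < .LOOP_LEN) return(.emptyEFHits())
    loopStarts <- seq_len(n - .LOOP_LEN + 1L)
  }

  reqPos <- as.integer(names(config@requiredPositions))
  scPos <- as.integer(names(config@scoredChecks))
  reqFlags <- vapply(seq_along(reqPos), function(i) {
    chars[loopStarts + reqPos[i] - 1L] %in% config@requiredPositions[[i]]
  }, logical(length(loopStarts)))
  scFlags <- vapply(seq_along(scPos), function(i) {
    chars[loopStarts + scPos[i] - 1L] %in% config@scoredChecks[[i]]
  }, logical(length(loopStarts)))
  reqFlags <- matrix(reqFlags, nrow = length(loopStarts),
                     dimnames = list(NULL, paste0("req", reqPos)))
  scFlags <- matrix(scFlags, nrow = length(loopStarts),
                    dimnames = list(NULL, paste0("sc", scPos)))

  score <- as.integer(rowSums(scFlags))
  pass <- rowSums(reqFlags) == length(reqPos) & score >= config@minScoredMatches
  if (!any(pass)) return(.emptyEFHits())

  keepIdx <- which(pass)
  if (!allCandidates) {
    # greedy left-to-right: drop any loop overlapping an already-accepted one
    accepted <- integer(0)
    lastEnd <- -1L
    for (i in keepIdx) {
      ls <- loopStarts[i]
      if (ls > lastEnd) {
        accepted <- c(accepted, i)
        lastEnd <- ls + .LOOP_LEN - 1L
      }
    }
    keepIdx <- accepted
  }
  ls <- loopStarts[keepIdx]
  flags <- cbind(reqFlags, scFlags)[keepIdx, , drop = FALSE]
  flagStr <- apply(flags, 1L, function(r)
    paste(paste0(colnames(flags), "=", as.integer(r)), collapse = ";"))
  data.frame(
    protein_id = rep(id, length(ls)),
    motif_start = ls - .LOOP_OFFSET,
    loop_start = ls,
    loop_seq = substring(seq, ls, ls + .LOOP_LEN - 1L),
    score = score[keepIdx],
    constraint_flags = flagStr,
    stringsAsFactors = FALSE
  )
}

#' Scan protein sequences for canonical EF-hand motifs
#'
#' Slides a 12-residue window over each sequence and evaluates the
#' coordination-loop grammar of `config` at every placement that (by
#' default) admits a full 29-residue helix-loop-helix unit around it (the
#' loop occupies motif residues 10--21). Windows passing all required checks
#' with at least `minScoredMatches` scored checks are reported. Overlapping
#' candidate loops are resolved greedily left-to-right, so one physical loop
#' is never counted twice; set `allCandidates = TRUE` to see every raw
#' candidate window instead.
#'
#' Helix content is not evaluated: the 29-residue window requirement is
#' purely positional, and detection is sequence-based throughout.
#'
#' @param x an [Biostrings::AAStringSet] (names used as protein ids) or a
#'   named character vector of sequences.
#' @param config a [PatternConfig-class]; defaults to [PatternConfig()].
#' @param allCandidates if `TRUE`, skip overlap resolution.
#' @return data.frame with one row per hit: `protein_id`, `motif_start`,
#'   `loop_start` (1-based, `loop_start = motif_start + 9`), `loop_seq`,
#'   `score`, and `constraint_flags` (semicolon-joined `key=0/1` pairs).
#'   Hits are sorted by protein then `loop_start`.
#' @examples
#' s <- paste0("AAELAAAFKEA", "DKDGDGTITTKE", "FAAELRHAM")
#' scanEFHands(c(demo = s))
#' @export
setGeneric("scanEFHands", function(x, config = PatternConfig(),
                                   allCandidates = FALSE)
  standardGeneric("scanEFHands"))

#' @rdname scanEFHands
#' @export
setMethod("scanEFHands", "AAStringSet",
  function(x, config = PatternConfig(), allCandidates = FALSE) {
    validObject(config)
    ids <- names(x)
    if (is.null(ids)) ids <- as.character(seq_along(x))
    res <- lapply(seq_along(x), function(i)
      .scanEFOne(as.character(x[[i]]), ids[i], config, allCandidates))
    do.call(rbind, c(list(.emptyEFHits()), res))
  })

#' @rdname scanEFHands
#' @export
setMethod("scanEFHands", "character",
  function(x, config = PatternConfig(), allCandidates = FALSE) {
    ids <- names(x)
    if (is.null(ids)) ids <- as.character(seq_along(x))
    aa <- Biostrings::AAStringSet(toupper(x))
    names(aa) <- ids
    scanEFHands(aa, config, allCandidates)
  })

#' Scan protein sequences for IQ motifs
#'
#' Reports every 11-residue window matching the calmodulin-binding IQ
#' consensus `(I/L/V) Q x x x R x x x x (R/K)`. Overlapping matches are all
#' reported; the scan is equivalent to an exhaustive per-window check. An
#' `X` at one of the four constrained positions fails the match.
#'
#' @param x an [Biostrings::AAStringSet] or named character vector.
#' @return data.frame with columns `protein_id`, `start` (1-based position
#'   of consensus position 1) and `matched_seq` (the 11-mer).
#' @examples
#' scanIQMotifs(c(iq1 = "AILLQTNIRALWKREYYRAA"))
#' @export
setGeneric("scanIQMotifs", function(x) standardGeneric("scanIQMotifs"))

.IQ_REGEX <- "(?=[ILV]Q...R....[RK])"

#' @rdname scanIQMotifs
#' @export
setMethod("scanIQMotifs", "AAStringSet", function(x) {
  ids <- names(x)
  if (is.null(ids)) ids <- as.character(seq_along(x))
  res <- lapply(seq_along(x), function(i) {
    s <- as.character(x[[i]])
    m <- gregexpr(.IQ_REGEX, s, perl = TRUE)[[1]]
    starts <- as.integer(m[m > 0L])
    if (length(starts) == 0L) return(.emptyIQHits())
    data.frame(protein_id = rep(ids[i], length(starts)), start = starts,
               matched_seq = substring(s, starts, starts + 10L),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(list(.emptyIQHits()), res))
})

#' @rdname scanIQMotifs
#' @export
setMethod("scanIQMotifs", "character", function(x) {
  ids <- names(x)
  if (is.null(ids)) ids <- as.character(seq_along(x))
  aa <- Biostrings::AAStringSet(toupper(x))
  names(aa) <- ids
  scanIQMotifs(aa)
})

#' Write EF-hand hits as TSV
#'
#' One row per hit with 1-based coordinate columns `motif_start_1based` and
#' `loop_start_1based`, matching the report convention used throughout.
#'
#' @param hits data.frame from [scanEFHands()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeHits <- function(hits, path) {
  out <- data.frame(protein_id = hits$protein_id,
                    motif_start_1based = hits$motif_start,
                    loop_start_1based = hits$loop_start,
                    loop_seq = hits$loop_seq,
                    score = hits$score,
                    constraint_flags = hits$constraint_flags,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
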