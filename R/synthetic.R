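#' Configuration for the synthetic proteome generator
#'
#' Bundles and validates the generator parameters. Defaults describe the
#' benchmark proteome used throughout the package: 500 proteins of 120--600
#' residues with uniform background composition, 300 embedded canonical
#' EF-hand units (the repeating per-protein count template
#' `1,2,0,0,1,2,0,0,0,0`), affinity mutations drawn uniformly from
#' k in 0..4 at loop positions 3/5/7/9, and an IQ motif in 10 percent of
#' proteins.
#'
#' @param nProteins number of proteins to generate.
#' @param lengthRange integer `c(min, max)` protein length in residues.
#' @param motifCounts integer vector, EF-hand units per protein; recycled to
#'   `nProteins`.
#' @param mutationLoad integer vector of candidate mutation counts k; each
#'   embedded motif draws its k uniformly from this vector. Pass e.g.
#'   `rep(0, 1)` for pristine consensus loops.
#' @param affinityPositions loop positions eligible for affinity mutations
#'   (default 3, 5, 7, 9: these change the identity fraction while leaving
#'   the required positions 1 and 12 intact).
#' @param detectabilityMutationRate fraction of embedded motifs additionally
#'   mutated at required position 1 or 12, rendering them invisible to the
#'   scanner by construction (recorded as such in the truth table).
#'   Default 0.
#' @param iqMotifRate fraction of proteins receiving one IQ motif.
#' @param background `"uniform"` over the 20 standard residues (default) or
#'   a named numeric vector of residue frequencies.
#' @param consensusLoop the 12-mer embedded (before mutation) as each
#'   EF-hand's coordination loop; defaults to the consensus of the packaged
#'   calmodulin reference set.
#' @param patternConfig the [PatternConfig-class] whose residue sets define
#'   what counts as a guaranteed check-breaking mutation and whether a
#'   mutated loop remains detectable.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return a validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(nProteins = 500L,
                            lengthRange = c(120L, 600L),
                            motifCounts = c(1L, 2L, 0L, 0L, 1L, 2L, 0L, 0L, 0L, 0L),
                            mutationLoad = 0:4,
                            affinityPositions = c(3L, 5L, 7L, 9L),
                            detectabilityMutationRate = 0,
                            iqMotifRate = 0.1,
                            background = "uniform",
                            consensusLoop = NULL,
                            patternConfig = PatternConfig(),
                            seed = 1L) {
  nProteins <- as.integer(nProteins)
  stopifnot(nProteins >= 1L, length(lengthRange) == 2L,
            lengthRange[1] <= lengthRange[2],
            all(mutationLoad >= 0L),
            all(affinityPositions %in% 1:12),
            detectabilityMutationRate >= 0, detectabilityMutationRate <= 1,
            iqMotifRate >= 0, iqMotifRate <= 1)
  if (is.null(consensusLoop))
    consensusLoop <- consensus(buildConsensus(referenceLoops()))
  stopifnot(nchar(consensusLoop) == .LOOP_LEN)
  counts <- rep_len(as.integer(motifCounts), nProteins)
  if (any(mutationLoad > length(affinityPositions)))
    stop("configuration error: mutation load exceeds the number of ",
         "affinity positions")
  # each EF unit occupies guard(2) + motif(29); a 1-residue gap separates units
  need <- counts * (.MOTIF_LEN + 3L) + 12L
  if (any(need > lengthRange[1]))
    stop("configuration error: minimum length ", lengthRange[1],
         " cannot hold ", max(counts), " motif(s)")
  structure(list(nProteins = nProteins,
                 lengthRange = as.integer(lengthRange),
                 motifCounts = counts,
                 mutationLoad = as.integer(mutationLoad),
                 affinityPositions = sort(as.integer(affinityPositions)),
                 detectabilityMutationRate = detectabilityMutationRate,
                 iqMotifRate = iqMotifRate,
                 background = background,
                 consensusLoop = toupper(consensusLoop),
                 patternConfig = patternConfig,
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

.sampleBackground <- function(n, background) {
  if (identical(background, "uniform"))
    sample(.AA_TIE_ORDER, n, replace = TRUE)
  else
    sample(names(background), n, replace = TRUE,
           prob = as.numeric(background))
}

# Residue set allowed by `config` at a loop position (required or scored);
# NULL when the position is unconstrained.
.allowedAt <- function(config, pos) {
  p <- as.character(pos)
  c(config@requiredPositions[[p]], config@scoredChecks[[p]])
}

#' Generate a synthetic proteome with ground truth
#'
#' Builds random-background proteins with canonical EF-hand helix-loop-helix
#' units and IQ motifs embedded at known, non-overlapping positions. Each
#' embedded coordination loop is the reference consensus mutated at exactly
#' k sampled affinity positions; every mutation substitutes a residue
#' outside both the position's allowed set and its consensus residue, so it
#' is guaranteed to break that position's check and its consensus identity.
#' The truth table records each placement, its mutation count, the intended
#' affinity tier, and whether the loop remains detectable under the pattern
#' config (required positions intact and enough scored checks surviving).
#'
#' To keep embedded motifs uniquely recoverable under the scanner's greedy
#' left-to-right overlap resolution, helix E and a two-residue guard before
#' each unit are drawn from residues outside the position-1 required set, so
#' no spurious candidate loop can overlap an embedded loop from the left.
#'
#' @param config a `SyntheticConfig` from [syntheticConfig()].
#' @return list with `proteins` (an [Biostrings::AAStringSet]) and `truth`
#'   (list of data.frames `ef` and `iq`; 1-based coordinates).
#' @examples
#' sim <- generateProteome(syntheticConfig(nProteins = 5, seed = 7))
#' sim$truth$ef[, c("protein_id", "loop_start", "k_mutations", "intended_tier")]
#' @export
generateProteome <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  hadSeed <- exists(".Random.seed", envir = globalenv())
  if (hadSeed) oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit(if (hadSeed) assign(".Random.seed", oldSeed, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(config$seed)

  pc <- config$patternConfig
  cons <- strsplit(config$consensusLoop, "")[[1]]
  guardAlphabet <- setdiff(.AA_TIE_ORDER, pc@requiredPositions[["1"]])
  critical <- c(1L, 3L, 5L, 7L, 9L)
  ids <- sprintf("syn%04d", seq_len(config$nProteins))

  seqs <- character(config$nProteins)
  efRows <- vector("list", config$nProteins)
  iqRows <- vector("list", config$nProteins)

  for (i in seq_len(config$nProteins)) {
    L <- sample(config$lengthRange[1]:config$lengthRange[2], 1L)
    chars <- .sampleBackground(L, config$background)
    m <- config$motifCounts[i]
    wantIQ <- stats::runif(1L) < config$iqMotifRate

    # sample non-overlapping intervals: EF units occupy [start-2, start+28]
    occupied <- matrix(numeric(0), ncol = 2)
    placeInterval <- function(width, minStart, maxStart) {
      for (try in 1:500) {
        s <- sample(minStart:maxStart, 1L)
        iv <- c(s, s + width - 1L)
        if (nrow(occupied) == 0L ||
            all(iv[2] < occupied[, 1] - 1L | iv[1] > occupied[, 2] + 1L)) {
          occupied <<- rbind(occupied, iv)
          return(s)
        }
      }
      stop("configuration error: could not place motifs without overlap ",
           "(protein length ", L, ", ", m, " EF unit(s))")
    }

    if (m > 0L) {
      efList <- vector("list", m)
      for (j in seq_len(m)) {
        g <- placeInterval(.MOTIF_LEN + 2L, 1L, L - .MOTIF_LEN - 1L)
        motifStart <- g + 2L
        loopStart <- motifStart + .LOOP_OFFSET

        k <- if (length(config$mutationLoad) == 1L) config$mutationLoad
             else sample(config$mutationLoad, 1L)
        mutPos <- if (k > 0L) sort(sample(config$affinityPositions, k))
                  else integer(0)
        invisibleMut <- stats::runif(1L) < config$detectabilityMutationRate
        if (invisibleMut)
          mutPos <- sort(unique(c(mutPos, sample(c(1L, 12L), 1L))))

        loop <- cons
        for (p in mutPos) {
          forbidden <- unique(c(.allowedAt(pc, p), cons[p]))
          loop[p] <- sample(setdiff(.AA_TIE_ORDER, forbidden), 1L)
        }

        # detectability from the constructed loop and the config, by rule
        reqOk <- all(vapply(names(pc@requiredPositions), function(p)
          loop[as.integer(p)] %in% pc@requiredPositions[[p]], logical(1)))
        scScore <- sum(vapply(names(pc@scoredChecks), function(p)
          loop[as.integer(p)] %in% pc@scoredChecks[[p]], logical(1)))
        detectable <- reqOk && scScore >= pc@minScoredMatches

        kCritical <- sum(mutPos %in% critical)
        tier <- as.character(
          classifyAffinity((5 - kCritical) / 5)$tier)

        # write guard + helix E + loop + helix F into the sequence
        chars[(motifStart - 2L):(motifStart - 1L)] <-
          sample(guardAlphabet, 2L, replace = TRUE)
        chars[motifStart:(motifStart + .LOOP_OFFSET - 1L)] <-
          sample(guardAlphabet, .LOOP_OFFSET, replace = TRUE)
        chars[loopStart:(loopStart + .LOOP_LEN - 1L)] <- loop
        helixF <- (loopStart + .LOOP_LEN):(motifStart + .MOTIF_LEN - 1L)
        chars[helixF] <- .sampleBackground(length(helixF), config$background)

        efList[[j]] <- data.frame(
          protein_id = ids[i], motif_start = motifStart,
          loop_start = loopStart, loop_seq = paste(loop, collapse = ""),
          k_mutations = length(mutPos),
          mutated_positions = paste(mutPos, collapse = ","),
          intended_tier = tier, detectable = detectable,
          stringsAsFactors = FALSE)
      }
      efRows[[i]] <- do.call(rbind, efList)
    }

    if (wantIQ) {
      s <- placeInterval(11L, 1L, L - 10L)
      iqChars <- .sampleBackground(11L, config$background)
      iqChars[1L] <- sample(c("I", "L", "V"), 1L)
      iqChars[2L] <- "Q"
      iqChars[6L] <- "R"
      iqChars[11L] <- sample(c("R", "K"), 1L)
      chars[s:(s + 10L)] <- iqChars
      iqRows[[i]] <- data.frame(protein_id = ids[i], start = s,
                                matched_seq = paste(iqChars, collapse = ""),
                                stringsAsFactors = FALSE)
    }
    seqs[i] <- paste(chars, collapse = "")
  }

  proteins <- Biostrings::AAStringSet(seqs)
  names(proteins) <- ids
  emptyEF <- data.frame(protein_id = character(0), motif_start = integer(0),
                        loop_start = integer(0), loop_seq = character(0),
                        k_mutations = integer(0),
                        mutated_positions = character(0),
                        intended_tier = character(0), detectable = logical(0),
                        stringsAsFactors = FALSE)
  ef <- do.call(rbind, c(list(emptyEF), Filter(Negate(is.null), efRows)))
  iq <- do.call(rbind, c(list(data.frame(protein_id = character(0),
                                         start = integer(0),
                                         matched_seq = character(0),
                                         stringsAsFactors = FALSE)),
                         Filter(Negate(is.null), iqRows)))
  list(proteins = proteins, truth = list(ef = ef, iq = iq))
}

#' Write / read a ground-truth table
#'
#' One TSV holding both motif kinds, with 1-based coordinates matching the
#' report conventions: EF rows carry `motif_start_1based`,
#' `loop_start_1based`, the (possibly mutated) loop in `seq`, the mutation
#' bookkeeping and intended tier; IQ rows carry `start_1based` and the
#' 11-mer in `seq`. `readTruth()` restores the in-memory list form, and
#' write-read-write round-trips byte-identically.
#'
#' @param truth list with `ef` and `iq` data.frames, as produced by
#'   [generateProteome()].
#' @param path output TSV path.
#' @return `path` invisibly (`writeTruth`); the truth list (`readTruth`).
#' @export
writeTruth <- function(truth, path) {
  ef <- truth$ef; iq <- truth$iq
  rows <- rbind(
    if (nrow(ef)) data.frame(kind = "EF", protein_id = ef$protein_id,
      start_1based = ef$motif_start, loop_start_1based = ef$loop_start,
      seq = ef$loop_seq, k_mutations = ef$k_mutations,
      mutated_positions = ef$mutated_positions,
      intended_tier = ef$intended_tier, detectable = ef$detectable,
      stringsAsFactors = FALSE),
    if (nrow(iq)) data.frame(kind = "IQ", protein_id = iq$protein_id,
      start_1based = iq$start, loop_start_1based = NA_integer_,
      seq = iq$matched_seq, k_mutations = NA_integer_,
      mutated_positions = NA_character_, intended_tier = NA_character_,
      detectable = NA, stringsAsFactors = FALSE))
  if (is.null(rows))
    rows <- data.frame(kind = character(0), protein_id = character(0),
                       start_1based = integer(0),
                       loop_start_1based = integer(0), seq = character(0),
                       k_mutations = integer(0),
                       mutated_positions = character(0),
                       intended_tier = character(0), detectable = logical(0))
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(mutated_positions = "character"))
  ef <- df[df$kind == "EF", , drop = FALSE]
  iq <- df[df$kind == "IQ", , drop = FALSE]
  list(
    ef = data.frame(protein_id = ef$protein_id,
                    motif_start = as.integer(ef$start_1based),
                    loop_start = as.integer(ef$loop_start_1based),
                    loop_seq = ef$seq,
                    k_mutations = as.integer(ef$k_mutations),
                    mutated_positions = ef$mutated_positions,
                    intended_tier = ef$intended_tier,
                    detectable = as.logical(ef$detectable),
                    stringsAsFactors = FALSE),
    iq = data.frame(protein_id = iq$protein_id,
                    start = as.integer(iq$start_1based),
                    matched_seq = iq$seq, stringsAsFactors = FALSE))
}

#' Score scanner and classifier recovery against ground truth
#'
#' Runs [scanEFHands()] plus [affinityOfProtein()] on a synthetic proteome
#' and compares with its truth table. A truth motif is *recovered* when a
#' reported hit shares its protein and loop start. Sensitivity and tier
#' recovery are computed over the detectable embedded motifs only;
#' scanner-invisible constructions (broken required position or too few
#' surviving scored checks) are excluded by design.
#'
#' @param proteins an [Biostrings::AAStringSet] from [generateProteome()].
#' @param truth the matching truth list.
#' @param config a [PatternConfig-class].
#' @param profile a [ConsensusProfile-class] (defaults to the packaged
#'   reference consensus).
#' @return list: `sensitivity` and `tier_recovery` (fractions in `[0, 1]`
#'   over detectable motifs), `iq_sensitivity`, `n_detectable`,
#'   `n_embedded`.
#' @export
recoveryStats <- function(proteins, truth, config = PatternConfig(),
                          profile = buildConsensus(referenceLoops())) {
  hits <- affinityOfProtein(scanEFHands(proteins, config), profile)
  det <- truth$ef[truth$ef$detectable, , drop = FALSE]
  key <- function(df, startCol) paste(df$protein_id, df[[startCol]])
  hitKey <- key(hits, "loop_start")
  found <- key(det, "loop_start") %in% hitKey
  tierOK <- logical(nrow(det))
  if (nrow(det)) {
    idx <- match(key(det, "loop_start"), hitKey)
    tierOK <- !is.na(idx) & as.character(hits$tier[idx]) == det$intended_tier
  }
  iqHits <- scanIQMotifs(proteins)
  iqFound <- paste(truth$iq$protein_id, truth$iq$start) %in%
    paste(iqHits$protein_id, iqHits$start)
  list(sensitivity = if (nrow(det)) mean(found) else NA_real_,
       tier_recovery = if (nrow(det)) mean(tierOK) else NA_real_,
       iq_sensitivity = if (nrow(truth$iq)) mean(iqFound) else NA_real_,
       n_detectable = nrow(det),
       n_embedded = nrow(truth$ef))
}

#' Empirical false-positive rate on motif-free background
#'
#' Scans a proteome known to contain no embedded EF-hands and reports the
#' accepted-hit density per 10,000 residues.
#'
#' @param proteins an [Biostrings::AAStringSet] (e.g. generated with all
#'   motif counts zero).
#' @param config a [PatternConfig-class].
#' @return list: `hits_per_10k_residues`, `n_hits`, `n_residues`.
#' @export
falsePositiveRate <- function(proteins, config = PatternConfig()) {
  hits <- scanEFHands(proteins, config)
  nres <- sum(Biostrings::width(proteins))
  list(hits_per_10k_residues = 1e4 * nrow(hits) / nres,
       n_hits = nrow(hits), n_residues = nres)
}
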