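#' Create an EF-hand pattern configuration
#'
#' Builds the sequence grammar used by [scanEFHands()]. The defaults encode
#' the canonical EF-hand coordination chemistry: loop positions 1, 3, 5, 9
#' and 12 supply oxygen ligands (position 7 uses its backbone carbonyl and is
#' unconstrained), and the Gly at motif residue 15 (loop position 6) is
#' highly conserved. Positions 1 and 12 are hard requirements; positions
#' 3, 5, 6 and 9 are scored, and a hit needs at least `minScoredMatches` of
#' them. All sets are user-configurable so specificity can be tightened or
#' relaxed.
#'
#' @param oxygenDonors residues whose side chain can donate a coordinating
#'   oxygen. Default `D, E, N, Q, S, T`.
#' @param requiredPositions named list mapping loop positions (names,
#'   `"1"`..`"12"`) to allowed residue sets; all must hold for a hit.
#' @param scoredChecks named list mapping loop positions to allowed residue
#'   sets; each satisfied check adds 1 to the score.
#' @param minScoredMatches minimum score for a window to be reported.
#' @param requireFullMotifWindow require the full 29-residue helix-loop-helix
#'   window to fit inside the sequence.
#'
#' @return A [PatternConfig-class] object.
#' @examples
#' cfg <- PatternConfig()
#' cfg
#' strict <- PatternConfig(minScoredMatches = 4L)
#' @export
PatternConfig <- function(oxygenDonors = c("D", "E", "N", "Q", "S", "T"),
                          requiredPositions = list(
                            `1` = c("D", "E", "N", "S"),
                            `12` = c("D", "E")
                          ),
                          scoredChecks = list(
                            `3` = oxygenDonors,
                            `5` = c(oxygenDonors, "G"),
                            `6` = "G",
                            `9` = c(oxygenDonors, "G")
                          ),
                          minScoredMatches = 3L,
                          requireFullMotifWindow = TRUE) {
  new("PatternConfig",
      oxygenDonors = toupper(oxygenDonors),
      requiredPositions = lapply(requiredPositions, toupper),
      scoredChecks = lapply(scoredChecks, toupper),
      minScoredMatches = as.integer(minScoredMatches),
      requireFullMotifWindow = requireFullMotifWindow)
}

#' Read a pattern configuration from YAML
#'
#' The YAML file mirrors the [PatternConfig()] arguments using snake_case
#' keys: `oxygen_donor_set`, `required_positions`, `scored_checks`,
#' `min_scored_matches`, `require_full_motif_window`. Missing keys fall back
#' to the defaults. Residue sets may be written as YAML lists or as compact
#' strings such as `"DENS"`.
#'
#' @param path path to a YAML file.
#' @return A [PatternConfig-class] object.
#' @export
readPatternConfig <- function(path) {
  y <- yaml::read_yaml(path)
  expand <- function(x) {
    lapply(x, function(v) {
      v <- as.character(v)
      # compact residue strings ("DENS") split into letters; the literal
      # token "oxygen_donor_set" is preserved for later substitution
      unlist(lapply(v, function(tok) {
        if (tok == "oxygen_donor_set" || nchar(tok) <= 1L) tok
        else strsplit(tok, "")[[1]]
      }), use.names = FALSE)
    })
  }
  args <- list()
  if (!is.null(y$oxygen_donor_set)) {
    v <- as.character(y$oxygen_donor_set)
    args$oxygenDonors <- if (length(v) == 1L && nchar(v) > 1L)
      strsplit(v, "")[[1]] else v
  }
  if (!is.null(y$required_positions))
    args$requiredPositions <- expand(y$required_positions)
  if (!is.null(y$scored_checks)) {
    sc <- expand(y$scored_checks)
    donors <- if (!is.null(args$oxygenDonors)) args$oxygenDonors
              else c("D", "E", "N", "Q", "S", "T")
    # the literal token "oxygen_donor_set" in a scored check expands to the set
    sc <- lapply(sc, function(v) {
      if (any(v == "oxygen_donor_set"))
        unique(c(donors, setdiff(v, "oxygen_donor_set")))
      else v
    })
    args$scoredChecks <- sc
  }
  if (!is.null(y$min_scored_matches))
    args$minScoredMatches <- as.integer(y$min_scored_matches)
  if (!is.null(y$require_full_motif_window))
    args$requireFullMotifWindow <- isTRUE(y$require_full_motif_window)
  do.call(PatternConfig, args)
}

#' Stable digest of a pattern configuration
#'
#' MD5 of the canonical serialized constraint table; recorded in survey
#' metadata so runs are auditable.
#'
#' @param config a [PatternConfig-class].
#' @return a character MD5 digest.
#' @export
configDigest <- function(config) {
  stopifnot(is(config, "PatternConfig"))
  canon <- paste(
    paste(sort(config@oxygenDonors), collapse = ""),
    paste(vapply(sort(as.integer(names(config@requiredPositions))),
                 function(p) paste0(p, ":", paste(sort(
                   config@requiredPositions[[as.character(p)]]), collapse = "")),
                 ""), collapse = ";"),
    paste(vapply(sort(as.integer(names(config@scoredChecks))),
                 function(p) paste0(p, ":", paste(sort(
                   config@scoredChecks[[as.character(p)]]), collapse = "")),
                 ""), collapse = ";"),
    config@minScoredMatches,
    config@requireFullMotifWindow,
    sep = "|")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(canon, tf)
  unname(tools::md5sum(tf))
}
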