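#' Tally EF-hands per protein
#'
#' @param hits data.frame from [scanEFHands()] (any set of proteins).
#' @param nProteinsTotal total number of proteins surveyed (with or without
#'   hits).
#' @return list with `counts` (data.frame `n_ef_hands`, `n_proteins`;
#'   proteins with zero hits are excluded from the table but counted in the
#'   total), `n_proteins_with_hits` and `n_proteins_total`.
#' @examples
#' h <- data.frame(protein_id = c("p1", "p1", "p2"))
#' countHistogram(h, nProteinsTotal = 3)
#' @export
countHistogram <- function(hits, nProteinsTotal) {
  perProt <- table(hits$protein_id)
  tab <- table(factor(as.integer(perProt)))
  counts <- data.frame(n_ef_hands = as.integer(names(tab)),
                       n_proteins = as.integer(tab))
  counts <- counts[order(counts$n_ef_hands), , drop = FALSE]
  rownames(counts) <- NULL
  nWith <- length(perProt)
  if (nWith > nProteinsTotal)
    stop("more proteins with hits than proteins surveyed")
  list(counts = counts,
       n_proteins_with_hits = nWith,
       n_proteins_total = as.integer(nProteinsTotal))
}

#' Pairing annotation for a protein's EF-hand count
#'
#' EF-hands function as pairs; an even count of two or more can pair within
#' the protein, while odd counts suggest pairing across molecules
#' (homo- or heterodimerisation, as in S100 proteins and calpain). A single
#' EF-hand is flagged separately.
#'
#' @param proteinId character vector of protein ids.
#' @param nEfHands integer vector (same length) of EF-hand counts, all >= 1.
#' @return data.frame with columns `protein_id`, `n_ef_hands`, `parity`
#'   (`"even"`/`"odd"`) and `note`.
#' @examples
#' pairingAnnotation(c("a", "b", "c"), c(4, 5, 1))
#' @export
pairingAnnotation <- function(proteinId, nEfHands) {
  n <- as.integer(nEfHands)
  if (length(proteinId) != length(n))
    stop("proteinId and nEfHands must have the same length")
  if (any(is.na(n)) || any(n < 1L))
    stop("validation error: nEfHands must be >= 1")
  parity <- ifelse(n %% 2L == 0L, "even", "odd")
  note <- ifelse(n == 1L, "single EF-hand",
          ifelse(parity == "even", "paired within protein",
                 "putative homo-/heterodimer pairing"))
  data.frame(protein_id = as.character(proteinId), n_ef_hands = n,
             parity = parity, note = note, stringsAsFactors = FALSE)
}

#' Run the full EF-hand survey over a proteome
#'
#' Deterministic composition of the pipeline stages: read FASTA (or take an
#' `AAStringSet` directly), optionally apply the length filter, scan each
#' protein for EF-hands and IQ motifs, classify each detected loop against
#' the consensus profile, and summarise with the per-protein count histogram
#' and pairing annotation. Proteins with zero hits appear only in the
#' totals.
#'
#' @param fasta path to a FASTA file, or an [Biostrings::AAStringSet].
#' @param config a [PatternConfig-class].
#' @param refs reference loops for [buildConsensus()] (data.frame or
#'   character vector), or a ready-made [ConsensusProfile-class]. Defaults
#'   to the packaged calmodulin set.
#' @param lengthFilter apply [filterByLength()] with `minLen`/`maxLen`.
#' @param minLen,maxLen length window (inclusive) when `lengthFilter` is on.
#' @param scanIQ also scan for IQ motifs (on by default).
#' @return A [SurveyReport-class].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">cam-like demo",
#'   paste0(strrep("A", 40), "AAELAAAFKEADKDGDGTITTKEFAAELRHAM", strrep("G", 40))),
#'   fa)
#' runSurvey(fa, lengthFilter = FALSE)
#' @export
runSurvey <- function(fasta, config = PatternConfig(), refs = referenceLoops(),
                      lengthFilter = TRUE, minLen = 100L, maxLen = 2200L,
                      scanIQ = TRUE) {
  if (is(fasta, "AAStringSet")) {
    records <- fasta
    src <- "<in-memory AAStringSet>"
  } else {
    records <- readProteome(fasta)
    src <- normalizePath(fasta)
  }
  if (length(records) == 0L) stop("empty-input error: no proteins to survey")
  if (lengthFilter)
    records <- filterByLength(records, minLen, maxLen)$retained
  if (length(records) == 0L)
    stop("empty-input error: no proteins pass the length filter")

  profile <- if (is(refs, "ConsensusProfile")) refs else buildConsensus(refs)
  hits <- scanEFHands(records, config)
  hits <- affinityOfProtein(hits, profile)
  iq <- if (scanIQ) scanIQMotifs(records) else .emptyIQHits()

  histo <- countHistogram(hits, nProteinsTotal = length(records))
  pairing <- if (nrow(hits)) {
    perProt <- table(hits$protein_id)
    pairingAnnotation(names(perProt), as.integer(perProt))
  } else {
    pairingAnnotation(character(0), integer(0))
  }

  new("SurveyReport",
      hits = hits,
      iqHits = iq,
      histogram = histo$counts,
      pairing = pairing,
      nProteinsWithHits = histo$n_proteins_with_hits,
      nProteinsTotal = histo$n_proteins_total,
      metadata = list(
        input = src,
        n_proteins_surveyed = length(records),
        length_filter = lengthFilter,
        consensus = consensus(profile),
        critical_positions = criticalPositions(profile),
        config_digest = configDigest(config),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      ))
}

#' @describeIn runSurvey per-hit rows (scan + affinity columns) of a report.
#' @param report a [SurveyReport-class].
#' @export
surveyHits <- function(report) {
  stopifnot(is(report, "SurveyReport"))
  report@hits
}

#' @describeIn runSurvey IQ motif hits of a report.
#' @export
surveyIQHits <- function(report) {
  stopifnot(is(report, "SurveyReport"))
  report@iqHits
}

#' @describeIn runSurvey EF-hand count histogram of a report.
#' @export
surveyHistogram <- function(report) {
  stopifnot(is(report, "SurveyReport"))
  report@histogram
}

#' @describeIn runSurvey pairing annotations of a report.
#' @export
surveyPairing <- function(report) {
  stopifnot(is(report, "SurveyReport"))
  report@pairing
}

#' @describeIn runSurvey run metadata of a report.
#' @export
surveyMetadata <- function(report) {
  stopifnot(is(report, "SurveyReport"))
  report@metadata
}

#' Write a survey report to a directory
#'
#' Writes `hits.tsv` (scan columns), `affinity.tsv` (per-loop calls),
#' `iq_hits.tsv`, `histogram.tsv`, `pairing.tsv` and `run.json` (metadata).
#' All coordinates are 1-based inclusive.
#'
#' @param report a [SurveyReport-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeSurvey <- function(report, dir) {
  stopifnot(is(report, "SurveyReport"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeHits(report@hits, file.path(dir, "hits.tsv"))
  writeAffinity(report@hits, file.path(dir, "affinity.tsv"))
  iq <- data.frame(protein_id = report@iqHits$protein_id,
                   start_1based = report@iqHits$start,
                   matched_seq = report@iqHits$matched_seq,
                   stringsAsFactors = FALSE)
  write.table(iq, file.path(dir, "iq_hits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report@histogram, file.path(dir, "histogram.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report@pairing, file.path(dir, "pairing.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- c(report@metadata,
            list(n_proteins_with_hits = report@nProteinsWithHits,
                 n_proteins_total = report@nProteinsTotal,
                 n_hits = nrow(report@hits),
                 n_iq_hits = nrow(report@iqHits)))
  jsonlite::write_json(meta, file.path(dir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Global-alignment percent identity between two protein sequences
#'
#' Aligns the two sequences globally with affine gap penalties (defaults:
#' match 1, mismatch 0, gap opening 10, gap extension 0.5) and reports
#' `100 * identical aligned pairs / alignment length`, with gap columns
#' included in the denominator. Symmetric in its arguments and equal to 100
#' exactly when the sequences are identical.
#'
#' @param a,b sequences as character strings or `AAString`s; optionally
#'   subset first with `rangeA`/`rangeB`.
#' @param match,mismatch substitution scores.
#' @param gapOpening,gapExtension affine gap penalties (positive costs).
#' @param rangeA,rangeB optional `c(first, last)` 1-based residue ranges
#'   extracted before aligning.
#' @return percent identity (numeric scalar in `[0, 100]`).
#' @examples
#' pairwiseIdentity("PEPTIDE", "PEPTIDE")
#' pairwiseIdentity("AC", "AD")
#' @export
pairwiseIdentity <- function(a, b, match = 1, mismatch = 0,
                             gapOpening = 10, gapExtension = 0.5,
                             rangeA = NULL, rangeB = NULL) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b))
    stop("validation error: sequences must be non-empty")
  if (!is.null(rangeA)) a <- substring(a, rangeA[1], rangeA[2])
  if (!is.null(rangeB)) b <- substring(b, rangeB[1], rangeB[2])
  letters <- unique(c(.AA_ALLOWED, "B", "Z", "J", "U", "O", "*",
                      strsplit(paste0(a, b), "")[[1]]))
  sub <- matrix(mismatch, length(letters), length(letters),
                dimnames = list(letters, letters))
  diag(sub) <- match
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = sub, gapOpening = gapOpening,
    gapExtension = gapExtension)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * sum(pa == pb & pa != "-") / length(pa)
}
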