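#' Read a protein FASTA file into a validated AAStringSet
#'
#' Parses a (multi-record, wrapped or unwrapped) FASTA file, uppercases the
#' sequences, and validates each record against the allowed alphabet (the 20
#' standard one-letter codes plus `X`). Records containing any other
#' character are dropped with a warning -- never silently altered. Names are
#' the first whitespace-delimited token of the header; the remainder of the
#' header is kept as a `description` metadata column.
#'
#' @param path path to a FASTA file.
#' @return An [Biostrings::AAStringSet] named by record id, with a
#'   `description` column in `S4Vectors::mcols()`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo record", "DKDGDGTITTKE"), fa)
#' readProteome(fa)
#' @export
readProteome <- function(path) {
  if (!file.exists(path))
    stop("input error: FASTA file not found: ", path)
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0L)
    stop("empty-input error: no FASTA records in ", path)
  seqs <- toupper(as.character(aa))
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  ok <- .checkAlphabet(seqs) & nzchar(seqs)
  if (any(!ok)) {
    warning("rejected ", sum(!ok), " record(s) with characters outside ",
            "the amino-acid alphabet: ", paste(ids[!ok], collapse = ", "))
    seqs <- seqs[ok]; ids <- ids[ok]; desc <- desc[ok]
  }
  if (length(seqs) == 0L)
    stop("empty-input error: no valid records in ", path)
  if (anyDuplicated(ids))
    stop("input error: duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

#' Length-filter a proteome
#'
#' Splits records into those retained by the survey's length window and
#' those excluded. The window is inclusive: sequences shorter than `minLen`
#' or longer than `maxLen` residues are excluded, so the boundary lengths
#' themselves are retained. Defaults reproduce the survey convention of
#' dropping fragments under 100 aa and giants over 2200 aa.
#'
#' @param records an [Biostrings::AAStringSet].
#' @param minLen,maxLen inclusive length bounds in residues.
#' @return list with elements `retained` and `excluded`, both
#'   `AAStringSet`s preserving input order.
#' @export
filterByLength <- function(records, minLen = 100L, maxLen = 2200L) {
  stopifnot(is(records, "AAStringSet"), minLen <= maxLen)
  len <- Biostrings::width(records)
  keep <- len >= minLen & len <= maxLen
  list(retained = records[keep], excluded = records[!keep])
}
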