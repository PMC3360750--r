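# Independent brute-force checkers, deliberately written as plain per-window
# loops so they share no code path with the vectorized scanners.

oracleEFCandidates <- function(seq, config = PatternConfig()) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  out <- list()
  if (n >= 12L) {
    for (ls in 1:(n - 11L)) {
      if (config@requireFullMotifWindow) {
        ms <- ls - 9L
        if (ms < 1L || ms + 28L > n) next
      }
      ok <- TRUE
      for (p in names(config@requiredPositions)) {
        if (!(chars[ls + as.integer(p) - 1L] %in%
              config@requiredPositions[[p]])) { ok <- FALSE; break }
      }
      if (!ok) next
      sc <- 0L
      for (p in names(config@scoredChecks)) {
        if (chars[ls + as.integer(p) - 1L] %in% config@scoredChecks[[p]])
          sc <- sc + 1L
      }
      if (sc >= config@minScoredMatches)
        out[[length(out) + 1L]] <- c(loop_start = ls, score = sc)
    }
  }
  if (length(out) == 0L)
    return(data.frame(loop_start = integer(0), score = integer(0)))
  as.data.frame(do.call(rbind, out))
}

oracleIQStarts <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  starts <- integer(0)
  if (n >= 11L) {
    for (s in 1:(n - 10L)) {
      if (chars[s] %in% c("I", "L", "V") && chars[s + 1L] == "Q" &&
          chars[s + 5L] == "R" && chars[s + 10L] %in% c("R", "K"))
        starts <- c(starts, s)
    }
  }
  starts
}

# Random test sequences; half drawn from a donor/Gly-enriched alphabet so
# candidate windows actually occur at a useful rate.
randomTestSeq <- function(len, enriched = FALSE) {
  aa <- strsplit("DENQSTGAVLIMFWYHKRCP", "")[[1]]
  prob <- if (enriched)
    ifelse(aa %in% c("D", "E", "N", "S", "G", "T", "Q"), 3, 1)
  else rep(1, 20)
  paste(sample(aa, len, replace = TRUE, prob = prob / sum(prob)),
        collapse = "")
}

writeTempFasta <- function(headers, seqs) {
  fa <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), fa)
  fa
}
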