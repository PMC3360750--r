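test_that("FASTA records are parsed, uppercased and alphabet-validated", {
  fa <- writeTempFasta("p1", "DKDGDGTITTKE")
  rec <- readProteome(fa)
  expect_equal(names(rec), "p1")
  expect_equal(as.character(rec[[1]]), "DKDGDGTITTKE")

  fa2 <- writeTempFasta("p1 some description", "acdef")
  rec2 <- readProteome(fa2)
  expect_equal(as.character(rec2[[1]]), "ACDEF")
  expect_equal(S4Vectors::mcols(rec2)$description, "some description")

  fa3 <- writeTempFasta(c("bad", "good"), c("DKD1GD", "ACDEF"))
  expect_warning(rec3 <- readProteome(fa3), "rejected")
  expect_equal(names(rec3), "good")

  fa4 <- writeTempFasta("onlybad", "DKD1GD")
  expect_warning(expect_error(readProteome(fa4), "empty-input"))
  expect_error(readProteome(tempfile()), "not found")
  expect_error(
    readProteome(writeTempFasta(c("dup", "dup"), c("ACDEF", "ACDEF"))),
    "duplicate")
})

test_that("a canonical calmodulin loop embedded in a 29-residue context is found exactly once", {
  s <- paste0("AAELAAAFKEA", "DKDGDGTITTKE", "FAAELRHAM")
  hits <- scanEFHands(c(p1 = s))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$loop_seq, "DKDGDGTITTKE")
  expect_equal(hits$loop_start, 12L)
  expect_equal(hits$motif_start, 3L)
  expect_equal(hits$loop_start, hits$motif_start + 9L)
  expect_equal(hits$score, 4L)
  expect_match(hits$constraint_flags,
               "req1=1;req12=1;sc3=1;sc5=1;sc6=1;sc9=1", fixed = TRUE)
})

test_that("sequences without admissible or matching windows yield no hits", {
  expect_equal(nrow(scanEFHands(c(p = strrep("A", 40)))), 0L)
  # shorter than the 29-residue motif unit: no admissible window
  expect_equal(nrow(scanEFHands(c(p = "DKDGDGTITTKE"))), 0L)
  # ...unless the full-window requirement is lifted
  cfg <- PatternConfig(requireFullMotifWindow = FALSE)
  expect_equal(nrow(scanEFHands(c(p = "DKDGDGTITTKE"), cfg)), 1L)
})

test_that("an X at a checked position fails that check", {
  s <- paste0("AAELAAAFKEA", "XKDGDGTITTKE", "FAAELRHAM")
  expect_equal(nrow(scanEFHands(c(p = s))), 0L)
  s2 <- paste0("AAELAAAFKEA", "DKXGXGTIXTKE", "FAAELRHAM")
  # scored checks at 3, 5 and 9 all fail on X; only the Gly at 6 survives
  expect_equal(nrow(scanEFHands(c(p = s2))), 0L)
})

test_that("IQ motif scanning matches the consensus and the printed IQ1 peptide", {
  iq1 <- scanIQMotifs(c(iq1 = "AILLQTNIRALWKREYYRAA"))
  expect_equal(nrow(iq1), 1L)
  expect_equal(iq1$start, 4L)
  expect_equal(iq1$matched_seq, "LQTNIRALWKR")

  expect_equal(scanIQMotifs(c(p = "IQAAARAAAAK"))$start, 1L)
  expect_equal(nrow(scanIQMotifs(c(p = "AQAAARAAAAK"))), 0L)
  # overlapping matches are all reported
  two <- scanIQMotifs(c(p = "IQLQARARAARAK"))
  expect_equal(two$start, c(1L, 3L))
})

test_that("length filter retains the inclusive 100..2200 window in input order", {
  lens <- c(99L, 100L, 150L, 2200L, 2201L)
  recs <- Biostrings::AAStringSet(vapply(lens, strrep, "", x = "A"))
  names(recs) <- paste0("p", lens)
  out <- filterByLength(recs)
  expect_equal(unname(Biostrings::width(out$retained)), c(100L, 150L, 2200L))
  expect_equal(unname(Biostrings::width(out$excluded)), c(99L, 2201L))
  expect_equal(names(out$retained), c("p100", "p150", "p2200"))

  empty <- Biostrings::AAStringSet(character(0))
  out0 <- filterByLength(empty)
  expect_equal(length(out0$retained), 0L)
  expect_equal(length(out0$excluded), 0L)

  short <- Biostrings::AAStringSet(rep(strrep("A", 50), 3))
  expect_equal(length(filterByLength(short)$retained), 0L)
})

test_that("scanner candidates agree with the brute-force oracle on random sequences", {
  set.seed(42)
  cfg <- PatternConfig()
  mismatches <- 0L
  for (i in 1:200) {
    s <- randomTestSeq(sample(20:400, 1), enriched = i %% 2 == 0)
    got <- scanEFHands(c(x = s), cfg, allCandidates = TRUE)
    want <- oracleEFCandidates(s, cfg)
    if (!identical(got$loop_start, want$loop_start) ||
        !identical(got$score, want$score)) mismatches <- mismatches + 1L
    if (!identical(scanIQMotifs(c(x = s))$start, oracleIQStarts(s)))
      mismatches <- mismatches + 1L
  }
  expect_identical(mismatches, 0L)
})

test_that("reported hits satisfy the hit invariants, are deterministic and non-overlapping", {
  set.seed(7)
  cfg <- PatternConfig()
  seqs <- vapply(1:40, function(i) randomTestSeq(300, enriched = TRUE), "")
  names(seqs) <- paste0("p", 1:40)
  h1 <- scanEFHands(seqs, cfg)
  h2 <- scanEFHands(seqs, cfg)
  expect_identical(h1, h2)
  expect_gt(nrow(h1), 0L)
  for (i in seq_len(nrow(h1))) {
    s <- seqs[[h1$protein_id[i]]]
    expect_equal(h1$loop_start[i], h1$motif_start[i] + 9L)
    expect_equal(substring(s, h1$loop_start[i], h1$loop_start[i] + 11L),
                 h1$loop_seq[i])
    expect_gte(h1$score[i], cfg@minScoredMatches)
    # required checks hold on every reported hit
    chars <- strsplit(h1$loop_seq[i], "")[[1]]
    expect_true(chars[1] %in% c("D", "E", "N", "S"))
    expect_true(chars[12] %in% c("D", "E"))
  }
  # greedy resolution leaves no overlapping loops within a protein
  for (p in unique(h1$protein_id)) {
    ls <- sort(h1$loop_start[h1$protein_id == p])
    if (length(ls) > 1L) expect_true(all(diff(ls) >= 12L))
  }
})

test_that("raising the scored-match threshold never adds candidate windows", {
  set.seed(11)
  for (i in 1:25) {
    s <- randomTestSeq(250, enriched = TRUE)
    prev <- NULL
    for (m in 0:4) {
      cfg <- PatternConfig(minScoredMatches = m)
      got <- scanEFHands(c(x = s), cfg, allCandidates = TRUE)$loop_start
      if (!is.null(prev)) expect_true(all(got %in% prev))
      prev <- got
    }
  }
})

test_that("pattern configs round-trip through YAML and validate their fields", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "oxygen_donor_set: DENQST",
    "required_positions:",
    "  '1': DENS",
    "  '12': DE",
    "scored_checks:",
    "  '3': [oxygen_donor_set]",
    "  '5': [oxygen_donor_set, G]",
    "  '6': G",
    "  '9': [oxygen_donor_set, G]",
    "min_scored_matches: 3",
    "require_full_motif_window: yes"), yml)
  cfg <- readPatternConfig(yml)
  expect_equal(configDigest(cfg), configDigest(PatternConfig()))

  expect_error(PatternConfig(requiredPositions = list(`13` = "D")), "1..12")
  expect_error(PatternConfig(minScoredMatches = 9L), "minScoredMatches")
})
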