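test_that("EF-hand count histogram tallies proteins and conserves hit mass", {
  h0 <- countHistogram(data.frame(protein_id = character(0)), 5)
  expect_equal(nrow(h0$counts), 0L)
  expect_equal(h0$n_proteins_with_hits, 0L)
  expect_equal(h0$n_proteins_total, 5L)

  hits <- data.frame(protein_id = c(rep("p1", 2), rep("p2", 2), rep("p3", 5)))
  h <- countHistogram(hits, 10)
  expect_equal(h$counts$n_ef_hands, c(2L, 5L))
  expect_equal(h$counts$n_proteins, c(2L, 1L))
  expect_equal(h$n_proteins_with_hits, 3L)
  expect_equal(sum(h$counts$n_ef_hands * h$counts$n_proteins), nrow(hits))
  expect_error(countHistogram(hits, 2), "more proteins")
})

test_that("pairing annotation follows the EF-hand pairing rule", {
  ann <- pairingAnnotation(c("a", "b", "c"), c(4L, 5L, 1L))
  expect_equal(ann$parity, c("even", "odd", "odd"))
  expect_equal(ann$note, c("paired within protein",
                           "putative homo-/heterodimer pairing",
                           "single EF-hand"))
  expect_error(pairingAnnotation("a", 0L), "validation")
})

test_that("the survey composes scan, affinity and summaries over a proteome", {
  # background restricted to residues that can never satisfy the loop
  # position-1 requirement, so the embedded loops are the only possible hits
  # and the derived histogram is exact by construction
  bg <- setNames(rep(1 / 16, 16),
                 setdiff(strsplit("DENQSTGAVLIMFWYHKRCP", "")[[1]],
                         c("D", "E", "N", "S")))
  cfg <- syntheticConfig(nProteins = 3, motifCounts = c(2L, 4L, 0L),
                         mutationLoad = 0L, iqMotifRate = 0,
                         background = bg,
                         lengthRange = c(200L, 300L), seed = 21)
  sim <- generateProteome(cfg)
  fa <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(sim$proteins, fa)

  rep <- runSurvey(fa, lengthFilter = FALSE)
  expect_s4_class(rep, "SurveyReport")
  expect_equal(surveyHistogram(rep),
               data.frame(n_ef_hands = c(2L, 4L), n_proteins = c(1L, 1L)))
  expect_equal(rep@nProteinsWithHits, 2L)
  expect_equal(rep@nProteinsTotal, 3L)
  # all k=0 embeddings classify strong
  expect_true(all(as.character(surveyHits(rep)$tier) == "strong"))
  pair <- surveyPairing(rep)
  expect_equal(sort(pair$parity), c("even", "even"))

  # determinism modulo the timestamp metadata field
  rep2 <- runSurvey(fa, lengthFilter = FALSE)
  expect_identical(surveyHits(rep), surveyHits(rep2))
  expect_identical(surveyHistogram(rep), surveyHistogram(rep2))
  expect_identical(surveyPairing(rep), surveyPairing(rep2))
  m1 <- surveyMetadata(rep); m2 <- surveyMetadata(rep2)
  m1$timestamp <- m2$timestamp <- NULL
  expect_identical(m1, m2)
})

test_that("a single embedded consensus loop yields one strong odd-count row", {
  cons <- consensus(buildConsensus(referenceLoops()))
  s <- paste0(strrep("A", 50), strrep("L", 9), cons, strrep("K", 8),
              strrep("A", 50))
  fa <- writeTempFasta("single", s)
  rep <- runSurvey(fa)
  expect_equal(nrow(surveyHits(rep)), 1L)
  expect_equal(as.character(surveyHits(rep)$tier), "strong")
  pair <- surveyPairing(rep)
  expect_equal(pair$parity, "odd")
  expect_equal(pair$note, "single EF-hand")
})

test_that("surveys reject empty input", {
  fa <- tempfile(fileext = ".fasta")
  file.create(fa)
  expect_error(runSurvey(fa), "empty-input")
  tooShort <- writeTempFasta("p", strrep("A", 50))
  expect_error(runSurvey(tooShort), "length filter")
})

test_that("survey reports write complete 1-based TSV/JSON output", {
  cfg <- syntheticConfig(nProteins = 4, motifCounts = c(1L, 2L, 0L, 1L),
                         mutationLoad = 0:2, iqMotifRate = 1,
                         lengthRange = c(150L, 200L), seed = 8)
  sim <- generateProteome(cfg)
  rep <- runSurvey(sim$proteins, lengthFilter = FALSE)
  dir <- tempfile()
  writeSurvey(rep, dir)
  expect_true(all(file.exists(file.path(dir,
    c("hits.tsv", "affinity.tsv", "iq_hits.tsv", "histogram.tsv",
      "pairing.tsv", "run.json")))))
  hits <- read.delim(file.path(dir, "hits.tsv"))
  expect_equal(names(hits), c("protein_id", "motif_start_1based",
                              "loop_start_1based", "loop_seq", "score",
                              "constraint_flags"))
  expect_equal(hits$loop_start_1based, hits$motif_start_1based + 9L)
  meta <- jsonlite::read_json(file.path(dir, "run.json"))
  expect_equal(meta$n_hits, nrow(surveyHits(rep)))
  expect_equal(meta$config_digest, configDigest(PatternConfig()))
})

test_that("global-alignment percent identity behaves like an identity measure", {
  expect_equal(pairwiseIdentity("PEPTIDE", "PEPTIDE"), 100)
  expect_equal(pairwiseIdentity("AC", "AD"), 50)
  expect_error(pairwiseIdentity("", "AC"), "non-empty")

  set.seed(3)
  for (i in 1:10) {
    a <- randomTestSeq(sample(30:80, 1))
    b <- randomTestSeq(sample(30:80, 1))
    expect_equal(pairwiseIdentity(a, b), pairwiseIdentity(b, a))
    expect_true(pairwiseIdentity(a, b) < 100)
    expect_equal(pairwiseIdentity(a, a), 100)
  }

  # gaps enter the denominator: a deletion caps identity below 100
  expect_equal(pairwiseIdentity("ACDEFGHIKL", "ACDEFHIKL"), 90)
})

test_that("the packaged synthetic calmodulin-like pair reproduces its frozen identity", {
  fa <- system.file("extdata", "synthetic_cam_like_pair.fasta",
                    package = "efhandscan")
  pair <- readProteome(fa)
  expect_equal(length(pair), 2L)
  # frozen regression value for the packaged (synthetic) demo pair
  expect_equal(pairwiseIdentity(pair[[1]], pair[[2]]), 74.48, tolerance = 0.01)
  # range extraction composes with alignment
  expect_equal(pairwiseIdentity(pair[[1]], pair[[1]], rangeA = c(10, 80),
                                rangeB = c(10, 80)), 100)
})
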