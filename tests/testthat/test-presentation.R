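test_that("cleavage probability follows the logistic window model", {
  m0 <- zeroMatrix("cleavage", 12L)
  expect_equal(cleavageProbability("KVAELVHFL", m0), 0.5)
  mBig <- zeroMatrix("cleavage", 12L, intercept = 40)
  expect_gt(cleavageProbability("KVAELVHFL", mBig), 1 - 1e-12)
  mNeg <- zeroMatrix("cleavage", 12L, intercept = -40)
  expect_lt(cleavageProbability("KVAELVHFL", mNeg), 1e-12)

  # seeded matrix: equals an independent sum-then-logistic evaluation
  set.seed(91)
  m <- randomMatrix("cleavage", 12L, intercept = 0.3)
  pep <- "KVAELVHFL"; fb <- "MNP"; fa <- "QRSTVW"
  w <- slot(m, "weights")
  ctx <- strsplit(paste0(fb, pep, fa), "")[[1]]
  bond <- nchar(fb) + nchar(pep)
  s <- 0.3
  for (j in 1:12) {
    pos <- bond - 6 + j
    if (pos >= 1 && pos <= length(ctx)) s <- s + w[j, ctx[pos]]
  }
  expect_equal(cleavageProbability(pep, m, fb, fa),
               unname(plogis(s)), tolerance = 1e-12)

  # short flanks are padded neutrally: only in-range positions score
  s2 <- 0.3
  for (j in 1:6) s2 <- s2 + w[j, substring(pep, j + 3, j + 3)]
  expect_equal(cleavageProbability(pep, m), unname(plogis(s2)),
               tolerance = 1e-12)
  expect_error(cleavageProbability(pep, zeroMatrix("tap", 4L)), "cleavage")
})

test_that("TAP affinity weights the N-terminus relative to the C-terminus", {
  m0 <- zeroMatrix("tap", 4L)
  expect_equal(tapAffinity("KVAELVHFL", m0), 1.0)

  set.seed(92)
  m <- randomMatrix("tap", 4L, intercept = 1.1)
  w <- slot(m, "weights")
  pep <- "KVAELVHFL"
  # tapWeight 0: only intercept + C-terminal residue weight remain
  expect_equal(tapAffinity(pep, m, tapWeight = 0),
               unname(10^(1.1 + w[4, "L"])), tolerance = 1e-12)
  # direct evaluation at the default weight
  lg <- 1.1 + w[4, "L"] + 0.2 * (w[1, "K"] + w[2, "V"] + w[3, "A"])
  expect_equal(tapAffinity(pep, m, tapWeight = 0.2), unname(10^lg),
               tolerance = 1e-12)
  expect_error(tapAffinity(pep, m, tapWeight = -1), ">= 0")
})

test_that("MHC affinity is position-additive in log space", {
  expect_equal(mhcAffinity("KVAELVHFL", zeroMatrix("mhc", 9L,
                                                   intercept = 2)), 100.0)
  set.seed(93)
  m <- randomMatrix("mhc", 9L, intercept = 2)
  w <- slot(m, "weights")
  pep <- "KVAELVHFL"
  lg <- 2 + sum(vapply(1:9, function(i)
    w[i, substring(pep, i, i)], numeric(1)))
  expect_equal(mhcAffinity(pep, m), unname(10^lg), tolerance = 1e-12)

  # single-position perturbation shifts log10 affinity by exactly delta
  w2 <- w; w2[5, "L"] <- w2[5, "L"] + 0.37
  m2 <- scoringMatrix("mhc", w2, 2)
  expect_equal(log10(mhcAffinity(pep, m2)) - log10(mhcAffinity(pep, m)),
               0.37, tolerance = 1e-12)

  expect_error(mhcAffinity("KVAELVHFLXX", m), "length")
})

test_that("qScore implements P_CL / (A_TAP * A_MHC) with guards", {
  expect_identical(qScore(1, 1, 1), 1.0)
  expect_identical(qScore(0.5, 50, 500), 2e-5)
  expect_identical(qScore(0, 123, 456), 0)
  expect_error(qScore(0.5, 0, 1), "positive")
  expect_error(qScore(0.5, 1, -2), "positive")
  expect_error(qScore(1.2, 1, 1), "\\[0, 1\\]")
  # strict monotonicity in each argument
  expect_gt(qScore(0.6, 10, 10), qScore(0.5, 10, 10))
  expect_lt(qScore(0.5, 20, 10), qScore(0.5, 10, 10))
  expect_lt(qScore(0.5, 10, 20), qScore(0.5, 10, 10))
})

test_that("scoring matrices round-trip through TSV bit-identically", {
  set.seed(94)
  m <- randomMatrix("mhc", 9L, intercept = 1.5)
  f <- tempfile(fileext = ".tsv")
  writeScoringMatrix(m, f)
  m2 <- readScoringMatrix(f, "mhc")
  expect_identical(mhcAffinity("KVAELVHFL", m),
                   mhcAffinity("KVAELVHFL", m2))
})

test_that("precomputed scores are validated and Q always recomputed", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("ne_sequence\tp_cl\ta_tap\ta_mhc\tq",
               "AAAAAAAAA\t1\t1\t1\t999"), f)
  sc <- loadPrecomputedScores(f)
  expect_identical(sc$q, 1.0)  # the file's q column is ignored

  writeLines(c("ne_sequence\tp_cl\ta_tap", "AAAAAAAAA\t1\t1"), f)
  expect_error(loadPrecomputedScores(f), "a_mhc")
  writeLines(c("ne_sequence\tp_cl\ta_tap\ta_mhc",
               "AAAAAAAAA\t1\tx\t1"), f)
  expect_error(loadPrecomputedScores(f), "row 1")
  writeLines(c("ne_sequence\tp_cl\ta_tap\ta_mhc",
               "AAAAAAAAA\t0.5\t1\t1", "CCCCCCCCC\t1.5\t1\t1"), f)
  expect_error(loadPrecomputedScores(f), "row 2")
  writeLines(c("ne_sequence\tp_cl\ta_tap\ta_mhc",
               "AAAAAAAAA\t0.5\t0\t1"), f)
  expect_error(loadPrecomputedScores(f), "row 1")
})

test_that("filterNEs applies both thresholds and is monotone", {
  set.seed(95)
  # a population of NEs with varied scores, via the precomputed-score path
  q <- randomPeptide(9)
  seqs <- setNames(vapply(1:20, function(i)
    paste0(randomPeptide(5), mutateAt(q, sample(0:2, 1)),
           randomPeptide(5)), character(1)), sprintf("P%02d", 1:20))
  fa <- tempfile(fileext = ".fasta")
  writeFasta(seqs, fa, genes = sprintf("G%02d", 1:20))
  p <- loadProteome(fa)
  nes <- findNaturalEpitopes(q, p, K = 2)
  expect_gte(length(nes), 20L)
  h <- as.data.frame(nes)
  scores <- data.frame(ne_sequence = unique(h$ne_sequence),
                       stringsAsFactors = FALSE)
  scores$p_cl <- runif(nrow(scores))
  scores$a_tap <- 10^runif(nrow(scores), -1, 2)
  scores$a_mhc <- 10^runif(nrow(scores), 0, 4)
  scores$q <- scores$p_cl / (scores$a_tap * scores$a_mhc)
  scored <- scoreNaturalEpitopes(nes, scores = scores)

  # identity filter at zero thresholds (all q > 0 here)
  expect_equal(length(filterNEs(scored, 0, 0)), length(scored))

  # predicate oracle at the default thresholds
  hs <- as.data.frame(scored)
  keep <- filterNEs(scored, 1e-4, 0.7)
  oracle <- hs[hs$q > 1e-4 & hs$p_cl >= 0.7, ]
  expect_equal(length(keep), nrow(oracle))
  expect_setequal(paste(as.data.frame(keep)$accession,
                        as.data.frame(keep)$start),
                  paste(oracle$accession, oracle$start))

  # monotone: raising either threshold never adds NEs
  for (i in 1:20) {
    q1 <- 10^runif(1, -6, -2); c1 <- runif(1)
    a <- length(filterNEs(scored, q1, c1))
    expect_lte(length(filterNEs(scored, q1 * 10, c1)), a)
    expect_lte(length(filterNEs(scored, q1, min(1, c1 + 0.1))), a)
  }

  # a low-Q NE is removed
  one <- scoreNaturalEpitopes(nes[1], scores = transform(
    scores[scores$ne_sequence == h$ne_sequence[1], ],
    p_cl = 1, a_tap = 100, a_mhc = 1000))
  expect_equal(length(filterNEs(one, 1e-4, 0)), 0L)  # Q = 1e-5
})

test_that("matrix-scored NEs use flanking context from the source protein", {
  fa <- tempfile(fileext = ".fasta")
  q <- "KVAELVHFL"
  writeFasta(c(P1 = paste0("MNPWEF", q, "QRSTVW")), fa, genes = "G1")
  p <- loadProteome(fa)
  nes <- findNaturalEpitopes(q, p, K = 0)
  set.seed(96)
  mats <- list(cleavage = randomMatrix("cleavage", 12L),
               tap = randomMatrix("tap", 4L, intercept = 1),
               mhc = randomMatrix("mhc", 9L, intercept = 2))
  scored <- as.data.frame(scoreNaturalEpitopes(nes, proteome = p,
                                               matrices = mats))
  expect_identical(scored$p_cl,
                   cleavageProbability(q, mats$cleavage,
                                       flankBefore = "MNPWEF",
                                       flankAfter = "QRSTVW"))
  expect_identical(scored$a_tap, tapAffinity(q, mats$tap, 0.2))
  expect_identical(scored$a_mhc, mhcAffinity(q, mats$mhc))
  # bit-identical reproducibility: same matrix + peptide, twice
  expect_identical(mhcAffinity(q, mats$mhc), mhcAffinity(q, mats$mhc))
  expect_identical(scored$q,
                   scored$p_cl / (scored$a_tap * scored$a_mhc))
})
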