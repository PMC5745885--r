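# Frozen high-precision reference values, computed once with 50-digit
# arbitrary-precision arithmetic from P(k) = 1-(1-0.05^(l-k))^(N-l+1) and
# v(k) = (1/P(k)) / sum(1/P(k)).
P0_9_65M <- 1.2694505117014230529e-4
V_9_3_65M <- c(0.9498270889088949, 0.04754865342123655,
               0.002435215149916917, 0.0001890425199516542)
V_10_2_1M <- c(0.9501186790034874, 0.0475059780226345,
               0.00237534297387806)

test_that("mismatchProbability matches closed forms and the hp oracle", {
  expect_equal(mismatchProbability(9, 9, 6.5e7), 1.0)     # k = l
  l <- 9
  for (k in 0:3)                                          # N = l: one window
    expect_equal(mismatchProbability(l, k, l), 0.05^(l - k),
                 tolerance = 1e-14)
  expect_equal(mismatchProbability(9, 0, 6.5e7), P0_9_65M,
               tolerance = 1e-12)
  expect_error(mismatchProbability(9, 0, 5), "N")
  expect_error(mismatchProbability(9, 10, 6.5e7), "k")
})

test_that("mismatchWeights reproduce the printed 9-mer values", {
  v <- mismatchWeights(9, 3, 6.5e7)
  expect_equal(unname(v), V_9_3_65M, tolerance = 1e-12)
  # printed precision (one unit in the last printed digit)
  expect_equal(round(v[["0"]], 2), 0.95)
  expect_equal(round(v[["1"]], 4), 0.0475)
  expect_lte(abs(round(v[["2"]], 4) - 0.0023), 1e-4 + 1e-12)
  expect_equal(round(v[["3"]], 4), 0.0002)

  expect_equal(unname(mismatchWeights(9, 0, 6.5e7)), 1.0)  # K = 0
  expect_equal(unname(mismatchWeights(10, 2, 1e6)), V_10_2_1M,
               tolerance = 1e-10)
})

test_that("mismatch weights sum to one and decrease, over random models", {
  set.seed(404)
  for (i in 1:300) {
    l <- sample(7:25, 1); K <- sample(0:3, 1)
    N <- sample(c(1e3, 1e5, 1e7, 6.5e7), 1) + sample(0:99, 1)
    if (N < l) next
    m <- mismatchModel(l, K, N)
    v <- normalizedWeights(m)
    expect_lt(abs(sum(v) - 1), 1e-12)
    if (K > 0) {
      expect_true(all(diff(v) < 0))
      expect_true(all(diff(mismatchProbabilities(m)) > 0))
    }
  }
})

test_that("tissueProfile implements the v-weighted log-abundance sum", {
  # no NEs: all-zero profile
  p <- blankProteome()
  empty <- findNaturalEpitopes("WYWYWYWYW", p, K = 0)
  tab <- makeTable(matrix(5, 1, 2, dimnames = list("G1",
                                                   c("lung", "heart"))))
  model <- mismatchModel(9, 0, 60)
  expect_equal(unname(tissueProfile(empty, tab, model)), c(0, 0))

  # one exact NE with abundance 999: S = v(0) * log10(1000) = 3
  fa <- tempfile(fileext = ".fasta")
  writeFasta(c(P1 = "MAKVAELVHFLQQ"), fa, genes = "G1")
  pr <- loadProteome(fa)
  nes <- findNaturalEpitopes("KVAELVHFL", pr, K = 0)
  tab999 <- makeTable(matrix(c(999, 0), 1, 2,
                             dimnames = list("G1", c("lung", "heart"))))
  m0 <- mismatchModel(9, 0, proteomeLength(pr))
  S <- tissueProfile(nes, tab999, m0)
  expect_equal(unname(S["lung"]), 3.0)
  expect_equal(unname(S["heart"]), 0.0)

  # mixed k = 0 and k = 1 across tissues: direct re-evaluation
  set.seed(55)
  q <- "KVAELVHFL"
  seqs <- c(E1 = paste0("AA", q, "CC"),
            E2 = paste0(mutateAt(q, 1), "DDDD"),
            E3 = paste0("W", mutateAt(q, 1), "W"))
  writeFasta(seqs, fa, genes = c("GA", "GB", "GC"))
  pr2 <- loadProteome(fa)
  nes2 <- deduplicateNEs(findNaturalEpitopes(q, pr2, K = 1))
  tissues <- c("lung", "heart", "skin", "eye")
  m <- matrix(10^runif(12, -1, 3), 3,
              dimnames = list(c("GA", "GB", "GC"), tissues))
  tab2 <- makeTable(m)
  model2 <- mismatchModel(9, 1, proteomeLength(pr2))
  v <- normalizedWeights(model2)
  S2 <- tissueProfile(nes2, tab2, model2)
  h <- as.data.frame(nes2)
  for (t in tissues) {
    a0 <- sum(m[h$gene[h$k == 0], t])
    a1 <- sum(m[h$gene[h$k == 1], t])
    manual <- v[1] * log10(1 + a0) + v[2] * log10(1 + a1)
    expect_equal(unname(S2[t]), unname(manual), tolerance = 1e-14)
  }

  # the raw convention recovers log10 of the sum where defined
  S3 <- tissueProfile(nes, tab999, m0, convention = "raw")
  expect_equal(unname(S3["lung"]), log10(999))
  expect_equal(unname(S3["heart"]), 0)
})

test_that("weightedCRIndex is a weighted mean excluding zero weights", {
  sch <- makeScheme(c(lung = 1, heart = 1, skin = 1))
  expect_equal(weightedCRIndex(c(lung = 2.5, heart = 2.5, skin = 2.5),
                               sch), 2.5)
  sch2 <- makeScheme(c(lung = 1, testis = 0))
  expect_equal(weightedCRIndex(c(lung = 2, testis = 5), sch2), 2.0)
  expect_error(weightedCRIndex(c(lung = 2), makeScheme(c(lung = 0))),
               "zero")

  # hand-computed weighted mean under the shipped scheme
  S <- c("lung/respiratory system" = 1.2, "heart" = 0.4, "skin" = 2.0,
         "eye" = 1.0, "tonsils" = 3.0, "testis" = 9.9)
  got <- weightedCRIndex(S, defaultTissueWeights())
  manual <- (1 * 1.2 + 1 * 0.4 + 0.8 * 2.0 + 0.5 * 1.0 + 0.3 * 3.0 +
               0 * 9.9) / (1 + 1 + 0.8 + 0.5 + 0.3 + 0)
  expect_equal(got, manual, tolerance = 1e-14)
})

test_that("bootstrapError is deterministic and follows the RNG contract", {
  set.seed(66)
  q <- "KVAELVHFL"
  n <- 30
  seqs <- setNames(vapply(seq_len(n), function(i)
    paste0(randomPeptide(4), mutateAt(q, sample(0:1, 1)),
           randomPeptide(4)), character(1)), sprintf("P%02d", seq_len(n)))
  fa <- tempfile(fileext = ".fasta")
  writeFasta(seqs, fa, genes = sprintf("G%02d", seq_len(n)))
  pr <- loadProteome(fa)
  nes <- deduplicateNEs(findNaturalEpitopes(q, pr, K = 1))
  expect_gte(length(nes), 25)
  m <- matrix(10^runif(length(unique(sprintf("G%02d", 1:n))) * 3, -1, 3),
              ncol = 3, dimnames = list(sprintf("G%02d", 1:n),
                                        c("lung", "heart", "skin")))
  tab <- makeTable(m)
  model <- mismatchModel(9, 1, proteomeLength(pr))
  sch <- makeScheme(c(lung = 1, heart = 0.8, skin = 0.5))

  e1 <- bootstrapError(nes, tab, model, sch, seed = 42)
  e2 <- bootstrapError(nes, tab, model, sch, seed = 42)
  expect_identical(e1, e2)
  expect_gt(e1, 0)

  # reference re-implementation sharing the RNG stream
  nn <- length(nes); mm <- max(1L, as.integer(floor(0.9 * nn)))
  set.seed(42)
  idx <- lapply(1:10, function(r) sort(sample.int(nn, mm)))
  ref <- sd(vapply(idx, function(ii)
    weightedCRIndex(tissueProfile(nes[ii], tab, model), sch), numeric(1)))
  expect_equal(e1, ref, tolerance = 1e-14)

  # degenerate cases give zero error
  expect_identical(bootstrapError(nes, tab, model, sch, frac = 1,
                                  seed = 1), 0)
  expect_identical(bootstrapError(nes[1], tab, model, sch, seed = 1), 0)
  p0 <- blankProteome()
  none <- findNaturalEpitopes("WYWYWYWYW", p0, K = 0)
  expect_identical(bootstrapError(none, tab, model, sch, seed = 1), 0)
})

test_that("averageOverDatabases is the plain mean", {
  expect_equal(averageOverDatabases(c(1, 3)), 2.0)
  expect_equal(averageOverDatabases(5.5), 5.5)
  expect_equal(averageOverDatabases(1:7), 4)
  expect_error(averageOverDatabases(numeric(0)), "no database")
})

test_that("I_CR is invariant under weight scaling and monotone in abundance", {
  set.seed(505)
  fa <- tempfile(fileext = ".fasta")
  q <- "KVAELVHFL"
  writeFasta(c(P1 = paste0("AA", q, "CC")), fa, genes = "GA")
  pr <- loadProteome(fa)
  nes <- findNaturalEpitopes(q, pr, K = 0)
  model <- mismatchModel(9, 0, proteomeLength(pr))
  for (i in 1:40) {
    tissues <- c("lung", "heart", "skin")
    m <- matrix(10^runif(3, -1, 3), 1, dimnames = list("GA", tissues))
    w <- runif(3, 0.05, 0.5)
    S <- tissueProfile(nes, makeTable(m), model)
    i1 <- weightedCRIndex(S, makeScheme(setNames(w, tissues)))
    i2 <- weightedCRIndex(S, makeScheme(setNames(2 * w, tissues)))
    expect_equal(i1, i2, tolerance = 1e-12)
    # adding abundance in a positive-weight tissue never decreases I_CR
    m2 <- m; m2[1, "lung"] <- m2[1, "lung"] + 10^runif(1, 0, 3)
    S2 <- tissueProfile(nes, makeTable(m2), model)
    expect_gte(weightedCRIndex(S2, makeScheme(setNames(w, tissues))), i1)
  }
})

test_that("planted self-matches in vital tissue outrank k=1 matches", {
  # identical setup except: exact match + weight-1 tissue vs one-mismatch
  # match + weight-0.3 tissue; the former must score strictly higher
  set.seed(606)
  for (i in 1:10) {
    q <- randomPeptide(9)
    fa <- tempfile(fileext = ".fasta")
    writeFasta(c(P1 = paste0("AAAA", q, "CCCC")), fa, genes = "GA")
    prExact <- loadProteome(fa)
    writeFasta(c(P1 = paste0("AAAA", mutateAt(q, 1), "CCCC")), fa,
               genes = "GA")
    prMm <- loadProteome(fa)
    ab <- matrix(c(800, 0), 1, dimnames = list("GA", c("vital", "minor")))
    tab <- makeTable(ab)
    tabSwap <- makeTable(matrix(c(0, 800), 1,
                                dimnames = list("GA",
                                                c("vital", "minor"))))
    sch <- makeScheme(c(vital = 1, minor = 0.3))
    mod <- mismatchModel(9, 1, proteomeLength(prExact))
    iExact <- weightedCRIndex(tissueProfile(
      findNaturalEpitopes(q, prExact, 1), tab, mod), sch)
    iMm <- weightedCRIndex(tissueProfile(
      findNaturalEpitopes(q, prMm, 1), tabSwap, mod), sch)
    expect_gt(iExact, iMm)
  }
})

test_that("computeCRResult assembles and averages per-database results", {
  fa <- tempfile(fileext = ".fasta")
  q <- "KVAELVHFL"
  writeFasta(c(P1 = paste0("AA", q, "CC")), fa, genes = "GA")
  pr <- loadProteome(fa)
  nes <- findNaturalEpitopes(q, pr, K = 0)
  model <- mismatchModel(9, 0, proteomeLength(pr))
  sch <- makeScheme(c(lung = 1, heart = 0.8))
  mk <- function(a, id) makeTable(matrix(c(a, a / 2), 1,
    dimnames = list("GA", c("lung", "heart"))), id)
  res <- computeCRResult(nes, list(mk(100, "d1"), mk(10, "d2")), model,
                         sch, seed = 3)
  expect_s4_class(res, "CRResult")
  icr <- crIndices(res)
  expect_equal(names(icr), c("d1", "d2"))
  expect_equal(averagedCRIndex(res), mean(icr))
  expect_true(all(vapply(tissueProfiles(res), function(S) all(S >= 0),
                         logical(1))))
})
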