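# A tiny tagger over the fixture DB, reused across blocks.
makeTinyTagger <- function(sum = FALSE, hidden = 8L, dim = 6L, seed = 2L) {
  db <- fixtureDB()
  corpus <- smallTaggedCorpus()
  left <- pretrainEmbeddings(corpus, "radical", db, dim = dim, epochs = 2,
                             seed = seed)
  right <- pretrainEmbeddings(corpus, "pinyin", db, dim = dim, epochs = 2,
                              seed = seed + 1L)
  fm <- featureModel("R+P", db, left, right, sum = sum)
  crfTagger(fm, tagSet(), hidden = hidden, seed = seed)
}

test_that("the BIO tag set encodes reachability of inside tags", {
  ts <- tagSet()
  expect_length(ts@tags, 11L)
  expect_true(ts@allowed["B-DIS", "I-DIS"])
  expect_true(ts@allowed["I-DIS", "I-DIS"])
  expect_false(ts@allowed["O", "I-DIS"])
  expect_false(ts@allowed["B-SYM", "I-DIS"])
  expect_false(ts@allowed["START", "I-BOD"])
  expect_true(ts@allowed["START", "B-BOD"])
  expect_true(validBIO(c("O", "B-DIS", "I-DIS", "O")))
  expect_false(validBIO(c("O", "I-DIS")))
  expect_false(validBIO(c("B-DIS", "I-SYM")))
})

test_that("path scores decompose into emissions plus transitions", {
  set.seed(11)
  ts <- openTagSet(5)
  for (rep in 1:20) {
    n <- sample(1:6, 1)
    E <- matrix(rnorm(5 * n), 5, n)
    tr <- matrix(rnorm(49), 7, 7)
    ids <- sample(1:5, n, replace = TRUE)
    # independent term-by-term summation
    want <- sum(E[cbind(ids, 1:n)]) + tr[ts@start, ids[1]] + tr[ids[n], ts@stop]
    if (n > 1) want <- want + sum(tr[cbind(ids[-n], ids[-1])])
    expect_equal(crfScore(E, tr, ids, ts), want)
  }
  # all-zero scores give score 0 for every path
  expect_identical(crfScore(matrix(0, 5, 3), matrix(0, 7, 7), c(1, 5, 2), ts), 0)
})

test_that("log-partition matches closed forms and exhaustive enumeration", {
  ts <- openTagSet(2)
  # single position: logsumexp of the two emission scores
  E <- matrix(c(0.3, -1.2), 2, 1)
  expect_equal(crfLogPartition(E, matrix(0, 4, 4), ts),
               log(sum(exp(c(0.3, -1.2)))))
  # uniform zero scores: log of the number of paths = n log T
  for (n in c(1, 3, 5)) {
    ts7 <- openTagSet(7)
    expect_equal(crfLogPartition(matrix(0, 7, n), matrix(0, 9, 9), ts7),
                 n * log(7))
  }
  set.seed(12)
  for (rep in 1:30) {
    T <- sample(2:7, 1); n <- sample(1:6, 1)
    tsr <- openTagSet(T)
    E <- matrix(rnorm(T * n), T, n)
    tr <- matrix(rnorm((T + 2)^2), T + 2, T + 2)
    b <- bruteCRF(E, tr, tsr)
    expect_equal(crfLogPartition(E, tr, tsr), b$logZ, tolerance = 1e-9)
  }
})

test_that("Viterbi equals exhaustive argmax and respects constraints", {
  set.seed(13)
  for (rep in 1:30) {
    T <- sample(2:7, 1); n <- sample(1:6, 1)
    tsr <- openTagSet(T)
    E <- matrix(rnorm(T * n), T, n)
    tr <- matrix(rnorm((T + 2)^2), T + 2, T + 2)
    expect_identical(crfViterbi(E, tr, tsr), unname(bruteCRF(E, tr, tsr)$best))
  }
  # under the BIO tag set the decoded path is always valid
  ts <- tagSet()
  for (rep in 1:20) {
    n <- sample(1:8, 1)
    E <- matrix(rnorm(11 * n, sd = 3), 11, n)
    ids <- crfViterbi(E, matrix(0, 13, 13), ts)
    expect_true(validBIO(ts@tags[ids]))
  }
})

test_that("tagger-level score, partition and decode are mutually consistent", {
  tg <- makeTinyTagger()
  s <- smallTaggedCorpus()[[1]]
  lz <- logPartition(tg, s$chars)
  expect_gte(lz, sequenceScore(tg, s$chars, s$tags))   # NLL >= 0
  dec <- viterbiDecode(tg, s$chars)
  expect_length(dec$tags, length(s$chars))
  expect_true(validBIO(dec$tags))
  expect_gte(lz, sequenceScore(tg, s$chars, dec$tags))
  expect_error(sequenceScore(tg, s$chars, s$tags[-1]), "length")
})

test_that("analytic gradients match finite differences", {
  tg <- makeTinyTagger(hidden = 4L, dim = 3L)
  enc <- phonosemNER:::.encodeFeatures(tg, c("病", "胃", "痛"))
  y <- match(c("B-DIS", "O", "B-SYM"), tg@tagset@tags) - 1L
  pen <- phonosemNER:::.penMatrix(tg@tagset)
  g <- phonosemNER:::cpp_tagger_grad(tg@params, enc$il, enc$ir, y, pen)
  set.seed(14)
  h <- 1e-5
  for (nm in c("LW", "Wf", "Ub", "Wout", "trans", "bc", "Ltab", "Rtab")) {
    for (idx in sample(length(tg@params[[nm]]), min(4, length(tg@params[[nm]])))) {
      pp <- tg@params; pm <- tg@params
      pp[[nm]][idx] <- pp[[nm]][idx] + h
      pm[[nm]][idx] <- pm[[nm]][idx] - h
      numg <- (phonosemNER:::cpp_tagger_nll(pp, enc$il, enc$ir, y, pen) -
               phonosemNER:::cpp_tagger_nll(pm, enc$il, enc$ir, y, pen)) / (2 * h)
      expect_equal(g[[nm]][idx], numg, tolerance = 1e-4,
                   label = paste("grad", nm, idx))
    }
  }
})

test_that("training descends, is reproducible, and can memorize", {
  corpus <- smallTaggedCorpus()
  tg <- makeTinyTagger(hidden = 16L)
  expect_error(trainTagger(tg, list(list(chars = c("病"), tags = c("I-DIS")))),
               "invalid BIO")
  fit1 <- trainTagger(tg, corpus, epochs = 60, lr = 5e-3, batchSize = 1,
                      seed = 7)
  expect_lt(fit1@lossTrace[2], fit1@lossTrace[1])
  fit2 <- trainTagger(tg, corpus, epochs = 60, lr = 5e-3, batchSize = 1,
                      seed = 7)
  expect_identical(fit1@lossTrace, fit2@lossTrace)
  # memorization: training-set F reaches 1 on a separable toy corpus
  pred <- tagSentences(fit1, corpus)
  expect_equal(overallF(scoreEntities(corpus, pred)), 1.0)
})

test_that("the Sum variant trains with the composition layer frozen", {
  corpus <- smallTaggedCorpus()
  tg <- makeTinyTagger(sum = TRUE)
  d <- nrow(tg@params$LW)
  fit <- trainTagger(tg, corpus, epochs = 10, lr = 5e-3, seed = 7)
  expect_identical(fit@params$LW, diag(d))
  expect_identical(fit@params$RW, diag(d))
  expect_identical(fit@params$bc, numeric(d))
  expect_lt(fit@lossTrace[10], fit@lossTrace[1])
})

test_that("a saved checkpoint reproduces decoding bit-exactly", {
  corpus <- smallTaggedCorpus()
  fit <- trainTagger(makeTinyTagger(), corpus, epochs = 5, seed = 3)
  f <- tempfile(fileext = ".rds")
  saveTagger(fit, f)
  back <- loadTagger(f)
  for (s in corpus)
    expect_identical(viterbiDecode(back, s$chars), viterbiDecode(fit, s$chars))
  expect_identical(emissionScores(back, corpus[[1]]$chars),
                   emissionScores(fit, corpus[[1]]$chars))
  unlink(f)
})
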