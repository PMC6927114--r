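test_that("word2vec text format round-trips value-identically", {
  set.seed(3)
  m <- matrix(rnorm(15), 5, 3,
              dimnames = list(c("a", "b", "走", "ing", "tǔ"), NULL))
  tab <- embeddingTable(m)
  f <- tempfile(fileext = ".vec")
  writeWord2vec(tab, f)
  tab2 <- readWord2vec(f)
  expect_identical(tab2@dim, 3L)
  expect_identical(tab2@vectors[rownames(m), ], m)
  expect_identical(tab2@unk, tab@unk)
  # a second write is byte-identical
  f2 <- tempfile(fileext = ".vec")
  writeWord2vec(tab2, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f, f2))
})

test_that("skip-gram pretraining is deterministic and separates contexts", {
  db <- makeDB(c("A", "B", "C", "D"), c("r", "r", "s", "s"),
               c("tā", "tō", "lǐng", "mǔ"), c("A", "B", "C", "D"))
  # A always next to B; C always next to D; the pairs never mix
  corpus <- c(rep(list(c("A", "B"), c("B", "A")), 40),
              rep(list(c("C", "D"), c("D", "C")), 40))
  t1 <- pretrainEmbeddings(corpus, "char", db, dim = 16, epochs = 8, seed = 4)
  t2 <- pretrainEmbeddings(corpus, "char", db, dim = 16, epochs = 8, seed = 4)
  expect_identical(t1@vectors, t2@vectors)     # bit-identical under one seed
  cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  coAB <- cosine(embLookup(t1, "A"), embLookup(t1, "B"))
  coAC <- cosine(embLookup(t1, "A"), embLookup(t1, "C"))
  expect_gt(coAB, coAC)
})

test_that("view mapping drives pretraining vocabulary and degenerate cases", {
  db <- makeDB(c("A", "B"), c("r", "r"), c("tā", "tō"), c("A", "B"))
  tab <- pretrainEmbeddings(list(c("A", "B", "A")), "radical", db,
                            dim = 8, epochs = 2, seed = 1)
  expect_identical(embTokens(tab), "r")        # single-type stream trains fine
  expect_error(pretrainEmbeddings(list(c("X", "Y")), "radical", db,
                                  dim = 8, seed = 1), "entirely unknown")
  # R+P vs R+F keys for the same characters
  fdb <- fixtureDB()
  expect_identical(viewTokens(fdb, "痨", "pinyin"), "lao")
  expect_identical(viewTokens(fdb, "痨", "final"), "ao")
})

test_that("composition implements the linear layer and its Sum degeneracy", {
  # fixed non-trainable variant is exact vector addition
  sum2 <- compositionParams(2, trainable = FALSE)
  expect_identical(compose(sum2, c(1, 2), c(3, 4)), c(4, 6))
  # identity/zero cases
  p <- compositionParams(2)
  p@RW <- matrix(0, 2, 2)
  expect_identical(compose(p, c(5, -1), c(9, 9)), c(5, -1))
  # hand-computed general case
  q <- new("CompositionParams", LW = matrix(c(1, 0, 0, 2), 2, 2, byrow = TRUE),
           RW = matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE),
           b = c(1, 1), trainable = TRUE)
  expect_identical(compose(q, c(1, 1), c(2, 3)), c(7, 3))
  # linearity in the left argument at fixed right input
  set.seed(8)
  for (i in 1:20) {
    pp <- new("CompositionParams", LW = matrix(rnorm(6), 2, 3),
              RW = matrix(rnorm(4), 2, 2), b = rnorm(2), trainable = TRUE)
    a <- rnorm(3); a2 <- rnorm(3); r <- rnorm(2)
    expect_equal(compose(pp, a + a2, r),
                 compose(pp, a, r) + compose(pp, a2, r) -
                   compose(pp, numeric(3), r))
  }
  expect_error(compose(sum2, c(1, 2, 3), c(1, 2)), "shape")
})

test_that("sentence embedding is position-wise with total UNK fallback", {
  db <- makeDB(c("A", "B", "C", "r", "s"), c("r", "r", "s", "r", "s"),
               c("tā", "tá", "lǐng", "pō", "pò"),
               c("⿰rs", "⿰rs", "⿰rs", "r", "s"))
  set.seed(5)
  left <- embeddingTable(matrix(rnorm(4), 2, 2, dimnames = list(c("r", "s"), NULL)))
  right <- embeddingTable(matrix(rnorm(6), 3, 2,
                                 dimnames = list(c("ta", "ling", "po"), NULL)))
  fm <- featureModel("R+P", db, left, right)
  E <- embedSentence(fm, c("A", "B", "C", "Z"))
  expect_identical(dim(E), c(2L, 4L))
  # A and B share radical and toneless pinyin -> identical vectors
  expect_identical(E[, 1], E[, 2])
  # unknown symbol composes the two UNK vectors
  expect_identical(E[, 4], compose(fm@params, left@unk, right@unk))
  # permuting the characters permutes the columns
  E2 <- embedSentence(fm, c("C", "Z", "A", "B"))
  expect_identical(E2, E[, c(3, 4, 1, 2)])
})

test_that("the Sum feature model equals element-wise addition everywhere", {
  db <- makeDB(c("A", "r"), c("r", "r"), c("tā", "pō"), c("A", "r"))
  set.seed(6)
  left <- embeddingTable(matrix(rnorm(3), 1, 3, dimnames = list("r", NULL)))
  right <- embeddingTable(matrix(rnorm(3), 1, 3, dimnames = list("ta", NULL)))
  fm <- featureModel("R+P", db, left, right, sum = TRUE)
  E <- embedSentence(fm, c("A", "A"))
  expect_identical(E[, 1], embLookup(left, "r") + embLookup(right, "ta"))
})
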