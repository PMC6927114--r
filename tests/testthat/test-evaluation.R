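test_that("entity extraction finds maximal runs and applies the strict policy", {
  e <- extractEntities(c("O", "B-DIS", "I-DIS", "O"))
  expect_identical(e, data.frame(type = "DIS", start = 1L, end = 3L))
  # type switch inside a run: B-DIS of length 1, dangling I-SYM dropped
  e2 <- extractEntities(c("B-DIS", "I-SYM"))
  expect_identical(e2, data.frame(type = "DIS", start = 0L, end = 1L))
  # lenient mode repairs the dangling inside tag to a new mention
  e3 <- extractEntities(c("B-DIS", "I-SYM"), lenient = TRUE)
  expect_identical(nrow(e3), 2L)
  expect_identical(e3$type, c("DIS", "SYM"))
  expect_identical(nrow(extractEntities(c("O", "O"))), 0L)
  # back-to-back mentions of one type split at each B
  e4 <- extractEntities(c("B-TRE", "B-TRE", "I-TRE"))
  expect_identical(e4$start, c(0L, 1L))
  expect_identical(e4$end, c(1L, 3L))
  expect_error(extractEntities(c("O", "Z-DIS")), "unknown tag")
})

test_that("exact-match micro scoring matches manual tallies", {
  gold <- list(list(chars = strsplit("abcdefg", "")[[1]],
                    tags = c("B-DIS", "I-DIS", "O", "B-SYM", "O", "B-BOD", "I-BOD")),
               list(chars = strsplit("hij", "")[[1]],
                    tags = c("O", "B-TRE", "O")))
  expect_equal(overallF(scoreEntities(gold, gold)), 1.0)
  pred <- list(list(chars = gold[[1]]$chars,
                    # DIS exact; SYM span wrong (len 2); BOD missed
                    tags = c("B-DIS", "I-DIS", "O", "B-SYM", "I-SYM", "O", "O")),
               list(chars = gold[[2]]$chars,
                    tags = c("O", "B-TRE", "O")))
  r <- scoreEntities(gold, pred)@table
  # manual tally: TP = DIS + TRE = 2, FP = bad SYM = 1, FN = SYM + BOD = 2
  all <- r[r$type == "ALL", ]
  expect_identical(all$tp, 2)
  expect_identical(all$fp, 1)
  expect_identical(all$fn, 2)
  expect_equal(all$precision, 2 / 3)
  expect_equal(all$recall, 1 / 2)
  expect_equal(all$f, 2 * (2/3) * (1/2) / (2/3 + 1/2))
  expect_equal(r$f[r$type == "DIS"], 1.0)
  expect_equal(r$f[r$type == "SYM"], 0.0)
  expect_error(scoreEntities(gold, pred[1]), "differ in size")
})

test_that("cross-validation folds partition the corpus into near-equal parts", {
  f <- cvFolds(103, 5, seed = 2)
  expect_identical(sort(lengths(f), decreasing = TRUE), c(21L, 21L, 21L, 20L, 20L))
  expect_identical(sort(unlist(f)), 1:103)
  expect_identical(cvFolds(103, 5, seed = 2), f)   # seeded determinism
  expect_false(identical(cvFolds(103, 5, seed = 3), f))
  expect_error(cvFolds(10, 1), "at least 2")
  expect_error(cvFolds(3, 5), "fewer items")
})

test_that("cross-validation reports per-fold metrics and their mean", {
  cfg <- syntheticConfig(nChars = 60L, nSentences = 40L, seed = 21L)
  g <- generateCharDB(cfg)
  corpus <- generateCorpus(cfg, g$db)
  # a trivial "model": remembers nothing, predicts the gold tags of its
  # input (perfect tagger) — exercises the scaffolding deterministically
  perfect <- crossValidate(corpus, k = 4, seed = 1,
                           trainFun = function(tr) NULL,
                           predictFun = function(m, test) test)
  expect_equal(perfect$meanF, 1.0)
  expect_length(perfect$foldF, 4L)
  expect_true(all(unlist(lapply(perfect$folds, length)) %in% 10L))
  expect_gte(perfect$meanF, min(perfect$foldF))
  expect_lte(perfect$meanF, max(perfect$foldF))
})

test_that("median sectioning follows the strict-above rule", {
  # percentages 20/30/40/50 -> median 35, A = {40, 50}
  db <- makeDB(c("P", "N", "p", "q", "r"), c("p", "p", "p", "p", "p"),
               c("tīng", "tā", "tú", "bǐng", "bò"),
               c("⿰pq", "⿰pr", "p", "q", "r"))
  mkdoc <- function(nP, nN) paste(c(rep("P", nP), rep("N", nN)), collapse = "")
  docs <- list(mkdoc(2, 8), mkdoc(3, 7), mkdoc(4, 6), mkdoc(5, 5))
  sp <- sectionByPhonoSemantic(db, docs)
  expect_equal(sp@median, 35)
  expect_identical(sp@sectionA, c(3L, 4L))
  expect_identical(sp@sectionB, c(1L, 2L))
  expect_true(all(sp@percentages[sp@sectionA] > sp@median))
  # all-equal percentages: nothing exceeds the median, A is empty
  sp2 <- sectionByPhonoSemantic(db, list(mkdoc(1, 1), mkdoc(2, 2), mkdoc(3, 3)))
  expect_length(sp2@sectionA, 0L)
  expect_length(sp2@sectionB, 3L)
  expect_error(sectionByPhonoSemantic(db, docs[1]), "at least 2")
})

test_that("the section invariant holds on random synthetic document sets", {
  cfg <- syntheticConfig(nChars = 100L, seed = 31L)
  g <- generateCharDB(cfg)
  set.seed(32)
  for (rep in 1:5) {
    docs <- lapply(1:11, function(i)
      sample(names(g$truth), 50, replace = TRUE))
    sp <- sectionByPhonoSemantic(g$db, docs)
    expect_true(all(sp@percentages[sp@sectionA] > sp@median))
    expect_true(all(sp@percentages[sp@sectionB] <= sp@median))
    expect_identical(sort(c(sp@sectionA, sp@sectionB)), 1:11)
  }
})

test_that("radical occurrence ranks planted correlations first", {
  db <- makeDB(c("A", "B", "C"), c("r1", "r2", "r2"),
               c("tā", "tō", "tē"), c("A", "B", "C"))
  corpus <- list(list(chars = c("A", "A", "B", "C"),
                      tags = c("B-DIS", "I-DIS", "O", "O")),
                 list(chars = c("A", "B"),
                      tags = c("B-DIS", "I-DIS")))
  ent <- radicalOccurrence(db, corpus, "entities")
  dis <- ent[ent$scope == "DIS", ]
  expect_identical(dis$radical[1], "r1")      # 3 of 4 entity chars
  expect_equal(dis$pct[1], 75)
  expect_equal(dis$pct[2], 25)
  ov <- radicalOccurrence(db, corpus, "overall")
  expect_equal(ov$pct[ov$radical == "r1"], 50)
  expect_true(all(tapply(ent$pct, ent$scope, sum) <= 100 + 1e-9))
  # one two-character entity with distinct radicals: 50% each
  one <- radicalOccurrence(db, list(list(chars = c("A", "B"),
                                         tags = c("B-SYM", "I-SYM"))),
                           "entities")
  expect_true(all(one$pct == 50))
})
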