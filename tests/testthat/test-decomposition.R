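test_that("IDS parsing handles leaves, nesting and arity, and round-trips", {
  expect_identical(idsToString(parseIDS("X")), "X")
  t2 <- parseIDS("⿰AB")
  expect_identical(t2$op, "⿰")
  expect_length(t2$children, 2L)
  t3 <- parseIDS("⿳宀丰口")
  expect_length(t3$children, 3L)          # ternary operator
  nested <- "⿰A⿱BC"
  expect_identical(idsToString(parseIDS(nested)), nested)
  expect_identical(idsLeaves(parseIDS(nested)), c("A", "B", "C"))
  expect_error(parseIDS("⿰A"), "truncated")
  expect_error(parseIDS("⿰ABC"), "trailing")
  expect_error(parseIDS(""), "non-empty")
})

test_that("random well-formed IDS strings round-trip through the parser", {
  set.seed(31)
  ops <- c("⿰", "⿱", "⿴", "⿳", "⿲")
  genIDS <- function(depth) {
    if (depth == 0 || runif(1) < 0.4)
      return(intToUtf8(0xF100 + sample.int(40, 1)))
    op <- sample(ops, 1)
    k <- if (op %in% c("⿳", "⿲")) 3 else 2
    paste0(op, paste(vapply(seq_len(k), function(i) genIDS(depth - 1),
                            character(1)), collapse = ""))
  }
  for (i in 1:50) {
    s <- genIDS(3)
    expect_identical(idsToString(parseIDS(s)), s)
  }
})

test_that("nested component enumeration respects depth, cycles and atoms", {
  db <- fixtureDB()
  # atomic characters have no components
  expect_identical(nrow(nestedComponents(db, "心")), 0L)
  # the 徒 case: depth-1 components plus the nested 土 at depth 2
  nc <- nestedComponents(db, "徒", maxDepth = 3)
  expect_identical(nc$component[nc$depth == 1], c("彳", "走"))
  expect_true("土" %in% nc$component[nc$depth == 2])
  expect_false("徒" %in% nc$component)
  nc1 <- nestedComponents(db, "徒", maxDepth = 1)
  expect_false("土" %in% nc1$component)
  # reference cycle terminates, each symbol listed once
  cyc <- makeDB(c("A", "B"), c("r", "r"), c("tā", "tō"), c("⿰BC", "⿰AD"))
  nc <- nestedComponents(cyc, "A", maxDepth = 10)
  expect_identical(sort(nc$component), c("B", "C", "D"))
})

test_that("the worked biomedical characters classify as published", {
  db <- fixtureDB()
  positive <- c("病", "痨", "痛", "肝", "胸")
  negative <- c("胃", "心", "害", "脑")
  for (ch in positive)
    expect_true(phonoSemanticCheck(db, ch)@isPhonoSemantic, label = ch)
  for (ch in negative)
    expect_false(phonoSemanticCheck(db, ch)@isPhonoSemantic, label = ch)
  v <- phonoSemanticCheck(db, "病")
  expect_identical(v@phoneticRadical, "丙")
  expect_identical(v@matchedFinal, "ing")
  # 徒 needs the nested expansion
  expect_false(phonoSemanticCheck(db, "徒", maxDepth = 1)@isPhonoSemantic)
  v2 <- phonoSemanticCheck(db, "徒", maxDepth = 2)
  expect_true(v2@isPhonoSemantic)
  expect_identical(v2@phoneticRadical, "土")
  expect_identical(v2@depth, 2L)
})

test_that("verdicts are monotone in depth and never positive for atoms", {
  set.seed(61)
  for (rep in 1:20) {
    db <- randomFixtureDB()
    for (ch in dbChars(db)) {
      verdicts <- vapply(1:4, function(d)
        phonoSemanticCheck(db, ch, maxDepth = d)@isPhonoSemantic, logical(1))
      expect_true(all(diff(verdicts) >= 0), label = paste("monotone", ch))
      if (charLookup(db, ch)@ids == ch)
        expect_false(verdicts[4])
    }
  }
})

test_that("the checker agrees with exhaustive-expansion enumeration", {
  set.seed(71)
  for (rep in 1:25) {
    db <- randomFixtureDB()
    for (ch in dbChars(db)) {
      expect_identical(phonoSemanticCheck(db, ch, maxDepth = 10)@isPhonoSemantic,
                       oraclePhonoSemantic(db, ch),
                       label = paste("db", rep, "char", ch))
    }
  }
})

test_that("phono-semantic percentages count tokens and unique characters", {
  # A phono-semantic by construction, B not
  db <- makeDB(c("A", "B", "p", "q", "r"), c("p", "p", "p", "p", "p"),
               c("tīng", "tā", "tú", "bǐng", "bò"),
               c("⿰pq", "⿰pr", "p", "q", "r"))
  expect_true(phonoSemanticCheck(db, "A")@isPhonoSemantic)
  expect_false(phonoSemanticCheck(db, "B")@isPhonoSemantic)
  expect_equal(phonoSemanticPercentage(db, "AABB"), 50)
  expect_equal(phonoSemanticPercentage(db, "AABB", unique = TRUE), 50)
  expect_equal(phonoSemanticPercentage(db, "AAAB"), 75)
  expect_equal(phonoSemanticPercentage(db, "AAAB", unique = TRUE), 50)
  # symbols outside the DB are excluded from both sides of the ratio
  expect_equal(phonoSemanticPercentage(db, "AAAxy,7B"), 75)
  expect_error(phonoSemanticPercentage(db, "xyz"), "no considered")
})

test_that("percentage recovers the construction rate of a synthetic inventory", {
  cfg <- syntheticConfig(nChars = 200L, phonoFraction = 0.4, seed = 5L)
  g <- generateCharDB(cfg)
  set.seed(9)
  tokens <- sample(names(g$truth), 10000, replace = TRUE)
  pct <- phonoSemanticPercentage(g$db, tokens)
  expect_lt(abs(pct - 100 * mean(g$truth[unique(tokens)][match(tokens, unique(tokens))])), 1e-9)
  expect_lt(abs(pct - 40), 5)
})
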