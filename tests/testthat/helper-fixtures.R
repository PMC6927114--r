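# Shared fixtures, built in code.

fixtureDBPath <- function() {
  system.file("extdata", "biomedical_chars.tsv", package = "phonosemNER")
}

fixtureDB <- local({
  db <- NULL
  function() {
    if (is.null(db)) db <<- readCharDB(fixtureDBPath())
    db
  }
})

# A tiny in-memory DB from a char/radical/readings/ids data.frame
makeDB <- function(char, radical, readings, ids) {
  tsv <- tempfile(fileext = ".tsv")
  on.exit(unlink(tsv))
  writeLines(paste(char, radical, readings, ids, sep = "\t"), tsv,
             useBytes = FALSE)
  readCharDB(tsv)
}

# Random fixture DB for decomposition oracle tests: a pool of private-use
# symbols, each atomic or composed of other pool symbols (reference cycles
# possible), with readings drawn from a small final pool (some symbols
# unreadable).
randomFixtureDB <- function(nChars = 30, finals = c("a", "ing", "ong", "u", "e")) {
  syms <- vapply(seq_len(nChars), function(i) intToUtf8(0xF000 + i), character(1))
  ops2 <- c("⿰", "⿱", "⿸")
  rows <- lapply(seq_len(nChars), function(i) {
    reading <- if (runif(1) < 0.85) {
      paste0(sample(c("b", "t", "l", "x", "zh", ""), 1),
             sample(finals, 1), sample(0:4, 1))
    } else ""   # unreadable symbol: line will be given a placeholder below
    ids <- if (runif(1) < 0.4 || i <= 2) {
      syms[i]
    } else {
      k <- sample(seq_len(nChars)[-i], 2)
      paste0(sample(ops2, 1), syms[k[1]], syms[k[2]])
    }
    list(char = syms[i], reading = reading, ids = ids)
  })
  # symbols with no reading are simply left out of the DB (unknown leaves)
  keep <- vapply(rows, function(r) nzchar(r$reading), logical(1))
  rows <- rows[keep]
  makeDB(vapply(rows, `[[`, character(1), "char"),
         rep("r", length(rows)),
         vapply(rows, `[[`, character(1), "reading"),
         vapply(rows, `[[`, character(1), "ids"))
}

# Independent oracle: exhaustively materialize the full nested component
# set (recursive expansion with a visited set) and test every reading pair.
oraclePhonoSemantic <- function(db, char) {
  rec <- charLookup(db, char)
  finalsOf <- function(r) {
    out <- character(0)
    for (x in r@readings) {
      p <- try(parsePinyin(x), silent = TRUE)
      if (!inherits(p, "try-error")) out <- c(out, p@final)
    }
    unique(out)
  }
  cf <- finalsOf(rec)
  if (length(cf) == 0L) return(FALSE)
  visited <- character(0)
  comps <- character(0)
  expand <- function(sym) {
    if (sym %in% visited) return(invisible())
    visited <<- c(visited, sym)
    r <- charLookup(db, sym)
    if (r@ids == sym) return(invisible())
    for (lf in idsLeaves(parseIDS(r@ids))) {
      if (isIDC(lf)) next
      if (!(lf %in% comps) && lf != char) comps <<- c(comps, lf)
      expand(lf)
    }
  }
  expand(char)
  for (cm in comps) {
    if (length(intersect(cf, finalsOf(charLookup(db, cm)))) > 0L) return(TRUE)
  }
  FALSE
}

# A fully connected tag set (every transition allowed) for unconstrained
# CRF oracle tests.
openTagSet <- function(nTags) {
  nTags <- as.integer(nTags)
  tags <- paste0("T", seq_len(nTags))
  allowed <- matrix(TRUE, nTags + 2L, nTags + 2L,
                    dimnames = list(c(tags, "START", "STOP"),
                                    c(tags, "START", "STOP")))
  allowed[, nTags + 1L] <- FALSE
  allowed[nTags + 2L, ] <- FALSE
  new("TagSet", tags = tags, types = character(0), allowed = allowed,
      start = nTags + 1L, stop = nTags + 2L)
}

# Brute-force CRF reference: enumerate all tag paths, score them with
# vectorized indexing, and return the log-sum-exp and the argmax path.
bruteCRF <- function(emissions, trans, tagset, penalty = -1e4) {
  T <- nrow(emissions); n <- ncol(emissions)
  eff <- trans + penalty * !tagset@allowed
  paths <- as.matrix(expand.grid(rep(list(seq_len(T)), n)))
  sc <- numeric(nrow(paths))
  for (t in seq_len(n)) sc <- sc + emissions[cbind(paths[, t], t)]
  sc <- sc + eff[cbind(tagset@start, paths[, 1])]
  if (n > 1) for (t in 2:n) sc <- sc + eff[cbind(paths[, t - 1], paths[, t])]
  sc <- sc + eff[cbind(paths[, n], tagset@stop)]
  m <- max(sc)
  list(logZ = m + log(sum(exp(sc - m))), best = paths[which.max(sc), ])
}

# A tiny well-separated tagged corpus over the fixture DB characters.
smallTaggedCorpus <- function() {
  list(
    list(chars = c("病", "人", "胃", "痛"),
         tags = c("B-DIS", "O", "B-BOD", "B-SYM")),
    list(chars = c("肝", "胸", "口"),
         tags = c("B-BOD", "I-BOD", "O")),
    list(chars = c("心", "痨", "病"),
         tags = c("O", "B-DIS", "I-DIS")))
}
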