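## Self-contained pseudo-script generator: a private-use-area character
## inventory with controlled phono-semantic fraction, and annotated
## corpora whose entity types correlate with primary radicals.

.PUA_RADICAL <- 0xE000L
.PUA_PHONETIC <- 0xE100L
.PUA_CHAR <- 0xE200L

#' Build a synthetic study configuration
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: a 300-character inventory over 12 radicals (two per entity type
#' plus a background group) and 30 phonetic components, 60% of characters
#' phono-semantic by construction, strong radical-type affinity
#' (`alpha = 19`, i.e. entity characters come from their type's radical
#' group with probability alpha/(alpha+1)), and 2000 sentences of mean
#' length 12 with about two entities each.
#'
#' @param nChars characters in the inventory.
#' @param nRadicals primary radicals; partitioned round-robin into one
#'   group per entity type plus one background group.
#' @param nPhoneticPool phonetic components.
#' @param phonoFraction fraction p of characters whose final is copied
#'   from their phonetic component.
#' @param finalsPool pinyin finals used for synthetic readings (at least 3,
#'   so a non-phono-semantic character can avoid both component finals).
#' @param entityTypes entity types.
#' @param alpha affinity strength; 0 draws entity characters uniformly.
#' @param nSentences,meanLen,entityDensity corpus shape.
#' @param seed master seed; fixes the inventory and the corpus.
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nChars = 300L, nRadicals = 12L,
                            nPhoneticPool = 30L, phonoFraction = 0.6,
                            finalsPool = c("a", "o", "e", "ai", "ao", "an",
                                           "ing", "ong"),
                            entityTypes = c("BOD", "SYM", "DIS", "EXP", "TRE"),
                            alpha = 19, nSentences = 2000L, meanLen = 12,
                            entityDensity = 2, seed = 1L) {
  new("SyntheticConfig", nChars = as.integer(nChars),
      nRadicals = as.integer(nRadicals),
      nPhoneticPool = as.integer(nPhoneticPool),
      phonoFraction = phonoFraction, finalsPool = finalsPool,
      entityTypes = entityTypes, alpha = alpha,
      nSentences = as.integer(nSentences), meanLen = meanLen,
      entityDensity = entityDensity, seed = as.integer(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(paste0("SyntheticConfig: %d chars / %d radicals / %d phonetic, ",
                     "p=%.2f, alpha=%.1f, %d sentences, seed %d\n"),
              object@nChars, object@nRadicals, object@nPhoneticPool,
              object@phonoFraction, object@alpha, object@nSentences,
              object@seed))
})

# round-robin radical -> group map; group ntypes+1 is background
.radGroups <- function(nRadicals, ntypes) {
  ((seq_len(nRadicals) - 1L) %% (ntypes + 1L)) + 1L
}

.syntheticReading <- function(initials, final) {
  paste0(sample(initials, 1L), final, sample(0:4, 1L))
}

#' Generate a synthetic character database
#'
#' Every synthetic character is composed of one primary radical and one
#' phonetic component under a left-right IDC; with probability
#' `phonoFraction` its pinyin final is copied from the phonetic
#' component (phono-semantic by construction), otherwise the final is
#' drawn to differ from both components' finals, so the ground-truth flag
#' is exactly recoverable by the checker. All symbols live in the Unicode
#' private use area, so no real-script knowledge enters.
#'
#' @param cfg a [SyntheticConfig-class].
#' @return list with `db` (a [CharacterDB-class] containing characters,
#'   radicals and components) and `truth` (named logical vector of
#'   ground-truth phono-semantic flags).
#' @export
generateCharDB <- function(cfg) {
  stopifnot(is(cfg, "SyntheticConfig"))
  set.seed(cfg@seed)
  initials <- .PY_INITIALS
  radSym <- vapply(seq_len(cfg@nRadicals),
                   function(i) intToUtf8(.PUA_RADICAL + i), character(1))
  phoSym <- vapply(seq_len(cfg@nPhoneticPool),
                   function(i) intToUtf8(.PUA_PHONETIC + i), character(1))
  chSym <- vapply(seq_len(cfg@nChars),
                  function(i) intToUtf8(.PUA_CHAR + i), character(1))

  radFinal <- sample(cfg@finalsPool, cfg@nRadicals, replace = TRUE)
  phoFinal <- sample(cfg@finalsPool, cfg@nPhoneticPool, replace = TRUE)
  radRead <- vapply(radFinal, .syntheticReading, character(1),
                    initials = initials)
  phoRead <- vapply(phoFinal, .syntheticReading, character(1),
                    initials = initials)

  radIdx <- sample.int(cfg@nRadicals, cfg@nChars, replace = TRUE)
  phoIdx <- sample.int(cfg@nPhoneticPool, cfg@nChars, replace = TRUE)
  flags <- runif(cfg@nChars) < cfg@phonoFraction
  chFinal <- character(cfg@nChars)
  for (i in seq_len(cfg@nChars)) {
    if (flags[i]) {
      chFinal[i] <- phoFinal[phoIdx[i]]
    } else {
      avoid <- c(phoFinal[phoIdx[i]], radFinal[radIdx[i]])
      chFinal[i] <- sample(setdiff(cfg@finalsPool, avoid), 1L)
    }
  }
  chRead <- vapply(chFinal, .syntheticReading, character(1),
                   initials = initials)

  rec <- rbind(
    data.frame(char = chSym, radical = radSym[radIdx], readings = chRead,
               ids = paste0("⿰", radSym[radIdx], phoSym[phoIdx]),
               stringsAsFactors = FALSE),
    data.frame(char = radSym, radical = radSym, readings = radRead,
               ids = radSym, stringsAsFactors = FALSE),
    data.frame(char = phoSym, radical = phoSym, readings = phoRead,
               ids = phoSym, stringsAsFactors = FALSE))
  list(db = .newCharDB(rec), truth = setNames(flags, chSym))
}

#' Generate an annotated synthetic corpus
#'
#' Sentences of background characters with inserted entity spans (valid
#' BIO). Entity characters of type t are drawn, with probability
#' `alpha/(alpha+1)`, from the characters whose primary radical belongs
#' to t's radical group (and uniformly otherwise); background characters
#' favour the background radical group the same way. Character choice
#' within a pool is Zipf-weighted, so the inventory has the long tail of
#' frequencies real text has. Byte-identical for a fixed config.
#'
#' @param cfg a [SyntheticConfig-class].
#' @param db the [CharacterDB-class] from [generateCharDB()] (pass
#'   `generateCharDB(cfg)$db`).
#' @return list of tagged sentences.
#' @export
generateCorpus <- function(cfg, db) {
  stopifnot(is(cfg, "SyntheticConfig"), is(db, "CharacterDB"))
  set.seed(cfg@seed + 1L)
  rec <- db@records
  cp <- vapply(rec$char, function(x) utf8ToInt(x)[1], integer(1))
  isChar <- cp >= .PUA_CHAR
  chars <- rec$char[isChar]
  radIdx <- vapply(rec$radical[isChar],
                   function(x) utf8ToInt(x)[1] - .PUA_RADICAL, integer(1))
  ntypes <- length(cfg@entityTypes)
  grp <- .radGroups(cfg@nRadicals, ntypes)[radIdx]
  # character frequency is a property of the inventory, not of one sample:
  # rank by inventory position so every corpus shares one Zipf distribution
  zipf <- 1 / seq_along(chars)

  drawChars <- function(k, group) {
    affine <- runif(k) < cfg@alpha / (cfg@alpha + 1)
    out <- character(k)
    inG <- which(grp == group)
    if (length(inG) == 0L) affine[] <- FALSE
    nA <- sum(affine)
    if (nA > 0L)
      out[affine] <- sample(chars[inG], nA, replace = TRUE,
                            prob = zipf[inG])
    if (k - nA > 0L)
      out[!affine] <- sample(chars, k - nA, replace = TRUE, prob = zipf)
    out
  }

  corpus <- vector("list", cfg@nSentences)
  for (s in seq_len(cfg@nSentences)) {
    L <- max(3L, rpois(1L, cfg@meanLen))
    m <- rpois(1L, cfg@entityDensity)
    lens <- if (m > 0L) sample(1:4, m, replace = TRUE) else integer(0)
    # entities are separated by at least one background character, so the
    # gold span boundaries remain a function of the observable sequence
    while (length(lens) > 0L &&
           (sum(lens) > L || length(lens) > L - sum(lens) + 1L))
      lens <- lens[-length(lens)]
    m <- length(lens)
    nbg <- L - sum(lens)
    gaps <- if (m > 0L) sort(sample.int(nbg + 1L, m)) else integer(0)
    chs <- character(0); tags <- character(0)
    for (slot in seq_len(nbg + 1L)) {
      j <- match(slot, gaps)
      if (!is.na(j)) {
        t <- sample.int(ntypes, 1L)
        chs <- c(chs, drawChars(lens[j], t))
        tags <- c(tags, c(paste0("B-", cfg@entityTypes[t]),
                          rep(paste0("I-", cfg@entityTypes[t]),
                              lens[j] - 1L)))
      }
      if (slot <= nbg) {
        chs <- c(chs, drawChars(1L, ntypes + 1L))
        tags <- c(tags, "O")
      }
    }
    corpus[[s]] <- list(chars = chs, tags = tags)
  }
  corpus
}

#' Shuffle the feature assignments of a character database
#'
#' Control condition for learnability experiments: the primary-radical
#' and reading assignments of the composed characters are permuted
#' (independently) across those characters, destroying any correlation
#' between a character's features and its entity behaviour while keeping
#' the marginal feature distributions intact.
#'
#' @param db a [CharacterDB-class].
#' @param seed permutation seed.
#' @return a new [CharacterDB-class].
#' @export
shuffleFeatures <- function(db, seed = 1L) {
  stopifnot(is(db, "CharacterDB"))
  set.seed(seed)
  rec <- db@records
  composed <- which(rec$ids != rec$char)
  if (length(composed) > 1L) {
    rec$radical[composed] <- rec$radical[composed][sample(length(composed))]
    rec$readings[composed] <- rec$readings[composed][sample(length(composed))]
  }
  .newCharDB(rec, log = db@log)
}
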