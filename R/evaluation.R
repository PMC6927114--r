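## Entity-level scoring, cross-validation, phono-semantic sectioning and
## radical-occurrence statistics.

#' Extract entity mentions from a tagged sentence
#'
#' Mentions are maximal runs `B-X (I-X)*`. In strict mode (default) an
#' `I-X` that does not continue a mention of the same type starts no
#' entity and is dropped; with `lenient = TRUE` such a dangling `I-X` is
#' repaired to a `B-X`.
#'
#' @param sentence a tagged sentence `list(chars=, tags=)`, or a tag
#'   vector.
#' @param lenient repair dangling `I-X` instead of dropping it.
#' @return data.frame with columns `type`, `start`, `end` (0-based,
#'   end-exclusive character offsets).
#' @export
extractEntities <- function(sentence, lenient = FALSE) {
  tags <- if (is.list(sentence)) sentence$tags else sentence
  bad <- !grepl("^(O|[BI]-[A-Za-z]+)$", tags)
  if (any(bad)) stop("extractEntities: unknown tag '", tags[bad][1], "'")
  type <- character(0); start <- integer(0); end <- integer(0)
  curType <- NA_character_; curStart <- NA_integer_
  close <- function(i) {
    if (!is.na(curType)) {
      type <<- c(type, curType); start <<- c(start, curStart)
      end <<- c(end, i)
    }
    curType <<- NA_character_
  }
  for (i in seq_along(tags)) {
    tg <- tags[i]
    if (tg == "O") { close(i - 1L); next }
    pre <- substr(tg, 1, 1); ty <- substring(tg, 3)
    if (pre == "B") {
      close(i - 1L); curType <- ty; curStart <- i - 1L
    } else if (!is.na(curType) && curType == ty) {
      # continues current mention
    } else {
      close(i - 1L)
      if (lenient) { curType <- ty; curStart <- i - 1L }
    }
  }
  close(length(tags))
  data.frame(type = type, start = start, end = end, stringsAsFactors = FALSE)
}

.prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f = f)
}

#' Entity-level precision/recall/F over aligned corpora
#'
#' Exact-match scoring: a predicted mention is a true positive iff a gold
#' mention with the same type, start and end exists in the same sentence.
#' Reports per-type and micro-averaged (`ALL`) metrics: the `ALL` row
#' pools counts over all mentions rather than averaging the type rows.
#'
#' @param gold,pred corpora of tagged sentences, aligned and of equal
#'   sentence lengths.
#' @param lenient passed to [extractEntities()].
#' @return a [PRFReport-class].
#' @export
scoreEntities <- function(gold, pred, lenient = FALSE) {
  if (length(gold) != length(pred))
    stop("scoreEntities: corpora differ in size")
  types <- character(0)
  counts <- new.env(parent = emptyenv())
  bump <- function(ty, slot) {
    key <- paste0(ty, ".", slot)
    assign(key, (if (exists(key, counts)) get(key, counts) else 0) + 1, counts)
  }
  for (i in seq_along(gold)) {
    if (length(gold[[i]]$chars) != length(pred[[i]]$chars))
      stop("scoreEntities: sentence ", i, " lengths differ")
    g <- extractEntities(gold[[i]], lenient)
    p <- extractEntities(pred[[i]], lenient)
    types <- union(types, union(g$type, p$type))
    gk <- paste(g$type, g$start, g$end)
    pk <- paste(p$type, p$start, p$end)
    for (j in seq_len(nrow(p))) bump(p$type[j], if (pk[j] %in% gk) "tp" else "fp")
    for (j in seq_len(nrow(g))) if (!(gk[j] %in% pk)) bump(g$type[j], "fn")
  }
  get0 <- function(ty, slot) {
    key <- paste0(ty, ".", slot)
    if (exists(key, counts)) get(key, counts) else 0
  }
  types <- sort(types)
  rows <- lapply(c(types, "ALL"), function(ty) {
    if (ty == "ALL") {
      tp <- sum(vapply(types, get0, numeric(1), "tp"))
      fp <- sum(vapply(types, get0, numeric(1), "fp"))
      fn <- sum(vapply(types, get0, numeric(1), "fn"))
    } else {
      tp <- get0(ty, "tp"); fp <- get0(ty, "fp"); fn <- get0(ty, "fn")
    }
    m <- .prf(tp, fp, fn)
    data.frame(type = ty, tp = tp, fp = fp, fn = fn,
               precision = m["precision"], recall = m["recall"], f = m["f"],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  new("PRFReport", table = do.call(rbind, rows))
}

#' Overall (micro) F of a report
#' @param report a [PRFReport-class].
#' @return a number.
#' @export
overallF <- function(report) {
  stopifnot(is(report, "PRFReport"))
  report@table$f[report@table$type == "ALL"]
}

setMethod("show", "PRFReport", function(object) {
  cat("Entity-level PRF (exact match, micro-averaged ALL):\n")
  print(object@table, row.names = FALSE, digits = 4)
})

#' Seeded k-fold partition
#'
#' Shuffles `1:n` with the seed and cuts it into `k` near-equal folds
#' (sizes differing by at most 1).
#'
#' @param n number of items.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return list of integer index vectors partitioning `1:n`.
#' @export
cvFolds <- function(n, k = 5L, seed = 1L) {
  if (k < 2L) stop("cvFolds: k must be at least 2")
  if (n < k) stop("cvFolds: fewer items than folds")
  set.seed(seed)
  idx <- sample.int(n)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  unname(split(idx, rep(seq_len(k), times = sizes)))
}

#' k-fold cross-validation of a tagging pipeline
#'
#' Each fold serves once as the test set; `trainFun(trainCorpus)` fits a
#' model and `predictFun(model, sentences)` tags the held-out sentences.
#' Fold metrics are averaged arithmetically.
#'
#' @param corpus list of tagged sentences.
#' @param k folds (default 5).
#' @param seed RNG seed for the fold shuffle.
#' @param trainFun function(corpus) -> model.
#' @param predictFun function(model, sentences) -> tagged sentences;
#'   defaults to [tagSentences()].
#' @return list with `folds` (index vectors), `reports` (per-fold
#'   [PRFReport-class]), `foldF` (per-fold overall F) and `meanF`.
#' @export
crossValidate <- function(corpus, k = 5L, seed = 1L, trainFun,
                          predictFun = tagSentences) {
  folds <- cvFolds(length(corpus), k, seed)
  reports <- vector("list", k)
  for (i in seq_len(k)) {
    test <- corpus[folds[[i]]]
    train <- corpus[-folds[[i]]]
    model <- trainFun(train)
    pred <- predictFun(model, test)
    reports[[i]] <- scoreEntities(test, pred)
  }
  foldF <- vapply(reports, overallF, numeric(1))
  list(folds = folds, reports = reports, foldF = foldF, meanF = mean(foldF))
}

#' Split documents at the median phono-semantic percentage
#'
#' Computes the token-level phono-semantic percentage of every document
#' and the median over documents (even counts: mean of the middle two);
#' documents strictly above the median form section A, the rest —
#' including ties — section B.
#'
#' @param db a [CharacterDB-class].
#' @param documents list of texts (strings or symbol vectors), each with
#'   at least one character present in the database.
#' @param maxDepth passed to [phonoSemanticCheck()].
#' @return a [SectionSplit-class].
#' @export
sectionByPhonoSemantic <- function(db, documents, maxDepth = 3L) {
  if (length(documents) < 2L)
    stop("sectionByPhonoSemantic: need at least 2 documents")
  pct <- vapply(documents, function(d)
    phonoSemanticPercentage(db, d, unique = FALSE, maxDepth = maxDepth),
    numeric(1))
  med <- stats::median(pct)
  a <- which(pct > med)
  new("SectionSplit", sectionA = as.integer(a),
      sectionB = as.integer(setdiff(seq_along(pct), a)),
      median = med, percentages = unname(pct))
}

setMethod("show", "SectionSplit", function(object) {
  cat(sprintf("SectionSplit: median %.2f%%; A = %d docs, B = %d docs\n",
              object@median, length(object@sectionA), length(object@sectionB)))
})

#' Primary-radical occurrence statistics
#'
#' For `scope = "entities"`: over the characters inside mentions of each
#' entity type, the percentage of each primary radical, ranked
#' descending; for `scope = "overall"`: the same over all characters of
#' the corpus. Characters with no known radical are excluded.
#'
#' @param db a [CharacterDB-class].
#' @param corpus list of tagged sentences.
#' @param scope `"entities"` or `"overall"`.
#' @param top keep the top-k radicals per column (default 5).
#' @return data.frame with columns `scope`, `radical`, `pct`, `rank`.
#' @export
radicalOccurrence <- function(db, corpus, scope = c("entities", "overall"),
                              top = 5L) {
  scope <- match.arg(scope)
  radOf <- function(chars) {
    r <- viewTokens(db, chars, "radical")
    r[!is.na(r)]
  }
  rankTab <- function(chars, label) {
    rads <- radOf(chars)
    if (length(rads) == 0L) return(NULL)
    tab <- sort(table(rads), decreasing = TRUE)
    n <- min(top, length(tab))
    data.frame(scope = label, radical = names(tab)[seq_len(n)],
               pct = 100 * as.numeric(tab[seq_len(n)]) / length(rads),
               rank = seq_len(n), stringsAsFactors = FALSE)
  }
  if (scope == "overall") {
    allChars <- unlist(lapply(corpus, `[[`, "chars"), use.names = FALSE)
    return(rankTab(allChars, "overall"))
  }
  byType <- new.env(parent = emptyenv())
  for (s in corpus) {
    ents <- extractEntities(s)
    for (j in seq_len(nrow(ents))) {
      ty <- ents$type[j]
      chs <- s$chars[(ents$start[j] + 1L):ents$end[j]]
      assign(ty, c(if (exists(ty, byType)) get(ty, byType) else character(0),
                   chs), byType)
    }
  }
  out <- lapply(sort(ls(byType)), function(ty) rankTab(get(ty, byType), ty))
  do.call(rbind, out)
}
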