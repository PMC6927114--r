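## Ideographic Description Sequences and the phono-semantic check.

.IDC_TERNARY <- c(0x2FF2L, 0x2FF3L)

.idcArity <- function(ch) {
  cp <- utf8ToInt(ch)[1]
  if (cp < .IDC_RANGE[1] || cp > .IDC_RANGE[2]) return(0L)
  if (cp %in% .IDC_TERNARY) 3L else 2L
}

#' Parse an Ideographic Description Sequence
#'
#' An IDS is a prefix-notation string: each IDC operator (U+2FF0..U+2FFB)
#' is followed by its 2 (or, for U+2FF2/U+2FF3, 3) component
#' subexpressions, each itself an IDS; a bare symbol is a leaf. The parse
#' is a recursive-descent over Unicode scalars; serializing the tree with
#' [idsToString()] reproduces the input exactly.
#'
#' @param ids non-empty IDS string.
#' @return a nested list of class `IDSTree` with fields `op` (IDC symbol
#'   or `NA` for a leaf), `children` (list of subtrees) and `leaf`
#'   (component symbol for leaves).
#' @examples
#' t <- parseIDS("⿸疒丙")
#' idsLeaves(t)    # "疒" "丙"
#' @export
parseIDS <- function(ids) {
  if (!is.character(ids) || length(ids) != 1L || is.na(ids) || !nzchar(ids))
    stop("parseIDS: need a non-empty string")
  chars <- strsplit(ids, "")[[1]]
  pos <- 1L
  descend <- function() {
    if (pos > length(chars))
      stop("parseIDS: truncated IDS at position ", pos)
    ch <- chars[pos]
    pos <<- pos + 1L
    ar <- .idcArity(ch)
    if (ar == 0L)
      return(structure(list(op = NA_character_, children = list(), leaf = ch),
                       class = "IDSTree"))
    kids <- vector("list", ar)
    for (k in seq_len(ar)) kids[[k]] <- descend()
    structure(list(op = ch, children = kids, leaf = NA_character_),
              class = "IDSTree")
  }
  tree <- descend()
  if (pos <= length(chars))
    stop("parseIDS: trailing symbols at position ", pos)
  tree
}

#' Serialize an IDS tree back to its prefix string
#' @param tree an `IDSTree` from [parseIDS()].
#' @return the IDS string.
#' @export
idsToString <- function(tree) {
  stopifnot(inherits(tree, "IDSTree"))
  if (is.na(tree$op)) return(tree$leaf)
  paste0(tree$op, paste(vapply(tree$children, idsToString, character(1)),
                        collapse = ""))
}

#' Leaf components of an IDS tree, left to right
#' @param tree an `IDSTree`.
#' @return character vector of component symbols (IDC operators excluded).
#' @export
idsLeaves <- function(tree) {
  stopifnot(inherits(tree, "IDSTree"))
  if (is.na(tree$op)) return(tree$leaf)
  unlist(lapply(tree$children, idsLeaves), use.names = FALSE)
}

#' @export
print.IDSTree <- function(x, ...) {
  cat("IDSTree:", idsToString(x), "\n")
  invisible(x)
}

#' Enumerate all nested components of a character
#'
#' Breadth-first expansion of the character's IDS: the leaves of its own
#' IDS are the depth-1 components; each component known to the database is
#' then expanded through its own IDS, and so on up to `maxDepth`. A
#' component whose IDS equals itself cannot be divided further and
#' terminates the recursion; unknown components are leaves. The character
#' itself is excluded, duplicates are kept once at their minimal depth,
#' and a visited set breaks reference cycles.
#'
#' @param db a [CharacterDB-class].
#' @param char a single symbol.
#' @param maxDepth maximum nesting depth (default 3).
#' @return data.frame with columns `component` and `depth`, in BFS order
#'   (depth, then component order within the IDS).
#' @export
nestedComponents <- function(db, char, maxDepth = 3L) {
  stopifnot(is(db, "CharacterDB"), maxDepth >= 1L)
  if (!.singleSymbol(char)) stop("nestedComponents: need one symbol")
  comp <- character(0); depth <- integer(0)
  seen <- char
  frontier <- char
  d <- 0L
  while (length(frontier) > 0L && d < maxDepth) {
    d <- d + 1L
    nxt <- character(0)
    for (sym in frontier) {
      rec <- charLookup(db, sym)
      if (rec@ids == sym) next                       # atomic: cannot divide
      leaves <- idsLeaves(parseIDS(rec@ids))
      leaves <- leaves[!isIDC(leaves)]
      for (lf in leaves) {
        if (lf %in% seen) next
        seen <- c(seen, lf)
        comp <- c(comp, lf); depth <- c(depth, d)
        nxt <- c(nxt, lf)
      }
    }
    frontier <- nxt
  }
  data.frame(component = comp, depth = depth, stringsAsFactors = FALSE)
}

.finalsOfRecord <- function(rec) {
  outs <- character(0)
  for (r in rec@readings) {
    p <- try(parsePinyin(r), silent = TRUE)
    if (!inherits(p, "try-error")) outs <- c(outs, p@final)
  }
  unique(outs)
}

.negativeVerdict <- function(char, note = "") {
  new("PhonoSemanticVerdict", char = char, isPhonoSemantic = FALSE,
      phoneticRadical = RADICAL_NONE, matchedFinal = "",
      depth = NA_integer_, note = note)
}

#' Phono-semantic check over nested IDS components
#'
#' A character counts as phono-semantic when it shares a pinyin final with
#' one of its forming radicals at any nesting depth: every nested
#' component (from recursively expanded IDS) with a known reading is
#' compared against every reading of the character, and the first match in
#' breadth-first order — minimal depth, ties broken by component order
#' within the IDS — is reported as the phonetic radical. Components
#' without a known reading are skipped for comparison but still expanded,
#' which is how 徒 (tú) is recognised through the 土 (tǔ) nested inside
#' its 走 (zǒu) component at depth 2.
#'
#' @param db a [CharacterDB-class].
#' @param char a single symbol.
#' @param maxDepth maximum component nesting depth (default 3).
#' @return a [PhonoSemanticVerdict-class].
#' @examples
#' db <- readCharDB(system.file("extdata", "biomedical_chars.tsv",
#'                              package = "phonosemNER"))
#' phonoSemanticCheck(db, "病")   # TRUE: 丙 (bǐng) shares final "ing"
#' phonoSemanticCheck(db, "胃")   # FALSE: 田 (tián) does not share "ei"
#' @export
phonoSemanticCheck <- function(db, char, maxDepth = 3L) {
  stopifnot(is(db, "CharacterDB"))
  if (!.singleSymbol(char)) stop("phonoSemanticCheck: need one symbol")
  rec <- charLookup(db, char)
  charFinals <- .finalsOfRecord(rec)
  if (length(charFinals) == 0L)
    return(.negativeVerdict(char, note = "no reading"))
  if (rec@ids == char)
    return(.negativeVerdict(char, note = "atomic"))

  comps <- nestedComponents(db, char, maxDepth = maxDepth)
  for (i in seq_len(nrow(comps))) {
    crec <- charLookup(db, comps$component[i])
    if (!crec@known) next
    compFinals <- .finalsOfRecord(crec)
    hit <- intersect(charFinals, compFinals)
    if (length(hit) > 0L) {
      return(new("PhonoSemanticVerdict", char = char, isPhonoSemantic = TRUE,
                 phoneticRadical = comps$component[i], matchedFinal = hit[1],
                 depth = comps$depth[i], note = ""))
    }
  }
  .negativeVerdict(char)
}

#' Percentage of phono-semantic characters in a text
#'
#' Computes 100 x (phono-semantic tokens / considered tokens). Considered
#' tokens are the symbols present in the database; symbols absent from it
#' (punctuation, Latin letters, digits, rare characters) are excluded from
#' numerator and denominator alike. With `unique = TRUE` the same ratio is
#' computed over the deduplicated character set.
#'
#' @param db a [CharacterDB-class].
#' @param text a single string or a character vector of single symbols.
#' @param unique compute over unique characters instead of token positions.
#' @param maxDepth passed to [phonoSemanticCheck()].
#' @return percentage in `[0, 100]`.
#' @export
phonoSemanticPercentage <- function(db, text, unique = FALSE, maxDepth = 3L) {
  stopifnot(is(db, "CharacterDB"))
  if (length(text) == 1L && nchar(text) > 1L) text <- strsplit(text, "")[[1]]
  text <- text[nzchar(text)]
  considered <- text[text %in% names(db@index)]
  if (unique) considered <- base::unique(considered)
  if (length(considered) == 0L)
    stop("phonoSemanticPercentage: no considered characters in text")
  uniq <- base::unique(considered)
  flags <- vapply(uniq, function(ch)
    phonoSemanticCheck(db, ch, maxDepth = maxDepth)@isPhonoSemantic,
    logical(1))
  100 * mean(flags[match(considered, uniq)])
}

setMethod("show", "PhonoSemanticVerdict", function(object) {
  if (object@isPhonoSemantic) {
    cat(sprintf("'%s' is phono-semantic: phonetic radical '%s' (final '%s', depth %d)\n",
                object@char, object@phoneticRadical, object@matchedFinal,
                object@depth))
  } else {
    cat(sprintf("'%s' is not phono-semantic%s\n", object@char,
                if (nzchar(object@note)) paste0(" (", object@note, ")") else ""))
  }
})
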