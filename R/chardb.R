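## Character knowledge base: char -> primary radical, readings, IDS.

.IDC_RANGE <- c(0x2FF0L, 0x2FFBL)

#' Is a symbol an Ideographic Description Character?
#'
#' IDC operators (U+2FF0..U+2FFB) are structural symbols inside IDS
#' strings; they are never characters of the script and never components.
#'
#' @param ch character vector of single symbols.
#' @return logical vector.
#' @export
isIDC <- function(ch) {
  cp <- vapply(ch, function(x) utf8ToInt(x)[1], integer(1))
  cp >= .IDC_RANGE[1] & cp <= .IDC_RANGE[2]
}

.singleSymbol <- function(x) {
  is.character(x) & !is.na(x) & nchar(x, type = "chars") == 1L
}

.sentinelRecord <- function(ch) {
  new("CharacterRecord", char = ch, radical = RADICAL_NONE,
      readings = character(0), ids = ch, known = FALSE)
}

.newCharDB <- function(records, log = character(0)) {
  rownames(records) <- NULL
  idx <- seq_len(nrow(records))
  names(idx) <- records$char
  new("CharacterDB", records = records, index = idx, log = log)
}

#' Read a character knowledge base from TSV
#'
#' The canonical input is a flattened four-column UTF-8 TSV: `char`,
#' `primary_radical`, `;`-separated pinyin readings (diacritic or
#' trailing-digit tones), and the IDS (equal to `char` for atomic
#' symbols). Lines starting with `#` are comments. When the same character
#' appears twice, the last line wins and a warning is logged.
#'
#' @param path TSV file path.
#' @param strict if TRUE, malformed lines (wrong column count, multi-symbol
#'   char field, unparsable readings, ill-formed IDS) raise an error; the
#'   default skips them and counts them in the load log.
#' @return a [CharacterDB-class].
#' @examples
#' db <- readCharDB(system.file("extdata", "biomedical_chars.tsv",
#'                              package = "phonosemNER"))
#' charLookup(db, "病")
#' @export
readCharDB <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("readCharDB: no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]

  log <- character(0)
  bad <- function(msg) {
    if (strict) stop("readCharDB: ", msg) else log <<- c(log, msg)
  }

  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4L) { bad(sprintf("line %d: expected 4 columns", i)); next }
    if (!.singleSymbol(f[1])) { bad(sprintf("line %d: char field is not one symbol", i)); next }
    if (isIDC(f[1])) { bad(sprintf("line %d: char is an IDC operator", i)); next }
    readings <- strsplit(f[3], ";", fixed = TRUE)[[1]]
    readings <- readings[nzchar(readings)]
    if (length(readings) == 0L) { bad(sprintf("line %d: no readings", i)); next }
    ok <- vapply(readings, function(r)
      !inherits(try(parsePinyin(r), silent = TRUE), "try-error"), logical(1))
    if (!all(ok)) { bad(sprintf("line %d: unparsable reading '%s'",
                                i, readings[!ok][1])); next }
    if (f[4] != f[1]) {
      tr <- try(parseIDS(f[4]), silent = TRUE)
      if (inherits(tr, "try-error")) { bad(sprintf("line %d: bad IDS", i)); next }
    }
    rows[[i]] <- data.frame(char = f[1], radical = f[2], readings = f[3],
                            ids = f[4], stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("readCharDB: no valid records in ", path)
  rec <- do.call(rbind, rows)

  nSkipped <- length(log)
  dup <- duplicated(rec$char, fromLast = TRUE)
  if (any(dup)) {
    log <- c(log, sprintf("duplicate character '%s': last line wins",
                          unique(rec$char[dup])))
    warning("readCharDB: ", sum(dup), " duplicated character(s); last line wins")
    rec <- rec[!dup, , drop = FALSE]
  }
  if (nSkipped > 0L && !strict)
    warning("readCharDB: skipped ", nSkipped, " malformed line(s)")
  .newCharDB(rec, log)
}

#' Write a character knowledge base to TSV
#'
#' Inverse of [readCharDB()]: the written file reloads to an identical DB.
#' @param db a [CharacterDB-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCharDB <- function(db, path) {
  stopifnot(is(db, "CharacterDB"))
  rec <- db@records
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(rec$char, rec$radical, rec$readings, rec$ids, sep = "\t"),
             con, useBytes = FALSE)
  invisible(path)
}

#' Look up one character
#'
#' Total over single non-IDC symbols: unknown characters return a sentinel
#' record (radical [RADICAL_NONE], no readings, self-IDS) so that tagging
#' never fails on rare clinical symbols.
#'
#' @param db a [CharacterDB-class].
#' @param char a single symbol.
#' @return a [CharacterRecord-class].
#' @export
charLookup <- function(db, char) {
  stopifnot(is(db, "CharacterDB"))
  if (!.singleSymbol(char))
    stop("charLookup: input must be exactly one symbol")
  if (isIDC(char))
    stop("charLookup: IDC operators are not characters")
  i <- db@index[char]
  if (is.na(i)) return(.sentinelRecord(char))
  r <- db@records[i, ]
  new("CharacterRecord", char = r$char, radical = r$radical,
      readings = strsplit(r$readings, ";", fixed = TRUE)[[1]],
      ids = r$ids, known = TRUE)
}

#' Characters present in a database
#' @param db a [CharacterDB-class].
#' @return character vector of symbols.
#' @export
dbChars <- function(db) {
  stopifnot(is(db, "CharacterDB"))
  db@records$char
}

#' Canonical (first) reading of a record, parsed
#' @param rec a [CharacterRecord-class].
#' @return a [Pinyin-class], or NULL when the record has no parsable reading.
#' @export
canonicalReading <- function(rec) {
  stopifnot(is(rec, "CharacterRecord"))
  for (r in rec@readings) {
    p <- try(parsePinyin(r), silent = TRUE)
    if (!inherits(p, "try-error")) return(p)
  }
  NULL
}

setMethod("show", "CharacterDB", function(object) {
  cat(sprintf("CharacterDB with %d characters", nrow(object@records)))
  if (length(object@log)) cat(sprintf(" (%d loader notes)", length(object@log)))
  cat("\n")
})

setMethod("show", "CharacterRecord", function(object) {
  cat(sprintf("CharacterRecord '%s': radical=%s readings=[%s] ids=%s%s\n",
              object@char, object@radical,
              paste(object@readings, collapse = ";"), object@ids,
              if (object@known) "" else " (unknown sentinel)"))
})

setMethod("length", "CharacterDB", function(x) nrow(x@records))
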