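## Pinyin segmentation: initial + final + tone.

# Longest-match order: digraphs zh/ch/sh before z/c/s. `y` and `w` are
# treated as initials, so yong segments as y + ong (not re-spelled iong).
.PY_INITIALS <- c("zh", "ch", "sh",
                  "b", "p", "m", "f", "d", "t", "n", "l",
                  "g", "k", "h", "j", "q", "x", "r", "z", "c", "s", "y", "w")

# Standard Mandarin finals plus the surface forms that arise when y/w are
# kept as initials (e.g. "ue" in yue/jue). Residue after initial removal
# must be a member, otherwise the syllable is rejected.
.PY_FINALS <- c("a", "o", "e", "i", "u", "ü", "er",
                "ai", "ei", "ao", "ou", "an", "en", "ang", "eng", "ong",
                "ia", "ie", "iao", "iu", "ian", "in", "iang", "ing", "iong",
                "ua", "uo", "uai", "ui", "uan", "un", "uang", "ueng", "ue",
                "üe", "üan", "ün")

# Precomposed toned vowels -> c(base letter, tone)
.PY_TONED <- local({
  rows <- list(
    a = c("ā", "á", "ǎ", "à"),
    e = c("ē", "é", "ě", "è"),
    i = c("ī", "í", "ǐ", "ì"),
    o = c("ō", "ó", "ǒ", "ò"),
    u = c("ū", "ú", "ǔ", "ù"),
    "ü" = c("ǖ", "ǘ", "ǚ", "ǜ"))
  out <- list()
  for (base in names(rows))
    for (t in 1:4) out[[rows[[base]][t]]] <- list(base = base, tone = t)
  out
})

# Combining tone marks (macron, acute, caron, grave)
.PY_COMBINING <- c("̄" = 1L, "́" = 2L, "̌" = 3L, "̀" = 4L)

#' Inventories used by the pinyin parser
#'
#' `pinyinInitials()` returns the initial inventory (longest-match order,
#' `y`/`w` included); `pinyinFinals()` the closed final inventory.
#' @return character vector.
#' @export
pinyinInitials <- function() .PY_INITIALS

#' @rdname pinyinInitials
#' @export
pinyinFinals <- function() .PY_FINALS

#' Segment a romanized syllable into initial, final and tone
#'
#' Accepts both tone dialects: diacritics (`bìng`) and trailing digits
#' (`bing4`); a trailing `5` maps to the neutral tone 0, and `v` is read
#' as `ü`. The initial is taken by longest match from the initial
#' inventory; the residue must be a member of the closed final inventory,
#' so `bìng` segments as `b` + `ing` with the falling tone, and `yǒng` as
#' `y` + `ong`.
#'
#' @param raw a single non-empty syllable.
#' @return a [Pinyin-class] object.
#' @examples
#' p <- parsePinyin("bìng")   # bìng
#' p@initial; p@final; p@tone      # "b", "ing", 4
#' toneless(p)                     # "bing"
#' @export
parsePinyin <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(trimws(raw)))
    stop("parsePinyin: need one non-empty syllable")
  s <- tolower(trimws(raw))
  chars <- strsplit(s, "", fixed = FALSE)[[1]]

  tone <- NA_integer_
  seen_marks <- 0L
  out <- character(0)
  for (ch in chars) {
    if (!is.null(.PY_TONED[[ch]])) {
      seen_marks <- seen_marks + 1L
      tone <- .PY_TONED[[ch]]$tone
      out <- c(out, .PY_TONED[[ch]]$base)
    } else if (ch %in% names(.PY_COMBINING)) {
      seen_marks <- seen_marks + 1L
      tone <- .PY_COMBINING[[ch]]
    } else if (ch == "ı") {        # dotless i as seen in some exports
      out <- c(out, "i")
    } else if (ch == "v") {
      out <- c(out, "ü")
    } else {
      out <- c(out, ch)
    }
  }
  if (seen_marks > 1L)
    stop("parsePinyin: multiple tone diacritics in '", raw, "'")

  # trailing-digit dialect
  n <- length(out)
  if (n > 0L && out[n] %in% as.character(0:5)) {
    if (seen_marks > 0L)
      stop("parsePinyin: both diacritic and digit tone in '", raw, "'")
    d <- as.integer(out[n])
    tone <- if (d == 5L) 0L else d
    out <- out[-n]
  }
  if (is.na(tone)) tone <- 0L

  toneless_str <- paste(out, collapse = "")
  if (!nzchar(toneless_str))
    stop("parsePinyin: no letters in '", raw, "'")
  if (grepl("[^a-zü]", toneless_str))
    stop("parsePinyin: unexpected symbol in '", raw, "'")

  initial <- ""
  for (ini in .PY_INITIALS) {
    if (startsWith(toneless_str, ini) && nchar(toneless_str) > nchar(ini)) {
      initial <- ini
      break
    }
  }
  final <- substring(toneless_str, nchar(initial) + 1L)
  if (!(final %in% .PY_FINALS))
    stop("parsePinyin: '", raw, "' has no recognised final ('", final, "')")

  new("Pinyin", raw = raw, initial = initial, final = final,
      tone = as.integer(tone))
}

#' Toneless form of a syllable
#'
#' Concatenates initial and final, dropping all tone information; this is
#' the key used by the radical+pinyin (R+P) embedding table.
#'
#' @param p a [Pinyin-class] object or a raw syllable string.
#' @return a string, e.g. `"bing"`.
#' @export
toneless <- function(p) {
  if (is.character(p)) p <- parsePinyin(p)
  stopifnot(is(p, "Pinyin"))
  paste0(p@initial, p@final)
}

#' Final of a syllable
#'
#' Convenience composition of [parsePinyin()] and the `final` slot: the
#' quantity the phono-semantic check compares across nested components.
#'
#' @param x a raw syllable string or a [Pinyin-class] object.
#' @return a string, e.g. `"ong"` for `tòng` and `yǒng` alike.
#' @export
finalOf <- function(x) {
  if (is.character(x)) x <- parsePinyin(x)
  stopifnot(is(x, "Pinyin"))
  x@final
}

setMethod("show", "Pinyin", function(object) {
  cat(sprintf("Pinyin '%s': initial='%s' final='%s' tone=%d\n",
              object@raw, object@initial, object@final, object@tone))
})
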