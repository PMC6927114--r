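## CoNLL-style BIO corpus IO: one "char<TAB>tag" per line, blank line
## between sentences.

#' Read a BIO-annotated corpus
#'
#' @param path UTF-8 file, one `char<TAB>tag` per line, sentences
#'   separated by blank lines.
#' @return list of tagged sentences `list(chars=, tags=)`.
#' @export
readBIO <- function(path) {
  if (!file.exists(path)) stop("readBIO: no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  corpus <- list()
  chars <- character(0); tags <- character(0)
  flush <- function() {
    if (length(chars) > 0L)
      corpus[[length(corpus) + 1L]] <<- list(chars = chars, tags = tags)
    chars <<- character(0); tags <<- character(0)
  }
  for (ln in lines) {
    if (!nzchar(ln)) { flush(); next }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 2L) stop("readBIO: malformed line: '", ln, "'")
    chars <- c(chars, f[1]); tags <- c(tags, f[2])
  }
  flush()
  if (length(corpus) == 0L) stop("readBIO: empty corpus in ", path)
  corpus
}

#' Write a BIO-annotated corpus
#'
#' Inverse of [readBIO()]; a write/read round trip is byte-identical.
#' @param corpus list of tagged sentences.
#' @param path output path.
#' @export
writeBIO <- function(corpus, path) {
  blocks <- vapply(corpus, function(s)
    paste(paste(s$chars, s$tags, sep = "\t"), collapse = "\n"),
    character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(blocks, collapse = "\n\n"), con)
  invisible(path)
}
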