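## Embedding tables, word2vec-format IO, skip-gram pretraining, and the
## composition layer that merges the radical view with a second feature view.

#' Construct an embedding table
#'
#' @param vectors numeric matrix with one row per token; rownames are the
#'   tokens.
#' @param unk vector used for out-of-vocabulary tokens; defaults to the
#'   column means of `vectors`.
#' @return an [EmbeddingTable-class].
#' @export
embeddingTable <- function(vectors, unk = colMeans(vectors)) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  new("EmbeddingTable", dim = ncol(vectors), vectors = vectors,
      unk = as.numeric(unk))
}

#' Look up a token's vector, with UNK fallback
#'
#' @param table an [EmbeddingTable-class].
#' @param token a token string, or `NA` for an explicit UNK.
#' @return numeric vector of length `table@dim`.
#' @export
embLookup <- function(table, token) {
  stopifnot(is(table, "EmbeddingTable"))
  if (is.na(token) || !(token %in% rownames(table@vectors))) return(table@unk)
  as.numeric(table@vectors[token, ])
}

#' Tokens of an embedding table
#' @param table an [EmbeddingTable-class].
#' @return character vector.
#' @export
embTokens <- function(table) rownames(table@vectors)

setMethod("show", "EmbeddingTable", function(object) {
  cat(sprintf("EmbeddingTable: %d tokens x %d dims\n",
              nrow(object@vectors), object@dim))
})

#' Read / write embedding tables in word2vec text format
#'
#' The format is a header line `<vocab_size> <dim>` followed by one line
#' per token, `<token> <v1> ... <vdim>`, UTF-8. Values are written with
#' 17 significant digits so a write/read round trip reproduces every
#' double exactly. A token equal to `<unk>` is interpreted as the UNK
#' vector on read and written out for the UNK vector.
#'
#' @param path file path.
#' @return [readWord2vec()] returns an [EmbeddingTable-class];
#'   [writeWord2vec()] returns `path` invisibly.
#' @export
readWord2vec <- function(path) {
  if (!file.exists(path)) stop("readWord2vec: no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), " +")[[1]])
  if (length(hdr) != 2L || any(is.na(hdr)))
    stop("readWord2vec: malformed header")
  nv <- hdr[1]; d <- hdr[2]
  body <- lines[1 + seq_len(nv)]
  parts <- strsplit(body, " ", fixed = TRUE)
  toks <- vapply(parts, `[[`, character(1), 1)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  rownames(mat) <- toks
  if (UNK_TOKEN %in% toks) {
    unk <- mat[UNK_TOKEN, ]
    mat <- mat[toks != UNK_TOKEN, , drop = FALSE]
    embeddingTable(mat, unk = unk)
  } else {
    embeddingTable(mat)
  }
}

#' @rdname readWord2vec
#' @param table an [EmbeddingTable-class].
#' @export
writeWord2vec <- function(table, path) {
  stopifnot(is(table, "EmbeddingTable"))
  m <- rbind(table@vectors, matrix(table@unk, nrow = 1,
                                   dimnames = list(UNK_TOKEN, NULL)))
  fmt <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  lines <- c(paste(nrow(m), ncol(m)),
             paste(rownames(m), apply(m, 1, fmt)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Map a character to its view token
#'
#' The four views used in pretraining and tagging: the character itself,
#' its primary radical, the toneless canonical reading, or the final of
#' the canonical reading. Unknown characters (or characters without a
#' parsable reading, for the pinyin-derived views) map to `NA`, which
#' downstream lookups resolve to the UNK vector.
#'
#' @param db a [CharacterDB-class].
#' @param chars character vector of single symbols.
#' @param view one of `"char"`, `"radical"`, `"pinyin"`, `"final"`.
#' @return character vector of tokens, `NA` where undefined.
#' @export
viewTokens <- function(db, chars, view = c("char", "radical", "pinyin", "final")) {
  view <- match.arg(view)
  if (view == "char") return(ifelse(chars %in% names(db@index), chars, NA))
  vapply(chars, function(ch) {
    rec <- charLookup(db, ch)
    if (!rec@known) return(NA_character_)
    if (view == "radical")
      return(if (rec@radical == RADICAL_NONE) NA_character_ else rec@radical)
    p <- canonicalReading(rec)
    if (is.null(p)) return(NA_character_)
    if (view == "pinyin") toneless(p) else p@final
  }, character(1), USE.NAMES = FALSE)
}

#' Pretrain an embedding table by skip-gram with negative sampling
#'
#' Each corpus position is first mapped to its view token (the character,
#' its primary radical, its toneless canonical pinyin, or its final), so
#' the radical/pinyin/final streams stay aligned with the character
#' stream; skip-gram with negative sampling is then trained over the
#' token stream. The UNK vector of the returned table is the mean of all
#' trained vectors.
#'
#' @param corpus list of sentences; each either a character vector of
#'   symbols or a list with a `chars` element.
#' @param view one of `"char"`, `"radical"`, `"pinyin"`, `"final"`.
#' @param db a [CharacterDB-class] resolving the view mapping.
#' @param dim embedding dimensionality (default 50).
#' @param window context window half-width (default 2).
#' @param epochs training passes (default 5).
#' @param seed RNG seed; fixed seed gives a bit-identical table.
#' @param negative negative samples per pair (default 5).
#' @param lr initial learning rate (default 0.025).
#' @return an [EmbeddingTable-class].
#' @export
pretrainEmbeddings <- function(corpus, view, db, dim = 50L, window = 2L,
                               epochs = 5L, seed = 1L, negative = 5L,
                               lr = 0.025) {
  stopifnot(length(corpus) > 0L)
  sent_chars <- lapply(corpus, function(s) if (is.list(s)) s$chars else s)
  streams <- lapply(sent_chars, viewTokens, db = db, view = view)
  vocab <- sort(unique(stats::na.omit(unlist(streams))))
  if (length(vocab) == 0L)
    stop("pretrainEmbeddings: view token stream is entirely unknown")
  ids <- lapply(streams, function(s) {
    i <- match(s, vocab) - 1L
    i[is.na(i)] <- -1L          # skipped by the trainer
    as.integer(i)
  })
  m <- cpp_sgns(ids, length(vocab), as.integer(dim), as.integer(window),
                as.integer(epochs), lr, as.integer(negative),
                as.integer(seed))
  rownames(m) <- vocab
  embeddingTable(m)
}

#' Composition layer parameters
#'
#' With `trainable = TRUE` (the default), `LW` and `RW` start at the
#' identity (zero-padded when rectangular) and `b` at zero, and all three
#' are updated jointly with the tagger. With `trainable = FALSE` the layer
#' is the fixed Sum variant: `LW = RW = I`, `b = 0`, so composition is
#' plain vector addition and the dims must agree.
#'
#' @param outDim output (composed) dimension.
#' @param leftDim,rightDim input dims (default `outDim`).
#' @param trainable FALSE for the Sum variant.
#' @return a [CompositionParams-class].
#' @export
compositionParams <- function(outDim, leftDim = outDim, rightDim = outDim,
                              trainable = TRUE) {
  eye <- function(nr, nc) {
    m <- matrix(0, nr, nc); diag(m) <- 1; m
  }
  if (!trainable && (leftDim != outDim || rightDim != outDim))
    stop("compositionParams: Sum variant requires equal dims")
  new("CompositionParams", LW = eye(outDim, leftDim), RW = eye(outDim, rightDim),
      b = numeric(outDim), trainable = trainable)
}

#' Compose two feature embeddings
#'
#' The linear composition `LW %*% left + RW %*% right + b`. For the Sum
#' variant this reduces to `left + right` exactly.
#'
#' @param params a [CompositionParams-class].
#' @param left,right numeric vectors of the dims the params expect.
#' @return numeric vector of the output dimension.
#' @export
compose <- function(params, left, right) {
  stopifnot(is(params, "CompositionParams"))
  if (length(left) != ncol(params@LW) || length(right) != ncol(params@RW))
    stop("compose: shape mismatch")
  if (!params@trainable) return(left + right)
  as.numeric(params@LW %*% left + params@RW %*% right + params@b)
}

#' Build a feature model
#'
#' Binds the radical table (left), the mode-keyed table (right), the
#' composition parameters and the character database into one of the
#' three feature models: radical+character (`R+C`), radical+pinyin
#' (`R+P`) or radical+final (`R+F`).
#'
#' @param mode `"R+C"`, `"R+P"` or `"R+F"`.
#' @param db a [CharacterDB-class].
#' @param left radical [EmbeddingTable-class].
#' @param right mode-keyed [EmbeddingTable-class].
#' @param params optional [CompositionParams-class]; defaults to a
#'   trainable layer with output dim = `left@dim`.
#' @param sum build the fixed Sum variant instead.
#' @return a [FeatureModel-class].
#' @export
featureModel <- function(mode, db, left, right, params = NULL, sum = FALSE) {
  if (is.null(params))
    params <- compositionParams(left@dim, left@dim, right@dim,
                                trainable = !sum)
  new("FeatureModel", mode = mode, left = left, right = right,
      params = params, db = db)
}

.rightView <- function(mode) switch(mode, "R+C" = "char", "R+P" = "pinyin",
                                    "R+F" = "final")

#' Right-table keys for a character sequence under a model's mode
#' @param model a [FeatureModel-class].
#' @param chars character vector of symbols.
#' @return character vector of tokens (`NA` = UNK).
#' @export
rightKeys <- function(model, chars) {
  stopifnot(is(model, "FeatureModel"))
  viewTokens(model@db, chars, .rightView(model@mode))
}

#' Embed a sentence position-wise
#'
#' For every character: the left input is the radical embedding of its
#' primary radical (UNK for unknown characters) and the right input is
#' the mode-keyed embedding (UNK when the key is missing or the character
#' has no reading); the outputs are their composition. Purely
#' position-wise: permuting the characters permutes the columns.
#'
#' @param model a [FeatureModel-class].
#' @param chars non-empty character vector of symbols.
#' @return numeric matrix, one column per position.
#' @export
embedSentence <- function(model, chars) {
  stopifnot(is(model, "FeatureModel"), length(chars) > 0L)
  lk <- viewTokens(model@db, chars, "radical")
  rk <- rightKeys(model, chars)
  out <- vapply(seq_along(chars), function(i)
    compose(model@params, embLookup(model@left, lk[i]),
            embLookup(model@right, rk[i])),
    numeric(nrow(model@params@LW)))
  matrix(out, nrow = nrow(model@params@LW), ncol = length(chars))
}

setMethod("show", "FeatureModel", function(object) {
  cat(sprintf("FeatureModel %s: left %d tokens/%dd, right %d tokens/%dd, %s composition\n",
              object@mode, nrow(object@left@vectors), object@left@dim,
              nrow(object@right@vectors), object@right@dim,
              if (object@params@trainable) "trainable" else "fixed Sum"))
})
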