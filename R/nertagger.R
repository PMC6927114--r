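## Character-based Bi-LSTM-CRF tagger: tag set, CRF primitives, training.

.BIO_PENALTY <- -1e4

#' Build the BIO tag set
#'
#' `O` plus `B-`/`I-` tags for each entity type (11 tags for the default
#' five clinical types), with virtual START/STOP states and the
#' allowed-transition matrix: `I-X` only after `B-X` or `I-X`, and never
#' directly after START.
#'
#' @param types entity types (default `BOD, SYM, DIS, EXP, TRE`).
#' @return a [TagSet-class].
#' @export
tagSet <- function(types = c("BOD", "SYM", "DIS", "EXP", "TRE")) {
  tags <- c("O", as.vector(rbind(paste0("B-", types), paste0("I-", types))))
  T <- length(tags)
  start <- T + 1L; stop <- T + 2L
  allowed <- matrix(TRUE, T + 2L, T + 2L,
                    dimnames = list(c(tags, "START", "STOP"),
                                    c(tags, "START", "STOP")))
  for (ty in types) {
    into <- paste0("I-", ty)
    ok <- c(paste0("B-", ty), into)
    allowed[, into] <- rownames(allowed) %in% ok
  }
  allowed[, "START"] <- FALSE
  allowed["STOP", ] <- FALSE
  allowed["START", "STOP"] <- TRUE
  new("TagSet", tags = tags, types = types, allowed = allowed,
      start = start, stop = stop)
}

setMethod("show", "TagSet", function(object) {
  cat(sprintf("TagSet: %d tags over types %s\n", length(object@tags),
              paste(object@types, collapse = "/")))
})

#' Is a tag sequence BIO-valid?
#'
#' @param tags character vector of tags.
#' @param tagset a [TagSet-class].
#' @return TRUE/FALSE.
#' @export
validBIO <- function(tags, tagset = tagSet()) {
  if (length(tags) == 0L || !all(tags %in% tagset@tags)) return(FALSE)
  ids <- match(tags, tagset@tags)
  path <- c(tagset@start, ids, tagset@stop)
  all(tagset@allowed[cbind(path[-length(path)], path[-1])])
}

.effTrans <- function(trans, allowed, penalty = .BIO_PENALTY) {
  trans + penalty * !allowed
}

#' Linear-chain CRF primitives over raw scores
#'
#' These operate on an emission matrix (tags x positions) and a
#' transition matrix over tags + START/STOP, independent of any encoder:
#' `crfScore` is the path score (emissions plus transitions including
#' START/STOP), `crfLogPartition` the log-sum-exp over all tag paths via
#' the forward recursion in log space (disallowed transitions enter at a
#' large negative penalty), and `crfViterbi` the argmax path under hard
#' transition constraints, ties broken toward the lowest tag index.
#'
#' @param emissions numeric matrix, `length(tagset@tags)` rows, one column
#'   per position.
#' @param trans numeric (|tags|+2)^2 transition matrix.
#' @param tagIds integer path (1-based tag indices) for `crfScore`.
#' @param tagset a [TagSet-class].
#' @param penalty additive score for disallowed transitions in the soft
#'   normalizer (default -1e4).
#' @return `crfScore`/`crfLogPartition`: a number; `crfViterbi`: integer
#'   vector of 1-based tag indices.
#' @export
crfScore <- function(emissions, trans, tagIds, tagset = tagSet(),
                     penalty = .BIO_PENALTY) {
  eff <- .effTrans(trans, tagset@allowed, penalty)
  n <- ncol(emissions)
  stopifnot(length(tagIds) == n)
  path <- c(tagset@start, tagIds, tagset@stop)
  sum(emissions[cbind(tagIds, seq_len(n))]) +
    sum(eff[cbind(path[-length(path)], path[-1])])
}

#' @rdname crfScore
#' @export
crfLogPartition <- function(emissions, trans, tagset = tagSet(),
                            penalty = .BIO_PENALTY) {
  eff <- .effTrans(trans, tagset@allowed, penalty)
  T <- nrow(emissions); n <- ncol(emissions)
  lse <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }
  alpha <- eff[tagset@start, seq_len(T)] + emissions[, 1]
  if (n > 1L) for (t in 2:n) {
    alpha <- vapply(seq_len(T), function(j)
      lse(alpha + eff[seq_len(T), j]), numeric(1)) + emissions[, t]
  }
  lse(alpha + eff[seq_len(T), tagset@stop])
}

#' @rdname crfScore
#' @export
crfViterbi <- function(emissions, trans, tagset = tagSet()) {
  T <- nrow(emissions); n <- ncol(emissions)
  eff <- trans
  eff[!tagset@allowed] <- -Inf
  delta <- eff[tagset@start, seq_len(T)] + emissions[, 1]
  psi <- matrix(0L, T, n)
  if (n > 1L) for (t in 2:n) {
    nd <- numeric(T)
    for (j in seq_len(T)) {
      sc <- delta + eff[seq_len(T), j]
      psi[j, t] <- which.max(sc)       # first max = lowest tag index
      nd[j] <- sc[psi[j, t]]
    }
    delta <- nd + emissions[, t]
  }
  fin <- delta + eff[seq_len(T), tagset@stop]
  path <- integer(n)
  path[n] <- which.max(fin)
  if (n > 1L) for (t in n:2) path[t - 1L] <- psi[path[t], t]
  path
}

## Tagger construction -----------------------------------------------------

#' Construct an (untrained) Bi-LSTM-CRF tagger
#'
#' Initializes all numeric parameters: the embedding tables are copied
#' from the feature model (plus an UNK column), the composition layer
#' starts at the feature model's `LW`/`RW`/`b`, LSTM and projection
#' weights are drawn uniformly in +/- 1/sqrt(hidden) (forget-gate bias 1),
#' and CRF transitions start at zero. Fully determined by `seed`.
#'
#' @param model a [FeatureModel-class].
#' @param tagset a [TagSet-class].
#' @param hidden LSTM hidden size per direction (default 100).
#' @param seed RNG seed for initialization.
#' @return a [CRFTagger-class].
#' @export
crfTagger <- function(model, tagset = tagSet(), hidden = 100L, seed = 1L) {
  stopifnot(is(model, "FeatureModel"))
  set.seed(seed)
  H <- as.integer(hidden)
  D <- nrow(model@params@LW)
  T <- length(tagset@tags)
  lv <- embTokens(model@left); rv <- embTokens(model@right)
  Ltab <- cbind(t(model@left@vectors), model@left@unk)
  Rtab <- cbind(t(model@right@vectors), model@right@unk)
  s <- 1 / sqrt(H)
  ru <- function(nr, nc) matrix(runif(nr * nc, -s, s), nr, nc)
  bf <- numeric(4 * H); bf[(H + 1):(2 * H)] <- 1   # forget bias
  params <- list(
    Ltab = Ltab, Rtab = Rtab,
    LW = model@params@LW, RW = model@params@RW, bc = model@params@b,
    Wf = ru(4 * H, D), Uf = ru(4 * H, H), bf = bf,
    Wb = ru(4 * H, D), Ub = ru(4 * H, H), bb = bf,
    Wout = ru(T, 2 * H), bout = numeric(T),
    trans = matrix(0, T + 2L, T + 2L))
  new("CRFTagger", model = model, tagset = tagset, params = params,
      leftVocab = lv, rightVocab = rv,
      config = list(hidden = H, seed = as.integer(seed)),
      trained = FALSE, lossTrace = numeric(0))
}

# 0-based feature ids for the C++ engine; unknown -> the UNK column
.encodeFeatures <- function(tagger, chars) {
  lt <- viewTokens(tagger@model@db, chars, "radical")
  rt <- rightKeys(tagger@model, chars)
  il <- match(lt, tagger@leftVocab) - 1L
  il[is.na(il)] <- length(tagger@leftVocab)
  ir <- match(rt, tagger@rightVocab) - 1L
  ir[is.na(ir)] <- length(tagger@rightVocab)
  list(il = as.integer(il), ir = as.integer(ir))
}

.penMatrix <- function(tagset, penalty = .BIO_PENALTY) {
  penalty * !tagset@allowed
}

#' Per-position emission scores of a sentence
#' @param tagger a [CRFTagger-class].
#' @param chars character vector of symbols.
#' @return numeric matrix, tags x positions.
#' @export
emissionScores <- function(tagger, chars) {
  stopifnot(is(tagger, "CRFTagger"), length(chars) > 0L)
  enc <- .encodeFeatures(tagger, chars)
  E <- cpp_tagger_emissions(tagger@params, enc$il, enc$ir)
  rownames(E) <- tagger@tagset@tags
  E
}

#' Score of one tagged path
#'
#' Sum of per-position emission scores and transition scores over
#' consecutive tags, including the virtual START and STOP transitions.
#'
#' @param tagger a [CRFTagger-class].
#' @param chars character vector of symbols.
#' @param tags tag sequence of equal length.
#' @return a number.
#' @export
sequenceScore <- function(tagger, chars, tags) {
  if (length(chars) != length(tags)) stop("sequenceScore: length mismatch")
  E <- emissionScores(tagger, chars)
  crfScore(E, tagger@params$trans, match(tags, tagger@tagset@tags),
           tagger@tagset)
}

#' Log-partition of a sentence
#'
#' log sum over all tag paths of exp(path score), by the forward
#' recursion in log space; always at least the score of any single path.
#'
#' @inheritParams sequenceScore
#' @return a number.
#' @export
logPartition <- function(tagger, chars) {
  E <- emissionScores(tagger, chars)
  crfLogPartition(E, tagger@params$trans, tagger@tagset)
}

#' Viterbi decoding
#'
#' Highest-scoring BIO-valid tag path (hard transition constraints at
#' decode time), deterministic under ties (lowest tag index).
#'
#' @inheritParams sequenceScore
#' @return a tagged sentence: `list(chars = ..., tags = ...)`.
#' @export
viterbiDecode <- function(tagger, chars) {
  E <- emissionScores(tagger, chars)
  ids <- crfViterbi(E, tagger@params$trans, tagger@tagset)
  list(chars = chars, tags = tagger@tagset@tags[ids])
}

#' Train the tagger
#'
#' Minimizes the mean negative log-likelihood (log-partition minus gold
#' path score) by Adam, jointly over LSTM, projection and transition
#' parameters, the composition layer (unless the model is the fixed Sum
#' variant) and, when `finetune = TRUE`, the embedding tables themselves.
#' The corpus must be BIO-valid; the loss trace is reproducible for a
#' fixed seed.
#'
#' @param tagger a [CRFTagger-class].
#' @param corpus list of tagged sentences (`list(chars=, tags=)`).
#' @param epochs training epochs (default 20).
#' @param lr Adam learning rate (default 1e-3).
#' @param batchSize sentences per gradient step (default 8).
#' @param seed RNG seed for shuffling.
#' @param finetune update the embedding tables during training (default
#'   TRUE; the pretrained tables are a starting point, not frozen).
#' @return the trained [CRFTagger-class] with `lossTrace` filled.
#' @export
trainTagger <- function(tagger, corpus, epochs = 20L, lr = 1e-3,
                        batchSize = 8L, seed = 1L, finetune = TRUE) {
  stopifnot(is(tagger, "CRFTagger"), length(corpus) > 0L)
  for (s in corpus) {
    if (length(s$chars) != length(s$tags) ||
        !validBIO(s$tags, tagger@tagset))
      stop("trainTagger: corpus contains an invalid BIO sentence")
  }
  data <- lapply(corpus, function(s) {
    enc <- .encodeFeatures(tagger, s$chars)
    enc$y <- match(s$tags, tagger@tagset@tags) - 1L
    enc
  })
  res <- cpp_tagger_train(tagger@params, data, .penMatrix(tagger@tagset),
                          as.integer(epochs), lr, as.integer(batchSize),
                          as.integer(seed),
                          updateComp = tagger@model@params@trainable,
                          updateTables = isTRUE(finetune))
  params <- res$params
  for (nm in c("bc", "bf", "bb", "bout")) params[[nm]] <- as.numeric(params[[nm]])
  tagger@params <- params
  tagger@trained <- TRUE
  tagger@lossTrace <- as.numeric(res$trace)
  tagger@config <- utils::modifyList(tagger@config,
    list(epochs = as.integer(epochs), lr = lr,
         batchSize = as.integer(batchSize), trainSeed = as.integer(seed),
         finetune = isTRUE(finetune)))
  tagger
}

#' Tag a list of sentences
#' @param tagger a trained [CRFTagger-class].
#' @param sentences list of character vectors (or tagged sentences, whose
#'   tags are ignored).
#' @return list of tagged sentences.
#' @export
tagSentences <- function(tagger, sentences) {
  lapply(sentences, function(s) {
    chars <- if (is.list(s)) s$chars else s
    viterbiDecode(tagger, chars)
  })
}

#' Save / load a tagger checkpoint
#'
#' Serializes the complete tagger (configuration, vocabularies and all
#' parameter arrays); reloading reproduces decoding bit-exactly.
#' @param tagger a [CRFTagger-class].
#' @param path file path.
#' @export
saveTagger <- function(tagger, path) {
  stopifnot(is(tagger, "CRFTagger"))
  saveRDS(tagger, path)
  invisible(path)
}

#' @rdname saveTagger
#' @export
loadTagger <- function(path) {
  t <- readRDS(path)
  stopifnot(is(t, "CRFTagger"))
  t
}

setMethod("show", "CRFTagger", function(object) {
  cat(sprintf("CRFTagger (%s, hidden %d, %s)\n", object@model@mode,
              object@config$hidden,
              if (object@trained) sprintf("trained, final NLL %.3f",
                                          tail(object@lossTrace, 1))
              else "untrained"))
})

#' Fit a complete NER model from a corpus
#'
#' Convenience pipeline: pretrains the radical table and the mode-keyed
#' table on the training corpus (character/pinyin/final view), builds the
#' feature model and tagger, and trains. All randomness derives from
#' `seed`.
#'
#' @param corpus training corpus of tagged sentences.
#' @param db a [CharacterDB-class].
#' @param mode `"R+C"`, `"R+P"` or `"R+F"`.
#' @param sum use the fixed Sum composition variant.
#' @param dim embedding dim for both tables.
#' @param hidden LSTM hidden size.
#' @param epochs tagger training epochs.
#' @param pretrainEpochs skip-gram epochs.
#' @param window skip-gram window.
#' @param lr Adam learning rate.
#' @param batchSize sentences per step.
#' @param seed master seed.
#' @param types entity types of the tag set.
#' @return a trained [CRFTagger-class].
#' @export
trainNERModel <- function(corpus, db, mode = "R+P", sum = FALSE, dim = 32L,
                          hidden = 64L, epochs = 6L, pretrainEpochs = 3L,
                          window = 2L, lr = 1e-3, batchSize = 8L, seed = 1L,
                          types = c("BOD", "SYM", "DIS", "EXP", "TRE")) {
  left <- pretrainEmbeddings(corpus, "radical", db, dim = dim,
                             window = window, epochs = pretrainEpochs,
                             seed = seed)
  right <- pretrainEmbeddings(corpus, .rightView(mode), db, dim = dim,
                              window = window, epochs = pretrainEpochs,
                              seed = seed + 1L)
  fm <- featureModel(mode, db, left, right, sum = sum)
  tagger <- crfTagger(fm, tagSet(types), hidden = hidden, seed = seed)
  trainTagger(tagger, corpus, epochs = epochs, lr = lr,
              batchSize = batchSize, seed = seed)
}
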