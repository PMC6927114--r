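#' @import methods
#' @importFrom stats median rbinom rnorm rpois runif setNames
#' @importFrom utils head tail modifyList
#' @useDynLib phonosemNER, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## Reserved symbols --------------------------------------------------------

#' Reserved radical symbol for characters with no known primary radical
#' @export
RADICAL_NONE <- "∅"

#' Token used for out-of-vocabulary entries in embedding tables
#' @export
UNK_TOKEN <- "<unk>"

## Pinyin ------------------------------------------------------------------

#' A segmented pinyin syllable
#'
#' One romanized Mandarin reading split into its three conventional parts:
#' an optional initial (consonantal onset), an obligatory final (the
#' vowel-bearing remainder) and a tone (0 = neutral, 1 = flat, 2 = rising,
#' 3 = falling-rising, 4 = falling).
#'
#' @slot raw the input string as given.
#' @slot initial member of the initial inventory, or `""` for zero-initial
#'   syllables.
#' @slot final member of the final inventory; never empty.
#' @slot tone integer in 0..4.
#' @seealso [parsePinyin()], [toneless()], [finalOf()]
#' @export
setClass("Pinyin",
  representation(raw = "character", initial = "character",
                 final = "character", tone = "integer"))

setValidity("Pinyin", function(object) {
  if (length(object@final) != 1L || !nzchar(object@final))
    return("final must be a single non-empty string")
  if (!(object@tone %in% 0:4)) return("tone must be in 0..4")
  TRUE
})

## Character knowledge base ------------------------------------------------

#' A single character record
#'
#' One script symbol together with the knowledge the tagger consults:
#' its primary (semantic) radical, its pinyin readings in priority order
#' (the first is the canonical reading), and its Ideographic Description
#' Sequence. Atomic symbols carry themselves as their IDS.
#'
#' @slot char single symbol.
#' @slot radical single symbol; [RADICAL_NONE] for the unknown-character
#'   sentinel.
#' @slot readings character vector of raw pinyin strings; empty for the
#'   sentinel.
#' @slot ids IDS string, equal to `char` for atomic symbols.
#' @slot known FALSE for the sentinel returned on failed lookup.
#' @export
setClass("CharacterRecord",
  representation(char = "character", radical = "character",
                 readings = "character", ids = "character",
                 known = "logical"))

#' Character knowledge base
#'
#' Maps script symbols to [CharacterRecord-class] entries. Built from a
#' flattened four-column TSV (`char`, `primary_radical`,
#' semicolon-separated `readings`, `ids`). Lookup is total: unknown symbols
#' yield a sentinel record rather than an error, so downstream feature
#' extraction degrades to UNK embeddings on rare clinical symbols.
#'
#' @slot records data.frame with character columns `char`, `radical`,
#'   `readings` (`;`-joined) and `ids`, one row per known symbol.
#' @slot index named integer vector mapping `char` to its row.
#' @slot log character vector of loader warnings (skipped/overridden lines).
#' @seealso [readCharDB()], [charLookup()]
#' @export
setClass("CharacterDB",
  representation(records = "data.frame", index = "integer", log = "character"))

setValidity("CharacterDB", function(object) {
  rec <- object@records
  need <- c("char", "radical", "readings", "ids")
  if (!all(need %in% names(rec))) return("records must have char/radical/readings/ids")
  if (anyDuplicated(rec$char)) return("duplicate characters in records")
  if (length(object@index) != nrow(rec)) return("index out of step with records")
  TRUE
})

#' Phono-semantic verdict
#'
#' Result of the nested-IDS phono-semantic check for one character: a
#' character is phono-semantic when some nested component shares a pinyin
#' final with the character itself; that component is reported as the
#' phonetic radical.
#'
#' @slot char the character examined.
#' @slot isPhonoSemantic logical verdict.
#' @slot phoneticRadical matching component, or [RADICAL_NONE].
#' @slot matchedFinal shared final, or `""` when negative.
#' @slot depth nesting depth of the match (1 = direct component); `NA` when
#'   negative.
#' @slot note diagnostic note (e.g. "no reading").
#' @export
setClass("PhonoSemanticVerdict",
  representation(char = "character", isPhonoSemantic = "logical",
                 phoneticRadical = "character", matchedFinal = "character",
                 depth = "integer", note = "character"))

setValidity("PhonoSemanticVerdict", function(object) {
  pos <- object@isPhonoSemantic
  if (pos != (object@phoneticRadical != RADICAL_NONE))
    return("positive verdict must carry a phonetic radical")
  if (pos != nzchar(object@matchedFinal))
    return("positive verdict must carry a matched final")
  TRUE
})

## Embeddings --------------------------------------------------------------

#' Embedding table
#'
#' A dense lookup table from tokens (characters, radicals, toneless pinyin
#' syllables or finals) to real vectors, with an explicit UNK vector used
#' for out-of-vocabulary tokens.
#'
#' @slot dim embedding dimensionality.
#' @slot vectors numeric matrix, one row per token, rownames = tokens.
#' @slot unk numeric vector of length `dim`.
#' @seealso [pretrainEmbeddings()], [readWord2vec()], [writeWord2vec()]
#' @export
setClass("EmbeddingTable",
  representation(dim = "integer", vectors = "matrix", unk = "numeric"))

setValidity("EmbeddingTable", function(object) {
  if (ncol(object@vectors) != object@dim) return("vector width != dim")
  if (length(object@unk) != object@dim) return("unk width != dim")
  if (is.null(rownames(object@vectors))) return("vectors must have token rownames")
  TRUE
})

#' Composition layer parameters
#'
#' The learned linear layer `E = LW %*% left + RW %*% right + b` that
#' combines a radical embedding with a character / pinyin / final
#' embedding into one composed character embedding. The non-trainable
#' ("Sum") variant fixes `LW` and `RW` to the identity and `b` to zero,
#' reducing composition to plain vector addition.
#'
#' @slot LW out_dim x left_dim weight matrix.
#' @slot RW out_dim x right_dim weight matrix.
#' @slot b bias vector of length out_dim.
#' @slot trainable FALSE for the Sum variant.
#' @seealso [compositionParams()], [compose()]
#' @export
setClass("CompositionParams",
  representation(LW = "matrix", RW = "matrix", b = "numeric",
                 trainable = "logical"))

setValidity("CompositionParams", function(object) {
  if (nrow(object@LW) != nrow(object@RW)) return("LW/RW output dims differ")
  if (length(object@b) != nrow(object@LW)) return("bias length != output dim")
  if (!object@trainable) {
    d <- nrow(object@LW)
    if (ncol(object@LW) != d || ncol(object@RW) != d)
      return("Sum variant requires square identity weights")
    if (!isTRUE(all.equal(object@LW, diag(d))) ||
        !isTRUE(all.equal(object@RW, diag(d))) ||
        any(object@b != 0))
      return("Sum variant requires LW = RW = I and b = 0")
  }
  TRUE
})

#' Feature model
#'
#' Binds the two embedding tables, the composition parameters, the
#' character knowledge base and the feature mode. The left table always
#' holds primary-radical embeddings; the right table is keyed per mode:
#' the character itself (`R+C`), the toneless canonical reading (`R+P`) or
#' the final of the canonical reading (`R+F`).
#'
#' @slot mode one of "R+C", "R+P", "R+F".
#' @slot left radical [EmbeddingTable-class].
#' @slot right mode-keyed [EmbeddingTable-class].
#' @slot params [CompositionParams-class].
#' @slot db [CharacterDB-class].
#' @seealso [featureModel()], [embedSentence()]
#' @export
setClass("FeatureModel",
  representation(mode = "character", left = "EmbeddingTable",
                 right = "EmbeddingTable", params = "CompositionParams",
                 db = "CharacterDB"))

setValidity("FeatureModel", function(object) {
  if (!object@mode %in% c("R+C", "R+P", "R+F")) return("unknown mode")
  if (ncol(object@params@LW) != object@left@dim) return("LW width != left dim")
  if (ncol(object@params@RW) != object@right@dim) return("RW width != right dim")
  TRUE
})

## Tagger ------------------------------------------------------------------

#' BIO tag set
#'
#' The closed tag alphabet `O` plus `B-`/`I-` for each entity type
#' (11 tags for the five clinical types BOD/SYM/DIS/EXP/TRE), with virtual
#' START/STOP states and the allowed-transition matrix of the linear-chain
#' CRF: `I-X` is reachable only from `B-X` or `I-X`, and START never
#' precedes an `I-X`.
#'
#' @slot tags character vector of real tags (O first).
#' @slot types entity types.
#' @slot allowed logical (|tags|+2)^2 matrix over tags + START/STOP.
#' @slot start,stop indices of the virtual states.
#' @seealso [tagSet()]
#' @export
setClass("TagSet",
  representation(tags = "character", types = "character",
                 allowed = "matrix", start = "integer", stop = "integer"))

#' Bi-LSTM-CRF tagger
#'
#' Character-based sequence tagger: composed character embeddings feed a
#' single-layer bidirectional LSTM whose hidden states are projected to
#' per-position tag emission scores, decoded under a linear-chain CRF.
#' All numeric parameters (embedding tables, composition layer, LSTM,
#' projection, transitions) live in `params` and are trained jointly.
#'
#' @slot model [FeatureModel-class] defining the input features.
#' @slot tagset [TagSet-class].
#' @slot params named list of numeric arrays (see [crfTagger()]).
#' @slot leftVocab,rightVocab token vectors indexing the embedding rows.
#' @slot config list of hyperparameters (hidden, lr, epochs, batchSize, seed).
#' @slot trained logical.
#' @slot lossTrace mean per-sentence negative log-likelihood per epoch.
#' @seealso [crfTagger()], [trainTagger()], [viterbiDecode()]
#' @export
setClass("CRFTagger",
  representation(model = "FeatureModel", tagset = "TagSet", params = "list",
                 leftVocab = "character", rightVocab = "character",
                 config = "list", trained = "logical", lossTrace = "numeric"))

## Evaluation --------------------------------------------------------------

#' Entity-level precision/recall/F report
#'
#' Exact-match (type + span) entity scoring, micro-averaged: the `ALL` row
#' pools true/false positives and false negatives over every mention
#' rather than averaging the per-type rows.
#'
#' @slot table data.frame with rows per type plus `ALL` and columns
#'   `type`, `tp`, `fp`, `fn`, `precision`, `recall`, `f`.
#' @seealso [scoreEntities()]
#' @export
setClass("PRFReport", representation(table = "data.frame"))

#' Median split of documents by phono-semantic proportion
#'
#' Documents whose token-level phono-semantic percentage is strictly above
#' the median go to section A; the rest (ties included) to section B.
#'
#' @slot sectionA,sectionB integer document indices.
#' @slot median median percentage.
#' @slot percentages per-document percentages.
#' @seealso [sectionByPhonoSemantic()]
#' @export
setClass("SectionSplit",
  representation(sectionA = "integer", sectionB = "integer",
                 median = "numeric", percentages = "numeric"))

## Synthetic ---------------------------------------------------------------

#' Synthetic study configuration
#'
#' Parameters of the self-contained pseudo-script generator: a character
#' inventory in the Unicode private-use area whose phono-semantic fraction
#' and radical/entity-type affinity are controlled, plus annotated-corpus
#' shape parameters. A single seed fixes everything downstream.
#'
#' @slot nChars,nRadicals,nPhoneticPool inventory sizes.
#' @slot phonoFraction fraction p of characters built phono-semantic.
#' @slot finalsPool pinyin finals used for synthetic readings.
#' @slot entityTypes entity types (default the five clinical types).
#' @slot alpha radical-type affinity strength; 0 = uniform.
#' @slot nSentences,meanLen,entityDensity corpus shape (sentences, mean
#'   length, mean entities per sentence).
#' @slot seed integer RNG seed.
#' @seealso [syntheticConfig()], [generateCharDB()], [generateCorpus()]
#' @export
setClass("SyntheticConfig",
  representation(nChars = "integer", nRadicals = "integer",
                 nPhoneticPool = "integer", phonoFraction = "numeric",
                 finalsPool = "character", entityTypes = "character",
                 alpha = "numeric", nSentences = "integer",
                 meanLen = "numeric", entityDensity = "numeric",
                 seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  if (object@phonoFraction < 0 || object@phonoFraction > 1)
    return("phonoFraction must lie in [0, 1]")
  if (length(object@finalsPool) < 3L)
    return("finalsPool needs at least 3 finals to control phono status")
  if (object@alpha < 0) return("alpha must be non-negative")
  TRUE
})
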