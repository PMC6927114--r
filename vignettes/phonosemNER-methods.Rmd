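---
title: "Radical and pinyin features for Chinese clinical NER: methods"
author: "phonosemNER"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radical and pinyin features for Chinese clinical NER: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonosemNER)
```

## The problem and the model

Clinical NER in Chinese must work at the character level: text has no word
boundaries, and segmenting it first imports segmentation errors into the
tagger. The modelling idea this package implements is that the characters
themselves carry usable structure. Most Chinese characters are
*phono-semantic* compounds: a primary (semantic) radical indicates the
meaning class — disease names share 疒, organ names share 月/肉 — while a
phonetic radical hints at the pronunciation. A character embedding built
from these parts should therefore transfer information across characters
that never co-occur: 病, 痛 and 痨 all carry 疒 even if only one of them
appears in training data.

Three feature models build the per-character embedding from two
pretrained tables:

* **R+C** — primary radical + the character itself;
* **R+P** — primary radical + the toneless pinyin of the character;
* **R+F** — primary radical + only the final of the pinyin.

The two vectors are merged by a learned affine composition layer

$$E_i = LW \cdot LE_i + RW \cdot RE_i + b,$$

with one `LW`, `RW`, `b` shared across all positions and updated jointly
with the tagger. We read the per-position subscripts of the layer as
"applied at position i with shared parameters": per-position weights
could not generalize across sentences and could not be trained jointly
with a sentence-level objective. A degenerate **Sum** variant fixes
`LW = RW = I`, `b = 0`, reducing composition to vector addition; it is
implemented as exactly that, so it is bit-reproducible, and it serves as
the ablation showing whether the learned layer earns its parameters.

The sequence model is a standard single-layer Bi-LSTM over the composed
embeddings, projected to per-position emission scores over the 11-tag BIO
alphabet (five clinical types BOD/SYM/DIS/EXP/TRE), decoded under a
linear-chain CRF. Training minimizes the exact negative log-likelihood
(forward-algorithm log-partition minus gold path score) with Adam.

## The phono-semantic check

There is no authoritative list of phono-semantic characters; the
historical dictionary route (*Shuowenjiezi*) misses every character coined
since. The operational test used here: a character is phono-semantic when
it **shares a pinyin final with one of its forming components**. The
components are found by parsing the character's Ideographic Description
Sequence (IDS, prefix notation over the IDC operators U+2FF0–U+2FFB) and
recursively expanding each component through its own IDS. The recursion
matters: 徒 (*tú*) decomposes into 彳 and 走 (*zǒu*), neither of which
matches — but 走 itself contains 土 (*tǔ*), and `u = u` makes 徒
phono-semantic at depth 2.

Choices a user should know about:

* **All readings are compared** (cross product) when a character or
  component is polyphonic: 干 reads *gān* and *gàn*, and either may carry
  the match.
* **The primary radical is not excluded** from candidate phonetic
  radicals; the rule is "one of the forming radicals", and excluding the
  semantic radical would silently change verdicts for characters whose
  semantic and phonetic roles coincide.
* **`maxDepth` defaults to 3** with a visited-set cycle guard. The worked
  examples need depth ≤ 2; real IDS data (CHISE) contains reference
  cycles between variant forms, so unbounded recursion is unsafe. A
  verdict that is positive at depth d stays positive at any larger depth.
* **Known failure mode, by design**: characters whose phonetic radical has
  drifted in pronunciation are rejected. 脑 (*nǎo*) has phonetic radical
  凶 (*xiōng*); since `ao ≠ iong`, the method calls it non-phono-semantic
  even though etymologically it is. This depresses measured percentages
  well below the ~90% quoted in the literature for the script at large.
* **Percentage denominators**: only symbols present in the knowledge base
  count. Punctuation, Latin letters and digits — ubiquitous in clinical
  text — are excluded from numerator and denominator alike, since no
  sensible phono-semantic status exists for them.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| embedding `dim` | 32 (pipeline), 50 (pretraining API) | dims | small corpora; larger dims overfit before they help |
| skip-gram `window` | 2 | tokens | character contexts are short-range |
| skip-gram `epochs` / `negative` / `lr` | 3–5 / 5 / 0.025 | — | word2vec conventions |
| LSTM `hidden` | 64 (pipeline), 100 (API default) | units/direction | smallest size that saturates the synthetic task |
| tagger `epochs` | 6 | passes | held-out F plateaus here; more epochs overfit rare characters |
| tagger `lr` | 1e-3 | — | Adam default |
| `batchSize` | 8 | sentences | gradient averaging without losing update count |
| `finetune` | TRUE | — | whether pretrained tables keep training with the tagger; fine-tuning is the common default for small corpora |
| `maxDepth` | 3 | levels | see above |

Disallowed BIO transitions are scored at −10⁴ inside the training
normalizer (soft but effectively prohibitive, keeps the loss finite and
differentiable) and excluded outright (−∞) at decode time, so decoded
output is always BIO-valid. Viterbi ties break toward the lowest tag
index, making decoding deterministic; with continuous scores ties have
probability zero anyway.

## The synthetic study design

Annotated clinical corpora are access-restricted as a rule, so the
package ships a generator that reproduces the *statistical
structure* the method exploits, on a pseudo-script in the Unicode private
use area (no real-script knowledge can leak into tests):

* **Inventory**: 300 characters over 12 radicals and 30 phonetic
  components; each character is radical + component under a left-right
  IDC. With probability p = 0.6 the character's final is copied from its
  component (phono-semantic by construction); otherwise the final is drawn
  to differ from *both* components' finals, so ground truth is exactly
  recoverable — the binomial spread of the realized fraction around p is
  the only noise.
* **Radical–entity affinity**: the 12 radicals split round-robin into one
  group per entity type plus a background group. An entity character of
  type t comes from t's radical group with probability α/(α+1), α = 19
  (i.e. 95%); background characters favour the background group the same
  way. This is a deliberately strong version of the radical–type
  concentration observed in real clinical data, where the top radical
  accounts for ~11–17% of entity characters per type.
* **Frequencies are Zipf** by inventory position, shared by every corpus
  drawn from the inventory — frequency is a property of the language, not
  of one sample. Rare characters are where the radical features should
  pay off, and the shuffled-feature control confirms they do.
* **Well-posedness**: consecutive entities are separated by at least one
  background character. Without a separator, adjacent same-type entities
  are indistinguishable from one long entity *in principle* — the gold
  segmentation is not a function of the observable sequence — and
  exact-match F is capped by label noise rather than by the model.
* **Corpus shape**: 2000 training / 500 test sentences, mean length 12
  (Poisson, min 3), about two entities per sentence of length 1–4.

What the generator does **not** emulate: sentence semantics, grammar,
punctuation and alphanumerics, polyphony, multi-level IDS nesting in the
inventory (nesting is exercised by the real-character fixture and by the
randomized decomposition tests instead), and annotation noise. Passing
the synthetic learnability test shows the pipeline can exploit
radical/pinyin structure when it is present; it does not certify clinical
performance.

Problem sizes throughout (2000/500 sentences, 300 characters, dim 32,
hidden 64, 6 epochs) are chosen so a full train/evaluate cycle of all
three conditions — R+P, Sum, shuffled control — completes in a few
minutes on one desktop CPU; they saturate the synthetic task, and scaling
them further moves held-out F by less than seed-to-seed variation.

## Numerical and implementation notes

* The CRF log-partition and its gradients (forward–backward marginals)
  are computed in log space; correctness is pinned by exhaustive path
  enumeration at small sizes and by finite-difference checks of every
  parameter block.
* Skip-gram and the Bi-LSTM-CRF are single-threaded C++ with an explicit
  Mersenne-Twister RNG: a fixed seed reproduces pretrained tables
  bit-identically and training loss traces exactly.
* Unknown characters never fail: lookup returns a sentinel record (radical
  ∅, no readings, self-IDS), features fall back to UNK vectors, and the
  phono-semantic check returns a negative verdict annotated "no reading".
* Pinyin parsing treats `y`/`w` as initials, so *yǒng* segments as
  `y + ong` and compares equal-final with *tòng* — the segmentation the
  worked examples require. The parser accepts diacritic and
  trailing-digit tone dialects and `v` for `ü`; the closed final
  inventory turns typos into detectable parse errors instead of silent
  mis-keys.
* Entity scoring is exact-match micro-averaged: the `ALL` row pools
  counts, it is not the mean of the per-type rows (the per-type rows of a
  micro report generally do not average to the overall row). Dangling
  `I-X` tags are dropped (strict BIO) by default; a `lenient` flag repairs
  them to `B-X`.
* Cross-validation averages fold F arithmetically; fold assignment is a
  seeded shuffle cut into near-equal parts.
* Median sectioning sends only documents *strictly* above the median to
  section A; with an even document count the median is the mean of the
  middle two percentages, and an all-tied set yields an empty A.

## Limitations

* Character-based only; word-level NER would need a segmenter and
  word-level embedding keys.
* The R+P/R+F embedding key uses the canonical (first) reading only;
  polyphones get one key at embedding time even though the
  phono-semantic check considers all readings.
* No traditional/simplified normalization (月 standing in for 肉 must be
  encoded in the knowledge table itself, as the shipped fixture does).
* The composition layer is affine; richer (gated, multiplicative)
  composition might help but costs training time.
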