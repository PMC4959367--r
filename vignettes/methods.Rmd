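---
title: "Methods: rule-featured MaxEnt relation extraction over brat corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-featured MaxEnt relation extraction over brat corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bratrelex)
```

## The task and its assumptions

The package extracts binary relations between typed entity mentions in
biomedical full text: a relation *signature* is the ordered triple
`<arg1 type, predicate, arg2 type>` with predicate `has` or `relatedTo`,
so `Gene-has-Mutation` and `Cohort-has-Mutation` are distinct relations.
Two standing assumptions shape everything downstream:

1. **Sentence-boundedness.** A relation is assumed to be expressed within
   one sentence. Gold relations whose arguments live in different
   sentences are flagged `cross_sentence` at binding time; they are
   unreachable by any extractor in this package and score as false
   negatives. This is a deliberate modelling limit, not a bug.
2. **Gold entities.** The evaluation protocol takes entity mentions as
   given. Candidate instances for a signature are therefore all
   same-sentence ordered gold pairs with matching types; the classifier's
   predictions are a subset of these, which immediately yields the
   recall bound `R(model) <= R(baseline)` that the evaluation suite
   asserts on every corpus.

## Feature rules

Each candidate pair is described by 19 rules computed from a parsed
sentence (tokens + POS, Stanford-style dependency arcs, constituency tree
with Collins heads):

* *Syntactic*: the labelled, direction-annotated dependency path between
  the two entity head tokens; whether a verb lies on that path (if
  several, the one closest to the dependency root anchors the rule, and
  its lexicon class — e.g. reduce → `DOWN_REGULATE` — is emitted); a
  no-verb flag that gates the nominalization rules; SBAR-based clause
  features (clause presence, whether an SBAR separates the entities,
  signed token distances to the nearest clause boundary); whether the two
  anchored nodes share a parent; the constituency label path through the
  lowest common ancestor and its length.
* *Lexical*: negation (a `neg` arc into the path, or a negative-lexicon
  word in a direct dependency with a path verb, as in "fails to reduce" —
  scope is deliberately restricted to the inter-entity path); voice via
  `auxpass`; the word sequence strictly between the entities; the
  inclusive token distance (entity widths count, so widths 1 and 2 with
  3 tokens between give 6); windows of `window_k` words (default 3,
  clipped at sentence edges) left of entity 1 and right of entity 2 with
  simplified POS; strict nominalization (a lexicon nominalization
  dominating both entity heads within two dependency steps) and weak
  nominalization (exactly one entity after a preposition with a lexicon
  nominalization ahead of it).
* *Supplementary*: number and types of gold mentions strictly between the
  pair, total mentions in the sentence, argument order in text, and the
  two argument type tags.

Booleans and categories become `name=value` indicators; integer features
are bucketed (`0..5`, `6-10`, `>10`, `inf`); token sequences contribute
per-token indicators plus a whole-sequence indicator. The three lexicons
(relation verbs with classes, nominalizations, negative words) ship as
editable TSVs under `inst/extdata/` — they are seed lists, not exhaustive
resources.

Design choices made where the published description is open: `window_k`
defaults to 3; the strict nominalization pattern is a reconstruction (the
published template is not recoverable from the text) and is therefore
driven entirely by the editable lexicon; the "full tree path" rule is
ambiguous between constituency and dependency readings, so both are
emitted under distinct names (`tree_path`, `dep_path`); multi-verb paths
anchor at the root-most verb. When a sentence cannot be parsed, only the
`unparsed` flag plus the supplementary entity-table features are emitted
(lexical windows need a tokenisation, which only an adapter provides).

## Parsing: the adapter contract

The method needs parse *structures*, not a particular parser. An adapter
is any function mapping sentence text to offset-aligned tokens, arcs and
a tree; cached parses can be supplied as CoNLL-style tables through
`parsed_sentence()`. The shipped `template_parser()` is a deterministic
rule parser for the controlled language the synthetic generator emits
(determiner–noun chunks, one verb group with optional `was/were`
passives and `not`, prepositional attachment, `and` coordination, one
subordinate clause). It is explicitly **not** a general English parser;
tests that need specific structures hand-build them in bracket notation
via `read_ptb_tree()`. Collins head rules follow the published table,
with unknown phrase labels defaulting to the rightmost child.

Entity anchoring: if some node spans exactly the entity's tokens, the
smallest such node wins (so a single-token entity anchors at its
pre-terminal); otherwise tokens are trimmed from the end of the span,
then from the beginning, until an exactly-spanning node exists; the last
resort is the pre-terminal of the entity's head-most token. Suffix
trimming is preferred over prefix trimming when both would succeed,
matching the order in which the heuristic is described.

## Models and tree inference

All classifiers are maximum-entropy (multinomial logistic) models over
sparse indicators, fitted by maximising the L2-penalised log-likelihood
with L-BFGS (`stats::optim`). Defaults, fixed for determinism where the
source leaves them open: zero-initialised weights, `l2 = 1.0`,
convergence tolerance `1e-6`, at most 500 iterations. The objective is
convex, so training is reproducible bit-for-bit; the recorded
`objective_trace` is over function evaluations (line-search probes
included), so tests assert improvement of the accepted optimum rather
than per-evaluation monotonicity.

Argument identification labels constituency nodes ARG/NONE for a trigger
under the non-overlap constraint (no ARG node may dominate another). The
bottom-up dynamic program is exact: for each node it compares "this node
is ARG and everything below is NONE" against "this node is NONE and each
child subtree takes its own optimum". The multi-class extension keeps the
top-*k* joint typings per subtree: a non-NONE node forces all descendants
to NONE; a NONE node combines its children's top-*k* lists, pruning to
*k* as children are folded in (safe because a subtree's contribution is a
product over independent child terms). `k` defaults to 5; joint-probability
ties break towards the lexicographically smallest labelling in preorder.
Both procedures are verified against exhaustive enumeration on random
trees of up to 12 nodes. One worked case deserves a note: with parent
P(ARG) = 0.9 over two children at 0.6 each, brute force gives the
parent-ARG labelling at 0.9·0.4·0.4 = 0.144, beating both-children-ARG at
0.1·0.6·0.6 = 0.036 — the test freezes the brute-force answer.

Trigger–argument interaction is an alternation: propose triggers (verb
and nominalization lexicon hits, plus an optional scored classifier),
label arguments for the best trigger, then re-score triggers conditioned
on the current argument count, for at most `rounds` rounds (default 2)
with a fixed-point early stop. For the gold-entity evaluation protocol
this machinery is off the default path: candidates are entity pairs, and
a binary REL/NONE classifier per signature decides. A training corpus
with no negative candidates yields a degenerate single-label model that
predicts the relation everywhere — deliberately identical to the
baseline's behaviour.

## Evaluation

Predictions and gold are both deduplicated to tuples of (predicate,
exact arg1 span, exact arg2 span) before counting; with gold entities the
spans cannot jitter, so exact-span matching is the right granularity.
`F_β = (1+β²)PR/(β²P+R)` with β = 0.5 for headline reports (precision
weighted above recall) and β = 1 where a plain harmonic mean is wanted.
Cross-validation permutes file names under a required seed, deals them
into near-equal contiguous folds, and reports per-fold counts plus two
aggregates. Both are always reported because fold-averaged F cannot in
general be reproduced from averaged P and R — e.g.
`F0.5(0.873, 0.921) = 0.882`, while a published table pairing those
averages prints 0.888 — so pinning a single aggregation would
misrepresent the ambiguity. `pooled_micro` sums counts and computes once;
`macro_over_folds` averages per-fold values, skipping folds where a
quantity is undefined (zero gold → recall undefined, zero predictions →
precision undefined).

## The synthetic world: what a green test establishes

`generate_corpus()` plants relations in templated frames
("The *cohort* **developed** the *disease* [in the *distractor*] ."):
a drawn candidate pair becomes gold with `plant_prob` (default 0.7);
positives carry their signature-specific trigger verb and negatives a
neutral verb, each flipped with noise probability ε (default 0); a
fraction *c* of gold relations is split across two adjacent sentences;
distractor entities (default rate 0.3) co-occur with gold pairs to give
the baseline false positives; with a configurable rate a disease surface
is additionally annotated as a metonymic cohort on the identical span,
reproducing the same-string multi-type situation that motivates the
same-string filter. Defaults were chosen once to make the stated world
realistic for a small curation corpus — a few hundred relations across
tens of documents, baseline precision well below 1, baseline recall 1−c —
and are not tuned against test outcomes.

Distractor types are drawn outside the frame signature's argument types.
That keeps a stated property of the world exactly true: at ε = 0 the
signature's trigger between a pair separates gold from non-gold with
P = R = 1, which is the ceiling the parameter-recovery tests measure the
classifier against (held-out P, R ≥ 0.9).

What the generator does **not** emulate: real biomedical prose and parser
errors on it, coreference, discontinuous mentions, n-ary events,
annotator disagreement, and genuinely hard negatives (negatives here are
lexically marked by the absent trigger). A green recovery test therefore
establishes that the pipeline is wired correctly end to end and that the
features can carry a deterministic lexical signal — not that the reported
real-corpus numbers are reproduced. Reproducing those requires the real
corpus and a full parser, both outside this package's offline scope.

## Numerical and degenerate-input choices

* Offsets are 0-based half-open (brat convention); token indices are
  1-based inside R.
* Discontinuous brat spans collapse to their envelope, and the mention
  surface is re-derived from the text so the span invariant holds.
* `patient` is folded into `cohort` by the default type map.
* Duplicate relation mentions are kept at read time and deduplicated only
  at scoring time.
* Same-span entity pairs (multi-type annotations) have coincident head
  tokens; their dependency path is empty by definition and the verb-path
  rule reports no verb.
* The same-string filter is OFF in every default pipeline, matching the
  reported baseline, which did not control for overlapping annotations.
* `fbeta(0, 0, β) = 0` by convention; undefined fold metrics propagate as
  `NA` into the macro average, never as zeros.
* Config files are flat `key = value` text or JSON (no YAML parser is
  assumed to be available).

## Known limitations

Cross-sentence relations are out of reach by design. The template parser
covers only the controlled generator language; real corpora need cached
external parses. The nominalization rule is lexicon-bound and its strict
pattern is a reconstruction. The trigger/argument alternation is exposed
and tested but not exercised by the default gold-entity protocol. No
significance testing or bootstrap intervals are provided.
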