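# bratrelex

Relation extraction for biomedical variant-curation corpora annotated in
the brat standoff format, in R.

Curated variant databases need structured statements like
*Cohort-has-Disease*, *Gene-has-Mutation* or *Cohort-has-Size* pulled out
of full-text articles. Given gold entity mentions (gene, disease,
mutation, patient cohort, ...), `bratrelex` decides which same-sentence
entity pairs actually express a relation. It provides, as a library and a
small CLI:

* **corpus I/O** — read/write paired `.txt`/`.ann` brat files, sentence
  segmentation with entity binding (entities are never split; straddled
  sentence boundaries merge), selection of studied relation signatures by
  attestation count, and collapsing of the *Characteristics* subtypes
  (Concepts&Ideas / Disorders / Physiology / Phenomena) into one category;
* **a parse layer** — pluggable parser adapters producing tokens, POS,
  Stanford-style dependencies and a constituency tree; Collins head
  finding; dependency paths; an entity-anchoring heuristic that trims a
  mention span until a covering subtree exists;
* **19 feature rules** — 7 syntactic (verb in dependency path, no-verb
  gating, clause/SBAR features, same head, tree path, path length),
  8 lexical (negation, voice, words between, surface distance, left/right
  windows of width *k*, strict and weak nominalization) and
  4 supplementary (entity counts, entities in between, entity order),
  plus the argument type tags;
* **maximum-entropy models** — multinomial logistic classifiers over
  sparse indicator features, fitted by L-BFGS with L2 penalty, used for
  per-signature relation classification, ARG/NONE argument
  identification and trigger scoring;
* **tree inference** — the exact dynamic program for non-overlapping
  argument labelling (no two ARG nodes in an ancestor–descendant
  relation) and its top-*k* re-ranking extension for joint semantic
  typing;
* **a co-occurrence baseline** — every type-compatible ordered entity
  pair within a sentence, optionally post-filtered to drop pairs whose
  two arguments annotate the identical string;
* **evaluation** — exact-span tuple matching, the precision-weighted
  F-β score `(1+β²)PR/(β²P+R)` (β = 0.5 by default), and seeded 10-fold
  cross-validation over permuted files with both macro-over-folds and
  pooled-micro aggregation;
* **a synthetic corpus generator** — seeded brat corpora with planted
  trigger-governed relations, distractor entities, configurable trigger
  noise ε, a cross-sentence relation fraction *c* and same-string
  multi-type annotations, so the entire pipeline is testable offline.

A structural property worth knowing: the classifier only ever filters the
baseline's candidate pairs, so its recall can never exceed the baseline's
— its job is to buy precision.

## Worked example

Generate a 24-document synthetic corpus, then cross-validate the
co-occurrence baseline against a trained per-signature classifier:

```r
library(bratrelex)

gen  <- generate_corpus(synth_config(n_docs = 24), seed = 11)
sig  <- parse_signature("cohort-has-disease")
plan <- make_folds(names(gen$corpus), 4, seed = 11)
parses <- lapply(gen$corpus, parse_document)

rb <- cross_validate(gen$corpus, baseline_factory(sig), sig, plan, beta = 0.5)
rm <- cross_validate(gen$corpus, model_factory(sig, parses = parses), sig, plan, beta = 0.5)

rb[rb$fold == "pooled_micro", ]
#>           signature         fold tp fp fn precision recall fbeta
#>  cohort-has-disease pooled_micro 24 19  0     0.558      1 0.612
rm[rm$fold == "pooled_micro", ]
#>           signature         fold tp fp fn precision recall fbeta
#>  cohort-has-disease pooled_micro 24  0  0         1      1     1
```

The baseline finds every gold relation (recall 1) but also every
type-compatible distractor pair (precision 0.56); the trained model keeps
recall and filters the false co-occurrences. On this noise-free corpus the
trigger verb is a perfect separator, so the model reaches precision 1;
with trigger noise its precision degrades while the recall bound still
holds.

## Command line

```sh
Rscript -e 'bratrelex::bratrelex_main()' simulate --seed 5 --docs 20 --out corpus/
Rscript -e 'bratrelex::bratrelex_main()' baseline --corpus corpus/ \
    --signature cohort-has-disease --same-string-filter off --out predictions/
Rscript -e 'bratrelex::bratrelex_main()' run --corpus corpus/ --mode model \
    --folds 10 --seed 5 --beta 0.5 --report report.tsv
```

(`inst/scripts/bratrelex` is an equivalent installed wrapper.)

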