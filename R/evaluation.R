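#' Precision-weighted F-beta score
#'
#' `F_beta = (1 + beta^2) P R / (beta^2 P + R)`, with `F = 0` when both
#' `P` and `R` are zero.  `beta = 0.5` weights precision above recall (the
#' headline metric); `beta = 1` is the plain F1 harmonic mean.
#'
#' @param p,r precision and recall, fractions in \[0, 1\].
#' @param beta positive weight.
#' @return F-beta, vectorised over `p` and `r`.
#' @export
fbeta <- function(p, r, beta = 0.5) {
  stopifnot(beta > 0)
  out <- ifelse(beta^2 * p + r > 0, (1 + beta^2) * p * r / (beta^2 * p + r), 0)
  out[is.na(p) | is.na(r)] <- NA_real_
  out
}

# dedup key for a relation tuple: predicate + exact argument spans
relation_tuples <- function(relations, doc) {
  if (!nrow(relations)) return(character())
  i1 <- match(relations$arg1, doc$entities$id)
  i2 <- match(relations$arg2, doc$entities$id)
  unique(paste(relations$predicate,
               doc$entities$start[i1], doc$entities$end[i1],
               doc$entities$start[i2], doc$entities$end[i2]))
}

# gold relations of one signature in a document (cross-sentence included)
gold_relations <- function(doc, signature) {
  type_of <- stats::setNames(doc$entities$type, doc$entities$id)
  rels <- doc$relations
  keep <- rels$predicate == signature$predicate &
    type_of[rels$arg1] == signature$arg1_type &
    type_of[rels$arg2] == signature$arg2_type
  rels[keep, , drop = FALSE]
}

#' Score predictions against gold relations
#'
#' A prediction is a true positive iff a gold relation with the same
#' predicate and exactly matching argument mention spans exists; both
#' sides are deduplicated to identical tuples first.  Unmatched gold
#' relations — including those whose arguments span sentences, which no
#' sentence-bound extractor can reach — count as false negatives.
#'
#' @param predicted,gold data.frames of relation mentions over `doc`.
#' @param doc the [brat_document()] the mention ids resolve in.
#' @return list with integer counts `tp`, `fp`, `fn`.
#' @export
match_predictions <- function(predicted, gold, doc) {
  pt <- relation_tuples(predicted, doc)
  gt <- relation_tuples(gold, doc)
  tp <- length(intersect(pt, gt))
  list(tp = tp, fp = length(pt) - tp, fn = length(gt) - tp)
}

#' Deal corpus files into cross-validation folds
#'
#' Files are randomly permuted under the given seed (so adjacent,
#' similar files spread across folds) and dealt into `n_folds` contiguous
#' groups whose sizes differ by at most one.  Deterministic per seed.
#'
#' @param files character vector of file/document identifiers.
#' @param n_folds number of folds (>= 2).
#' @param seed integer seed; required, no default.
#' @return object of class `fold_plan`: list with `seed` and `folds` (list
#'   of character vectors partitioning `files`).
#' @export
make_folds <- function(files, n_folds = 10L, seed) {
  if (n_folds < 2L) stop("n_folds must be >= 2", call. = FALSE)
  stopifnot(!missing(seed))
  perm <- with_seed(seed, sample(files))
  sizes <- rep(length(files) %/% n_folds, n_folds)
  extra <- length(files) %% n_folds
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  folds <- lapply(seq_len(n_folds), function(k) {
    if (sizes[k] == 0L) character() else perm[seq(starts[k], ends[k])]
  })
  structure(list(seed = seed, folds = folds), class = "fold_plan")
}

# evaluate a seeded expression without disturbing the global RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Cross-validated evaluation of an extractor
#'
#' For each fold, the extractor factory is trained on the union of the
#' other folds and evaluated on the held-out fold.  Per-fold counts and
#' metrics are reported together with two aggregates: `macro_over_folds`
#' (mean of per-fold P, R and F over folds where they are defined; folds
#' with no gold relations are skipped for recall) and `pooled_micro`
#' (counts summed over folds, then P/R/F computed once).
#'
#' @param corpus named list of segmented [brat_document()].
#' @param extractor_factory function(train_docs) -> function(doc) ->
#'   data.frame of predicted relations.
#' @param signature a [relation_signature()].
#' @param plan a [make_folds()] plan over `names(corpus)`.
#' @param beta F-beta weight (default 0.5).
#' @return data.frame with one row per fold plus rows `macro_over_folds`
#'   and `pooled_micro`; columns `signature`, `fold`, `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `fbeta`.
#' @export
cross_validate <- function(corpus, extractor_factory, signature, plan,
                           beta = 0.5) {
  stopifnot(inherits(plan, "fold_plan"))
  sig_str <- format(signature)
  rows <- list()
  for (k in seq_along(plan$folds)) {
    test_ids <- plan$folds[[k]]
    train_ids <- setdiff(names(corpus), test_ids)
    predictor <- extractor_factory(corpus[train_ids])
    tp <- fp <- fn <- 0L
    for (id in test_ids) {
      doc <- corpus[[id]]
      cnt <- match_predictions(predictor(doc), gold_relations(doc, signature), doc)
      tp <- tp + cnt$tp; fp <- fp + cnt$fp; fn <- fn + cnt$fn
    }
    p <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
    r <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
    rows[[k]] <- data.frame(signature = sig_str, fold = as.character(k),
                            tp = tp, fp = fp, fn = fn,
                            precision = p, recall = r,
                            fbeta = fbeta(p, r, beta),
                            stringsAsFactors = FALSE)
  }
  per_fold <- do.call(rbind, rows)
  macro <- data.frame(
    signature = sig_str, fold = "macro_over_folds",
    tp = sum(per_fold$tp), fp = sum(per_fold$fp), fn = sum(per_fold$fn),
    precision = mean(per_fold$precision, na.rm = TRUE),
    recall = mean(per_fold$recall, na.rm = TRUE),
    fbeta = mean(per_fold$fbeta, na.rm = TRUE),
    stringsAsFactors = FALSE)
  tp <- sum(per_fold$tp); fp <- sum(per_fold$fp); fn <- sum(per_fold$fn)
  p <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  r <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  micro <- data.frame(signature = sig_str, fold = "pooled_micro",
                      tp = tp, fp = fp, fn = fn,
                      precision = p, recall = r, fbeta = fbeta(p, r, beta),
                      stringsAsFactors = FALSE)
  out <- rbind(per_fold, macro, micro)
  rownames(out) <- NULL
  out
}

#' Extractor factories for the two experimental pipelines
#'
#' `baseline_factory` ignores the training fold and applies the
#' co-occurrence baseline (optionally with the same-string filter);
#' `model_factory` trains a per-signature MaxEnt classifier on the
#' training fold.
#'
#' @param signature a [relation_signature()].
#' @param same_string whether to apply [same_string_filter()].
#' @return a factory suitable for [cross_validate()].
#' @export
baseline_factory <- function(signature, same_string = FALSE) {
  function(train_docs) {
    function(doc) {
      same_string_filter(extract_cooccurrence_relations(doc, signature),
                         doc, enabled = same_string)
    }
  }
}

#' @rdname baseline_factory
#' @param cfg a [rule_config()].
#' @param adapter parser adapter.
#' @param parses optional named list of pre-computed [parse_document()]
#'   outputs for the whole corpus (big speed-up across folds).
#' @param l2,max_iter passed to the trainer.
#' @export
model_factory <- function(signature, cfg = default_rule_config(),
                          adapter = template_parser(), parses = NULL,
                          l2 = 1.0, max_iter = 200L) {
  function(train_docs) {
    model <- train_relation_classifier(train_docs, signature, cfg, adapter,
                                       parses = parses, l2 = l2,
                                       max_iter = max_iter)
    function(doc) {
      predict_relations(model, doc, signature, cfg, adapter,
                        parses = if (!is.null(parses)) parses[[doc$doc_id]])
    }
  }
}
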