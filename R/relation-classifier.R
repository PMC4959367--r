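#' Per-signature relation classifiers
#'
#' The evaluation protocol takes gold entities as given: for each studied
#' relation signature, candidate instances are all same-sentence ordered
#' gold entity pairs whose types match the signature's argument types.  A
#' binary MaxEnt classifier (REL / NONE) over the rule-based feature
#' vectors decides which candidates express the relation; its positive
#' predictions are therefore always a subset of the co-occurrence
#' baseline's extractions, so its recall can never exceed the baseline's.
#'
#' @name relation_classifier
NULL

#' Parse every sentence of a bound document once
#'
#' @param doc segmented [brat_document()].
#' @param adapter parser adapter (see [parse_sentence()]).
#' @return list of `parsed_sentence` / `unparsed_sentence`, one per
#'   sentence index.
#' @export
parse_document <- function(doc, adapter = template_parser()) {
  stopifnot(!is.null(doc$sentences))
  lapply(seq_len(nrow(doc$sentences)), function(i) {
    s <- doc$sentences[i, ]
    txt <- text_slice(doc$text, s$start, s$end)
    parse_sentence(txt, adapter)
  })
}

#' Candidate entity pairs for a signature
#'
#' @param doc segmented document.
#' @param signature a [relation_signature()].
#' @return data.frame with columns `sentence`, `arg1`, `arg2` (entity
#'   ids); all same-sentence ordered type-matching pairs with distinct
#'   mention ids.
#' @export
candidate_pairs <- function(doc, signature) {
  stopifnot(!is.null(doc$sentences))
  ents <- doc$entities
  rows <- list()
  for (s in doc$sentences$index) {
    a_set <- ents$id[ents$type == signature$arg1_type & ents$sentence == s]
    b_set <- ents$id[ents$type == signature$arg2_type & ents$sentence == s]
    for (a in a_set) for (b in b_set) {
      if (a != b) rows[[length(rows) + 1L]] <-
          data.frame(sentence = s, arg1 = a, arg2 = b, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(sentence = integer(), arg1 = character(),
                      arg2 = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# feature strings for every candidate pair in a document
candidate_features <- function(doc, cands, parses, cfg) {
  ents <- doc$entities
  lapply(seq_len(nrow(cands)), function(i) {
    s <- cands$sentence[i]
    sent <- doc$sentences[doc$sentences$index == s, ]
    sent_ents <- ents[!is.na(ents$sentence) & ents$sentence == s, , drop = FALSE]
    ctx <- entity_pair_context(
      parses[[s]],
      ents[ents$id == cands$arg1[i], ],
      ents[ents$id == cands$arg2[i], ],
      sent_entities = sent_ents,
      sent_start = sent$start)
    feature_strings(extract_feature_vector(ctx, cfg))
  })
}

# gold label per candidate: REL iff an annotated relation of this
# signature connects exactly these mention ids in this order
candidate_labels <- function(doc, cands, signature) {
  rels <- doc$relations[doc$relations$predicate == signature$predicate, , drop = FALSE]
  key <- paste(rels$arg1, rels$arg2)
  ifelse(paste(cands$arg1, cands$arg2) %in% key, "REL", "NONE")
}

#' Train the binary relation classifier for one signature
#'
#' Positives are candidate pairs attested as gold relations of the
#' signature; negatives are the remaining candidates.
#'
#' @param corpus list of segmented [brat_document()].
#' @param signature a [relation_signature()].
#' @param cfg a [rule_config()].
#' @param adapter parser adapter.
#' @param parses optional pre-computed list of [parse_document()] outputs,
#'   named by doc id (avoids re-parsing across folds).
#' @param l2,max_iter passed to [train_maxent()].
#' @return a `maxent_model` (single-label degenerate model when the
#'   training corpus has no negative candidates).
#' @export
train_relation_classifier <- function(corpus, signature,
                                      cfg = default_rule_config(),
                                      adapter = template_parser(),
                                      parses = NULL, l2 = 1.0,
                                      max_iter = 500L) {
  feats <- list(); labs <- character()
  for (doc in corpus) {
    cands <- candidate_pairs(doc, signature)
    if (!nrow(cands)) next
    pr <- if (!is.null(parses)) parses[[doc$doc_id]] else parse_document(doc, adapter)
    feats <- c(feats, candidate_features(doc, cands, pr, cfg))
    labs <- c(labs, candidate_labels(doc, cands, signature))
  }
  if (!any(labs == "REL")) {
    stop("no positive training candidates for signature ",
         format(signature), call. = FALSE)
  }
  labels <- intersect(c("REL", "NONE"), unique(labs))
  train_maxent(feats, labs, labels = labels, l2 = l2, max_iter = max_iter)
}

#' Predict relation mentions in a document
#'
#' Classifies every candidate pair of the signature and emits those with
#' P(REL) >= 0.5.  Predictions are by construction a subset of
#' [extract_cooccurrence_relations()] on the same document.
#'
#' @param model output of [train_relation_classifier()].
#' @param doc segmented document.
#' @param signature a [relation_signature()].
#' @param cfg a [rule_config()].
#' @param adapter parser adapter.
#' @param parses optional pre-computed [parse_document()] output.
#' @return data.frame of predicted relations (`id`, `predicate`, `arg1`,
#'   `arg2`).
#' @export
predict_relations <- function(model, doc, signature,
                              cfg = default_rule_config(),
                              adapter = template_parser(), parses = NULL) {
  cands <- candidate_pairs(doc, signature)
  if (!nrow(cands)) return(empty_relations())
  pr <- if (!is.null(parses)) parses else parse_document(doc, adapter)
  feats <- candidate_features(doc, cands, pr, cfg)
  P <- predict(model, feats)
  pos <- if ("REL" %in% colnames(P)) which(P[, "REL"] >= 0.5) else integer()
  if (!length(pos)) return(empty_relations())
  data.frame(id = paste0("P", seq_along(pos)),
             predicate = signature$predicate,
             arg1 = cands$arg1[pos], arg2 = cands$arg2[pos],
             cross_sentence = FALSE, stringsAsFactors = FALSE)
}
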