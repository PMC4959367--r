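#' Sentential co-occurrence baseline with semantic type constraints
#'
#' Declares a relation for every ordered pair of same-sentence gold
#' entities whose types match the signature's argument types — the
#' simplest possible relation extractor, and an upper bound on the recall
#' of any sentence-bound method.
#'
#' @param doc segmented [brat_document()] with gold entities.
#' @param signature a [relation_signature()].
#' @return data.frame of extracted relations (`id`, `predicate`, `arg1`,
#'   `arg2`), deduplicated (set semantics).
#' @export
extract_cooccurrence_relations <- function(doc, signature) {
  cands <- candidate_pairs(doc, signature)
  if (!nrow(cands)) return(empty_relations())
  data.frame(id = paste0("C", seq_len(nrow(cands))),
             predicate = signature$predicate,
             arg1 = cands$arg1, arg2 = cands$arg2,
             cross_sentence = FALSE, stringsAsFactors = FALSE)
}

#' Filter relations whose arguments are the same string annotation
#'
#' Removes relations whose two argument mentions have identical character
#' spans (one surface string annotated under two entity types, as with a
#' disease term metonymically annotated as a patient cohort).  Partially
#' overlapping arguments are kept.  The filter is OFF by default in the
#' evaluation pipelines, matching the reported baseline, which did not
#' control for overlapping annotations.
#'
#' @param relations data.frame of relation mentions.
#' @param doc the document the mention ids resolve in.
#' @param enabled when `FALSE`, returns `relations` unchanged.
#' @return filtered data.frame.
#' @export
same_string_filter <- function(relations, doc, enabled = TRUE) {
  if (!enabled || !nrow(relations)) return(relations)
  span <- function(ids) {
    i <- match(ids, doc$entities$id)
    paste(doc$entities$start[i], doc$entities$end[i])
  }
  keep <- span(relations$arg1) != span(relations$arg2)
  relations[keep, , drop = FALSE]
}
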