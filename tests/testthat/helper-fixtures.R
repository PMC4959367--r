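# Hand-built parses and documents used across test files.  All fixtures
# are constructed in code; nothing is read from disk.

# "EPA reduce the vasoconstriction in a dose-dependent manner"
epa_doc <- function() {
  txt <- "EPA reduce the vasoconstriction in a dose-dependent manner"
  doc <- brat_document(
    "epa", txt,
    data.frame(id = c("T1", "T2"), type = c("gene", "body-part"),
               start = c(0L, 15L), end = c(3L, 31L),
               surface = c("EPA", "vasoconstriction"),
               stringsAsFactors = FALSE))
  segment_and_bind(doc)
}

epa_context <- function(doc = epa_doc()) {
  p <- parse_document(doc)[[1]]
  entity_pair_context(p, doc$entities[1, ], doc$entities[2, ],
                      sent_entities = doc$entities, sent_start = 0L)
}

# one-sentence document in the shape of the corpus's metonymic example:
# "cancers" is annotated both as a disease and as a patient cohort on the
# identical span
fig4_style_doc <- function() {
  txt <- "In individuals with germline mutations colorectal cancers were observed ."
  #       0123456789...
  # individuals: 3..14 ; colorectal cancers: 39..57 ; cancers: 50..57
  ents <- data.frame(
    id = c("T1", "T2", "T3", "T4"),
    type = c("cohort", "disease", "disease", "cohort"),
    start = c(3L, 39L, 50L, 50L),
    end = c(14L, 57L, 57L, 57L),
    surface = c("individuals", "colorectal cancers", "cancers", "cancers"),
    stringsAsFactors = FALSE)
  segment_and_bind(brat_document("fig4", txt, ents))
}

# hand-built passive parse: "TP53 is regulated by MDM2"
passive_parsed <- function() {
  tokens <- data.frame(
    index = 1:5,
    surface = c("TP53", "is", "regulated", "by", "MDM2"),
    lemma = c("tp53", "is", "regulated", "by", "mdm2"),
    pos = c("NN", "VBZ", "VBN", "IN", "NN"),
    char_start = c(0L, 5L, 8L, 18L, 21L),
    char_end = c(4L, 7L, 17L, 20L, 25L),
    stringsAsFactors = FALSE)
  arcs <- data.frame(
    head = c(3L, 3L, 3L),
    dep = c(1L, 2L, 5L),
    label = c("nsubjpass", "auxpass", "prep_by"),
    stringsAsFactors = FALSE)
  tree <- "(S (NP (NN TP53)) (VP (VBZ is) (VP (VBN regulated) (PP (IN by) (NP (NN MDM2))))))"
  parsed_sentence(tokens, arcs, tree)
}

pair_ctx_from_parsed <- function(parsed, e1_tok, e2_tok, types = c("gene", "gene")) {
  tk <- parsed$tokens
  ents <- data.frame(
    id = c("T1", "T2"), type = types,
    start = tk$char_start[c(e1_tok, e2_tok)],
    end = tk$char_end[c(e1_tok, e2_tok)],
    surface = tk$surface[c(e1_tok, e2_tok)],
    stringsAsFactors = FALSE)
  entity_pair_context(parsed, ents[1, ], ents[2, ],
                      sent_entities = ents, sent_start = 0L)
}

# ---- random trees and exhaustive oracles ------------------------------

# random tree with n nodes, branching capped at 3; returns indexed tree
rand_tree <- function(n) {
  stopifnot(n >= 1L)
  kids <- vector("list", n)
  if (n > 1L) {
    for (i in 2:n) {
      open <- which(vapply(kids[seq_len(i - 1L)], length, integer(1)) < 3L)
      p <- if (length(open) == 1L) open else sample(open, 1L)
      kids[[p]] <- c(kids[[p]], i)
    }
  }
  build <- function(i) {
    ch <- lapply(kids[[i]], build)
    structure(list(label = if (length(ch)) "X" else "W", children = ch,
                   word = if (length(ch)) NULL else "w",
                   start = NA_integer_, end = NA_integer_, id = NA_integer_),
              class = "const_node")
  }
  index_tree(build(1L))
}

# parent vector and ancestor bitmasks for a tree (ids are preorder)
tree_anc_masks <- function(tree) {
  parent <- bratrelex:::tree_parents(tree)
  n <- length(parent)
  masks <- integer(n)
  for (i in seq_len(n)) {
    m <- 0L; p <- parent[i]
    while (!is.na(p)) { m <- bitwOr(m, bitwShiftL(1L, p - 1L)); p <- parent[p] }
    masks[i] <- m
  }
  masks
}

# brute-force maximum over all valid ARG/NONE labelings (filtered 2^n scan)
oracle_nonoverlap_max <- function(tree, probs) {
  n <- attr(tree, "n_nodes")
  masks <- tree_anc_masks(tree)
  best <- -Inf
  for (s in 0:(2^n - 1L)) {
    arg <- which(bitwAnd(s, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    if (any(bitwAnd(masks[arg], s) != 0L)) next  # ancestor also ARG: invalid
    score <- prod(ifelse(seq_len(n) %in% arg, probs[seq_len(n)],
                         1 - probs[seq_len(n)]))
    if (score > best) best <- score
  }
  best
}

# enumerate ALL valid joint typings (recursive, no pruning) and return
# their probabilities sorted descending
oracle_typing_probs <- function(tree, type_probs) {
  types <- colnames(type_probs)
  non_none <- setdiff(types, "NONE")
  none_prob <- function(node) {
    p <- type_probs[node$id, "NONE"]
    for (ch in node$children) p <- p * none_prob(ch)
    p
  }
  enum <- function(node) {
    out <- numeric()
    below_none <- prod(vapply(node$children, none_prob, numeric(1)))
    for (t in non_none) out <- c(out, type_probs[node$id, t] * below_none)
    child_lists <- lapply(node$children, enum)
    combo <- type_probs[node$id, "NONE"]
    for (cl in child_lists) combo <- as.numeric(outer(combo, cl))
    c(out, combo)
  }
  sort(unname(enum(tree)), decreasing = TRUE)
}

# brute-force double loop over sentence entity pairs (baseline oracle)
oracle_cooccurrence <- function(doc, signature) {
  out <- character()
  for (s in doc$sentences$index) {
    ents <- doc$entities[!is.na(doc$entities$sentence) &
                         doc$entities$sentence == s, , drop = FALSE]
    for (i in seq_len(nrow(ents))) for (j in seq_len(nrow(ents))) {
      if (i == j) next
      if (ents$type[i] == signature$arg1_type &&
          ents$type[j] == signature$arg2_type) {
        out <- c(out, paste(ents$id[i], ents$id[j]))
      }
    }
  }
  sort(unique(out))
}

# gold relations of one signature (re-derived here so tests do not lean
# on the package's internal helper)
gold_relations_for_test <- function(doc, sig) {
  type_of <- stats::setNames(doc$entities$type, doc$entities$id)
  keep <- doc$relations$predicate == sig$predicate &
    type_of[doc$relations$arg1] == sig$arg1_type &
    type_of[doc$relations$arg2] == sig$arg2_type
  doc$relations[keep, , drop = FALSE]
}

# small, fast synthetic corpus for classifier tests
small_synth <- function(n_docs = 24L, seed = 11L, ...) {
  generate_corpus(synth_config(n_docs = n_docs, ...), seed = seed)
}
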