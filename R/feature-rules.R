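#' Entity-pair feature extraction
#'
#' The feature rules turn one (entity pair, parsed sentence) context into a
#' named feature vector.  There are 19 rules in three families — 7
#' syntactic (verb in dependency path, no verb in path, contains clause,
#' clause distance, same head, full tree path, path length), 8 lexical
#' (negation, voice, words between, surface distance, left/right windows,
#' nominalization, weak nominalization) and 4 supplementary (number of
#' entities between, entities in between, entity counts, entity order) —
#' plus the entity-type tags of the two arguments.  Extraction is a pure
#' function of the context and configuration.
#'
#' @name feature_rules
NULL

#' Build the context for one candidate entity pair
#'
#' `e1` is always the entity that precedes in text; `arg1_is_first` records
#' whether the signature's first argument is that entity.
#'
#' @param parsed a `parsed_sentence` (or `unparsed_sentence`).
#' @param arg1,arg2 entity rows (document offsets) playing the signature's
#'   first and second argument role.
#' @param sent_entities data.frame of all gold entities in the sentence.
#' @param sent_start 0-based document offset of the sentence start, used to
#'   rebase entity offsets onto the sentence-local token offsets.
#' @return object of class `pair_context`.
#' @export
entity_pair_context <- function(parsed, arg1, arg2, sent_entities = NULL,
                                sent_start = 0L) {
  swap <- arg2$start < arg1$start
  first <- if (swap) arg2 else arg1
  second <- if (swap) arg1 else arg2
  mk <- function(e) {
    out <- list(id = e$id, type = e$type,
                start = e$start - sent_start, end = e$end - sent_start)
    if (inherits(parsed, "parsed_sentence")) {
      rng <- entity_token_range(parsed, out$start, out$end)
      if (is.null(rng)) stop("entity '", e$id, "' is not token-aligned", call. = FALSE)
      out$tok_lo <- rng[1]; out$tok_hi <- rng[2]
      out$node <- anchor_entity_node(list(id = e$id, start = out$start,
                                          end = out$end), parsed)
      out$head_tok <- find_head_token(out$node)
    }
    out
  }
  ents <- NULL
  if (!is.null(sent_entities) && nrow(sent_entities)) {
    ents <- sent_entities
    ents$start <- ents$start - sent_start
    ents$end <- ents$end - sent_start
    if (inherits(parsed, "parsed_sentence")) {
      rngs <- lapply(seq_len(nrow(ents)), function(i)
        entity_token_range(parsed, ents$start[i], ents$end[i]))
      ents$tok_lo <- vapply(rngs, function(r) if (is.null(r)) NA_integer_ else r[1], integer(1))
      ents$tok_hi <- vapply(rngs, function(r) if (is.null(r)) NA_integer_ else r[2], integer(1))
    }
  }
  structure(list(parsed = parsed, e1 = mk(first), e2 = mk(second),
                 arg1_is_first = !swap,
                 arg1_type = arg1$type, arg2_type = arg2$type,
                 sent_entities = ents),
            class = "pair_context")
}

# token indices lying on the dependency path between the entity heads,
# including both endpoints
path_token_set <- function(path, a, b) {
  unique(c(a, path$from, path$to, b))
}

# dependency path between the two entity heads; empty when the heads
# coincide (same-string multi-type annotations produce such pairs)
pair_dep_path <- function(ctx) {
  if (ctx$e1$head_tok == ctx$e2$head_tok) {
    return(data.frame(from = integer(), to = integer(), label = character(),
                      dir = character(), stringsAsFactors = FALSE))
  }
  dependency_path(ctx$parsed, ctx$e1$head_tok, ctx$e2$head_tok)
}

ft_verb_path <- function(ctx, cfg) {
  path <- pair_dep_path(ctx)
  toks <- ctx$parsed$tokens
  on_path <- setdiff(path_token_set(path, ctx$e1$head_tok, ctx$e2$head_tok),
                     c(ctx$e1$head_tok, ctx$e2$head_tok))
  verbs <- on_path[startsWith(toks$pos[on_path], "VB")]
  sig <- paste(paste0(path$label, ":", path$dir), collapse = "|")
  if (!length(verbs)) {
    return(list(no_verb_in_path = TRUE, dep_path = sig,
                dep_path_length = nrow(path)))
  }
  depth <- dep_depth(ctx$parsed)
  anchor <- verbs[order(depth[verbs], verbs)][1]  # root-most verb wins
  lemma <- toks$lemma[anchor]
  cls <- if (lemma %in% names(cfg$verb_lexicon)) unname(cfg$verb_lexicon[[lemma]]) else "NONE"
  # which sides of the anchor verb carry path steps
  nodes_seq <- c(path$from[1], path$to)
  pos_anchor <- match(anchor, nodes_seq)
  sides <- if (pos_anchor == 1L) "right"
           else if (pos_anchor == length(nodes_seq)) "left" else "both"
  list(no_verb_in_path = FALSE, dep_path = sig, dep_path_length = nrow(path),
       verb_path_verb = lemma, verb_path_class = cls, verb_path_sides = sides,
       verb_path_anchor = anchor)
}

ft_clause <- function(ctx) {
  nodes <- tree_nodes(ctx$parsed$tree)
  sbars <- Filter(function(n) n$label == "SBAR", nodes)
  e1 <- ctx$e1; e2 <- ctx$e2
  if (!length(sbars)) {
    return(list(contains_clause = FALSE, sbar_between = FALSE,
                clause_distance_e1 = 999L, clause_distance_e2 = 999L))
  }
  inside <- function(e, s) s$start <= e$tok_lo && e$tok_hi <= s$end
  strictly_between <- function(s) s$start > e1$tok_hi && s$end < e2$tok_lo
  separates <- vapply(sbars, function(s) {
    xor(inside(e1, s), inside(e2, s)) || strictly_between(s)
  }, logical(1))
  dist_to <- function(e) {
    signed <- vapply(sbars, function(s) {
      if (inside(e, s)) 0L
      else if (e$tok_hi < s$start) -(s$start - e$tok_hi)  # entity left of clause
      else if (e$tok_lo > s$end) e$tok_lo - s$end         # entity right of clause
      else 0L  # overlapping boundary
    }, integer(1))
    signed[which.min(abs(signed))]
  }
  list(contains_clause = TRUE, sbar_between = any(separates),
       clause_distance_e1 = dist_to(e1), clause_distance_e2 = dist_to(e2))
}

ft_tree_path <- function(ctx) {
  tree <- ctx$parsed$tree
  parent <- tree_parents(tree)
  nodes <- tree_nodes(tree)
  labs <- vapply(nodes, `[[`, character(1), "label")
  chain <- function(id) { out <- id; while (!is.na(parent[id])) { id <- parent[id]; out <- c(out, id) }; out }
  c1 <- chain(ctx$e1$node$id); c2 <- chain(ctx$e2$node$id)
  lca <- intersect(c1, c2)[1]
  up <- c1[seq_len(match(lca, c1))]
  down <- rev(c2[seq_len(match(lca, c2))])
  path_ids <- c(up, down[-1])
  same_head <- identical(parent[ctx$e1$node$id], parent[ctx$e2$node$id]) &&
    !is.na(parent[ctx$e1$node$id])
  list(same_head = same_head,
       tree_path = paste(labs[path_ids], collapse = "-"),
       tree_path_length = length(path_ids) - 1L)
}

ft_negation <- function(ctx, cfg) {
  path <- pair_dep_path(ctx)
  on_path <- path_token_set(path, ctx$e1$head_tok, ctx$e2$head_tok)
  arcs <- ctx$parsed$arcs
  toks <- ctx$parsed$tokens
  # scope restricted to the inter-entity path: a NEG arc attaching to a
  # path token, or a negation-lexicon word standing in a direct dependency
  # with a verb on the path ("fails to reduce")
  neg <- any(arcs$label == "neg" & arcs$head %in% on_path)
  if (!neg && length(cfg$negation_words)) {
    path_verbs <- on_path[startsWith(toks$pos[on_path], "VB")]
    if (length(path_verbs)) {
      lem <- toks$lemma
      neg <- any((arcs$head %in% path_verbs &
                    lem[arcs$dep] %in% cfg$negation_words) |
                 (arcs$dep %in% path_verbs &
                    lem[arcs$head] %in% cfg$negation_words))
    }
  }
  list(negated = neg)
}

ft_voice <- function(ctx) {
  path <- pair_dep_path(ctx)
  on_path <- path_token_set(path, ctx$e1$head_tok, ctx$e2$head_tok)
  arcs <- ctx$parsed$arcs
  list(passive = any(arcs$label == "auxpass" & arcs$head %in% on_path))
}

ft_lexical <- function(ctx, cfg) {
  toks <- ctx$parsed$tokens
  n <- nrow(toks)
  e1 <- ctx$e1; e2 <- ctx$e2
  between <- if (e2$tok_lo - e1$tok_hi > 1L) seq(e1$tok_hi + 1L, e2$tok_lo - 1L) else integer()
  k <- cfg$window_k
  left <- if (e1$tok_lo > 1L) seq(max(1L, e1$tok_lo - k), e1$tok_lo - 1L) else integer()
  right <- if (e2$tok_hi < n) seq(e2$tok_hi + 1L, min(n, e2$tok_hi + k)) else integer()
  win <- function(ix) {
    if (!length(ix)) character() else
      paste0(toks$lemma[ix], "/", toks$simple_pos[ix])
  }
  list(
    words_between = paste(toks$lemma[between], collapse = " "),
    words_between_tokens = toks$lemma[between],
    window_left_e1 = win(left),
    window_right_e2 = win(right),
    surface_distance = e2$tok_hi - e1$tok_lo + 1L
  )
}

# does entity e sit after a preposition with a lexicon nominalization
# ahead of that preposition?
nom_prep_pattern <- function(e, parsed, lex) {
  toks <- parsed$tokens
  p <- e$tok_lo - 1L
  while (p >= 1L && p >= e$tok_lo - 2L) {
    if (toks$pos[p] == "IN") {
      lo <- max(1L, p - 3L)
      if (p > 1L && any(toks$lemma[seq(lo, p - 1L)] %in% lex)) return(TRUE)
      return(FALSE)
    }
    p <- p - 1L
  }
  FALSE
}

ft_nominalization <- function(ctx, cfg) {
  lex <- cfg$nominalization_lexicon
  if (!length(lex)) {
    return(list(nominalization = FALSE, weak_nominalization = FALSE,
                nominalization_side = "none", nominalization_distance = 999L))
  }
  parsed <- ctx$parsed
  toks <- parsed$tokens
  h <- dep_head_of(parsed)
  up2 <- function(i) {
    out <- integer()
    if (h$head[i] != 0L) { out <- h$head[i]
      if (h$head[out] != 0L) out <- c(out, h$head[out]) }
    out
  }
  e1 <- ctx$e1; e2 <- ctx$e2
  cand <- intersect(up2(e1$head_tok), up2(e2$head_tok))
  cand <- cand[toks$lemma[cand] %in% lex &
               !(cand %in% c(e1$head_tok, e2$head_tok))]
  strict <- length(cand) > 0L
  side <- "none"; dist <- 999L
  if (strict) {
    t <- cand[1]
    d1 <- min(abs(t - e1$tok_lo), abs(t - e1$tok_hi))
    d2 <- min(abs(t - e2$tok_lo), abs(t - e2$tok_hi))
    if (d1 <= d2) { side <- if (t < e1$tok_lo) "left" else "right"; dist <- d1 }
    else { side <- if (t < e2$tok_lo) "left" else "right"; dist <- d2 }
  }
  weak <- !strict && xor(nom_prep_pattern(e1, parsed, lex),
                         nom_prep_pattern(e2, parsed, lex))
  list(nominalization = strict, weak_nominalization = weak,
       nominalization_side = side, nominalization_distance = dist)
}

ft_supplementary <- function(ctx) {
  ents <- ctx$sent_entities
  e1 <- ctx$e1; e2 <- ctx$e2
  between_types <- character()
  total <- 0L
  if (!is.null(ents) && nrow(ents)) {
    total <- nrow(ents)
    others <- ents[!(ents$id %in% c(e1$id, e2$id)), , drop = FALSE]
    between <- others[others$start >= e1$end & others$end <= e2$start, , drop = FALSE]
    between_types <- sort(between$type)
  }
  list(
    n_entities_between = length(between_types),
    entities_between_types = paste(between_types, collapse = "+"),
    entity_counts = total,
    entity_order = if (ctx$arg1_is_first) "arg1_first" else "arg2_first",
    arg1_type = ctx$arg1_type,
    arg2_type = ctx$arg2_type
  )
}

# lexical + supplementary fallback when the sentence could not be parsed:
# whitespace tokens stand in for the parser's tokenisation
ft_unparsed <- function(ctx, cfg) {
  list(unparsed = TRUE)
}

#' Extract the full feature vector for an entity pair
#'
#' Concatenates all rule outputs under stable names.  On an
#' `unparsed_sentence` only the supplementary (entity-based) features and
#' an `unparsed` flag are emitted.
#'
#' @param ctx a [entity_pair_context()].
#' @param cfg a [rule_config()].
#' @return named list of feature values.
#' @export
extract_feature_vector <- function(ctx, cfg = default_rule_config()) {
  supp <- ft_supplementary(ctx)
  if (!inherits(ctx$parsed, "parsed_sentence")) {
    return(c(ft_unparsed(ctx, cfg), supp))
  }
  vp <- ft_verb_path(ctx, cfg)
  vp$verb_path_anchor <- NULL
  out <- c(
    vp,
    ft_clause(ctx),
    ft_tree_path(ctx),
    ft_negation(ctx, cfg),
    ft_voice(ctx),
    ft_lexical(ctx, cfg),
    ft_nominalization(ctx, cfg),
    supp
  )
  out
}

bucket_int <- function(x) {
  if (x >= 999L) "inf" else if (x <= -999L) "-inf"
  else if (abs(x) <= 5L) as.character(x)
  else if (abs(x) <= 10L) paste0(sign(x) * 6L, "-", sign(x) * 10L)
  else if (x > 0L) ">10" else "<-10"
}

#' Flatten a feature vector into sparse indicator strings
#'
#' Booleans and categories become `name=value` indicators; integer-valued
#' features are bucketed; token sequences contribute one indicator per
#' token plus one for the whole sequence.  These strings are the feature
#' space of the maximum-entropy classifiers.
#'
#' @param fv output of [extract_feature_vector()].
#' @return character vector of active indicator features.
#' @export
feature_strings <- function(fv) {
  out <- character()
  for (nm in names(fv)) {
    v <- fv[[nm]]
    if (nm %in% c("words_between_tokens", "window_left_e1", "window_right_e2")) {
      if (length(v)) out <- c(out, paste0(nm, "=", v))
    } else if (is.numeric(v)) {
      out <- c(out, paste0(nm, "=", bucket_int(as.integer(v))))
    } else {
      out <- c(out, paste0(nm, "=", as.character(v)))
    }
  }
  unique(out)
}
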