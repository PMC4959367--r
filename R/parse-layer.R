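#' Parsed sentences
#'
#' A `parsed_sentence` carries the full syntactic substrate the feature
#' rules operate on: tokens with POS tags and character offsets, a
#' dependency graph in Stanford-dependencies-style labels (`nsubj`,
#' `dobj`, `prep_*`, `neg`, `auxpass`, ...), and a constituency tree whose
#' nodes carry Collins heads.
#'
#' @param tokens data.frame with columns `index` (1-based, contiguous),
#'   `surface`, `lemma`, `pos`, and optionally `char_start`, `char_end`
#'   (0-based document offsets).
#' @param arcs data.frame with columns `head`, `dep` (token indices; head 0
#'   marks the root) and `label`.
#' @param tree root `const_node` covering the same token sequence, or the
#'   bracket string for one.
#' @return object of class `parsed_sentence`.
#' @export
parsed_sentence <- function(tokens, arcs, tree) {
  tokens <- as.data.frame(tokens, stringsAsFactors = FALSE)
  if (is.null(tokens$lemma)) tokens$lemma <- tolower(tokens$surface)
  if (is.null(tokens$index)) tokens$index <- seq_len(nrow(tokens))
  stopifnot(identical(tokens$index, seq_len(nrow(tokens))))
  tokens$simple_pos <- simplify_pos(tokens$pos)
  arcs <- as.data.frame(arcs, stringsAsFactors = FALSE)
  if (is.character(tree)) tree <- read_ptb_tree(tree)
  if (!is.na(tree$end) && tree$end != nrow(tokens)) {
    stop("constituency tree covers ", tree$end, " tokens but sentence has ",
         nrow(tokens), call. = FALSE)
  }
  # each non-root token must have exactly one head; graph must be a tree
  if (nrow(arcs)) {
    dep_counts <- table(factor(arcs$dep[arcs$label != "_extra"],
                               levels = tokens$index))
    if (any(dep_counts > 1L)) {
      stop("token has more than one dependency head", call. = FALSE)
    }
  }
  structure(list(tokens = tokens, arcs = arcs, tree = tree),
            class = "parsed_sentence")
}

#' @export
print.parsed_sentence <- function(x, ...) {
  cat(sprintf("<parsed_sentence> %d tokens: %s\n", nrow(x$tokens),
              paste(x$tokens$surface, collapse = " ")))
  invisible(x)
}

#' Simplify Penn Treebank tags into seven categories
#'
#' `NN*` -> noun, `VB*` -> verb, `RB*` -> adverb, `JJ*` -> adjective,
#' `CD` -> number, `FW` -> foreign, everything else -> other.
#'
#' @param pos character vector of Penn tags.
#' @return character vector over
#'   `{noun, verb, adverb, adjective, number, foreign, other}`.
#' @export
simplify_pos <- function(pos) {
  out <- rep("other", length(pos))
  out[startsWith(pos, "NN")] <- "noun"
  out[startsWith(pos, "VB")] <- "verb"
  out[startsWith(pos, "RB")] <- "adverb"
  out[startsWith(pos, "JJ")] <- "adjective"
  out[pos == "CD"] <- "number"
  out[pos == "FW"] <- "foreign"
  out
}

#' Parse one sentence through an adapter
#'
#' The adapter contract decouples the feature rules from any particular
#' parser: an adapter is a function (or list with a `$parse` function)
#' mapping sentence text to the `tokens` / `arcs` / `tree` triple accepted
#' by [parsed_sentence()], with tokenisation offset-aligned to the input.
#' Parsing is deterministic for a fixed adapter and input.  An adapter
#' failure yields an object of class `unparsed_sentence`, which downstream
#' feature extraction treats as "lexical and supplementary features only".
#'
#' @param sentence_text the sentence string (non-empty).
#' @param adapter parser adapter; defaults to [template_parser()].
#' @return a `parsed_sentence`, or an `unparsed_sentence` on adapter
#'   failure.
#' @export
parse_sentence <- function(sentence_text, adapter = template_parser()) {
  if (!nzchar(trimws(sentence_text))) stop("empty sentence", call. = FALSE)
  fn <- if (is.function(adapter)) adapter else adapter$parse
  res <- tryCatch(fn(sentence_text), error = function(e) e)
  if (inherits(res, "error")) {
    return(structure(list(text = sentence_text, reason = conditionMessage(res)),
                     class = "unparsed_sentence"))
  }
  res
}

# ---- dependency graph utilities ---------------------------------------

# adjacency: for token i, its head (0 if root) and label
dep_head_of <- function(parsed) {
  n <- nrow(parsed$tokens)
  head <- rep(0L, n); lab <- rep(NA_character_, n)
  core <- parsed$arcs[parsed$arcs$label != "_extra", , drop = FALSE]
  head[core$dep] <- core$head
  lab[core$dep] <- core$label
  list(head = head, label = lab)
}

#' Undirected dependency path between two tokens
#'
#' Returns the unique tree path from `a` to `b`, one row per step, with the
#' arc `label` and a `dir`ection: `"up"` when moving from a dependent to
#' its head, `"down"` when descending.  Reversing the path and flipping
#' directions gives the `b`-to-`a` path.
#'
#' @param parsed a `parsed_sentence`.
#' @param a,b distinct token indices.
#' @return data.frame with columns `from`, `to`, `label`, `dir`.
#' @export
dependency_path <- function(parsed, a, b) {
  stopifnot(a != b)
  h <- dep_head_of(parsed)
  anc <- function(i) { out <- i; while (h$head[i] != 0L) { i <- h$head[i]; out <- c(out, i) }; out }
  anc_a <- anc(a); anc_b <- anc(b)
  common <- intersect(anc_a, anc_b)
  if (!length(common)) stop("disconnected dependency graph", call. = FALSE)
  lca <- common[1]  # first common ancestor along a's chain (nearest)
  up <- anc_a[seq_len(match(lca, anc_a))]      # a .. lca
  down <- rev(anc_b[seq_len(match(lca, anc_b))])  # lca .. b
  steps <- list()
  if (length(up) > 1L) {
    for (i in seq_len(length(up) - 1L)) {
      steps[[length(steps) + 1L]] <- data.frame(
        from = up[i], to = up[i + 1L], label = h$label[up[i]], dir = "up",
        stringsAsFactors = FALSE)
    }
  }
  if (length(down) > 1L) {
    for (i in seq_len(length(down) - 1L)) {
      steps[[length(steps) + 1L]] <- data.frame(
        from = down[i], to = down[i + 1L], label = h$label[down[i + 1L]],
        dir = "down", stringsAsFactors = FALSE)
    }
  }
  if (!length(steps)) {
    return(data.frame(from = integer(), to = integer(), label = character(),
                      dir = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, steps)
}

# depth of each token in the dependency tree (root = 0)
dep_depth <- function(parsed) {
  h <- dep_head_of(parsed)
  n <- length(h$head)
  vapply(seq_len(n), function(i) {
    d <- 0L
    while (h$head[i] != 0L) { i <- h$head[i]; d <- d + 1L }
    d
  }, integer(1))
}

# ---- entity anchoring --------------------------------------------------

# token index range covered by a character span (0-based half-open), using
# tokens' char offsets; a token belongs if it overlaps the span
entity_token_range <- function(parsed, start, end) {
  tk <- parsed$tokens
  hit <- which(tk$char_start < end & tk$char_end > start)
  if (!length(hit)) return(NULL)
  c(min(hit), max(hit))
}

# smallest node whose span is exactly [lo, hi]; NULL if none
exact_span_node <- function(root, lo, hi) {
  best <- NULL
  walk <- function(node) {
    if (node$start > hi || node$end < lo) return()
    if (node$start == lo && node$end == hi) best <<- node  # deeper wins
    for (ch in node$children) walk(ch)
  }
  walk(root)
  best
}

#' Anchor an entity mention to a constituency node
#'
#' If a node spans exactly the entity's tokens, the smallest such node is
#' returned.  Otherwise tokens are trimmed from the end of the span until a
#' covering node exists; if suffix trimming exhausts the span, trimming
#' restarts from the beginning.  As a last resort the pre-terminal of the
#' entity's head-most token (the token whose dependency head lies outside
#' the entity) is returned.
#'
#' @param entity one row of a document's `entities` table.
#' @param parsed a `parsed_sentence` with `char_start`/`char_end` on its
#'   tokens.
#' @return a `const_node` overlapping the entity's tokens.
#' @export
anchor_entity_node <- function(entity, parsed) {
  rng <- entity_token_range(parsed, entity$start, entity$end)
  if (is.null(rng)) stop("entity '", entity$id, "' covers no tokens", call. = FALSE)
  lo <- rng[1]; hi <- rng[2]
  # suffix trimming
  for (h in hi:lo) {
    node <- exact_span_node(parsed$tree, lo, h)
    if (!is.null(node)) return(node)
  }
  # prefix trimming
  for (l in lo:hi) {
    node <- exact_span_node(parsed$tree, l, hi)
    if (!is.null(node)) return(node)
  }
  # fallback: pre-terminal of the head-most token in the range
  h <- dep_head_of(parsed)
  inside <- seq(lo, hi)
  headmost <- inside[which(!(h$head[inside] %in% inside))]
  tok <- if (length(headmost)) headmost[1] else hi
  exact_span_node(parsed$tree, tok, tok)
}

# parent map: id -> parent id (NA for root), computed once per tree
tree_parents <- function(root) {
  n <- attr(root, "n_nodes") %||% count_nodes(root)
  parent <- rep(NA_integer_, n)
  walk <- function(node) {
    for (ch in node$children) {
      parent[ch$id] <<- node$id
      walk(ch)
    }
  }
  walk(root)
  parent
}
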