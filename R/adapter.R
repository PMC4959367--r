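#' Deterministic parser adapter for controlled template language
#'
#' The feature rules only need tokens, POS tags, Stanford-style dependency
#' arcs and a constituency tree; they do not care where these come from.
#' This adapter is a small deterministic rule parser for the controlled
#' subject-verb-object / prepositional language produced by
#' [generate_corpus()]: determiner + noun chunks, verb groups (with
#' passive `was/were + participle` and `not` negation), prepositional
#' attachment, `and` coordination, and one optional subordinate clause
#' introduced by `although`/`because`/`while`.  It is NOT a general English
#' parser; arbitrary prose should be parsed externally and supplied as
#' CoNLL-style tables via [parsed_sentence()].
#'
#' @param verbs character vector of verb surface forms the adapter should
#'   tag as verbs (defaults to the shipped verb lexicon plus common
#'   neutral verbs).
#' @return an adapter function usable with [parse_sentence()].
#' @export
template_parser <- function(verbs = NULL) {
  if (is.null(verbs)) {
    lex <- default_rule_config()$verb_lexicon
    verbs <- unique(c(names(lex),
                      "developed", "carried", "harboured", "examined",
                      "studied", "screened", "observed", "reported",
                      "recruited", "enrolled", "showed", "affected",
                      "confirmed", "noted", "assessed"))
  }
  verbs <- unique(tolower(verbs))
  force(verbs)
  function(text) parse_template_sentence(text, verbs)
}

TEMPLATE_DETS <- c("the", "a", "an", "all", "this", "these", "several")
TEMPLATE_PREPS <- c("of", "in", "with", "by", "for", "from", "among", "at", "on")
TEMPLATE_SUBORD <- c("although", "because", "while", "whereas")
TEMPLATE_AUX <- c("was", "were", "is", "are")

template_tokenize <- function(text) {
  words <- list(); starts <- integer()
  m <- gregexpr("\\S+", text, perl = TRUE)[[1]]
  raw <- regmatches(text, list(m))[[1]]
  pos0 <- as.integer(m) - 1L  # 0-based
  for (i in seq_along(raw)) {
    w <- raw[i]; s <- pos0[i]
    while (nchar(w) > 1L && grepl("[.,!?;]$", w)) {
      p <- substr(w, nchar(w), nchar(w))
      w2 <- substr(w, 1L, nchar(w) - 1L)
      words[[length(words) + 1L]] <- list(w = w2, s = s)
      words[[length(words) + 1L]] <- list(w = p, s = s + nchar(w2))
      w <- ""
      break
    }
    if (nzchar(w)) words[[length(words) + 1L]] <- list(w = w, s = s)
  }
  data.frame(
    surface = vapply(words, `[[`, character(1), "w"),
    char_start = vapply(words, function(x) x$s, integer(1)),
    stringsAsFactors = FALSE
  )
}

template_tag <- function(surface, verbs) {
  lw <- tolower(surface)
  vapply(seq_along(surface), function(i) {
    w <- lw[i]
    if (w %in% TEMPLATE_DETS) "DT"
    else if (w %in% TEMPLATE_AUX) if (w %in% c("was", "were")) "VBD" else "VBZ"
    else if (w == "not") "RB"
    else if (w %in% TEMPLATE_SUBORD) "IN"
    else if (w %in% TEMPLATE_PREPS) "IN"
    else if (w %in% c("and", "or")) "CC"
    else if (grepl("^[0-9]+([.,][0-9]+)?$", w)) "CD"
    else if (w %in% c(".", "!", "?")) "."
    else if (w %in% c(",", ";")) ","
    else if (w %in% verbs) "VBD"
    else "NN"
  }, character(1))
}

# parse a clause (token index range, no trailing punctuation); returns
# list(arcs = data.frame, tree = const_node children list, root = verb or
# head token index)
parse_template_clause <- function(tok, idx) {
  pos <- tok$pos[idx]
  arcs <- list()
  add_arc <- function(head, dep, label) {
    arcs[[length(arcs) + 1L]] <<- data.frame(head = head, dep = dep,
                                             label = label, stringsAsFactors = FALSE)
  }
  pre <- function(i) const_node(tok$pos[i], word = tok$surface[i])

  # locate main verb group: aux? (not)? verb  (first verbal token pattern)
  verb_pos <- idx[pos %in% c("VBD", "VBZ")]
  aux_i <- NA_integer_; neg_i <- NA_integer_; verb_i <- NA_integer_
  passive <- FALSE
  if (length(verb_pos)) {
    v1 <- verb_pos[1]
    if (tolower(tok$surface[v1]) %in% TEMPLATE_AUX) {
      rest <- idx[idx > v1]
      j <- v1 + 1L
      if (j %in% idx && tok$pos[j] == "RB") { neg_i <- j; j <- j + 1L }
      if (j %in% idx && tok$pos[j] %in% c("VBD", "VBZ") &&
          !(tolower(tok$surface[j]) %in% TEMPLATE_AUX)) {
        aux_i <- v1; verb_i <- j; passive <- TRUE
      } else {
        verb_i <- v1  # copular-ish; treat aux as main verb
        if (!is.na(neg_i) && neg_i > v1) neg_i <- neg_i
      }
    } else {
      verb_i <- v1
      if ((v1 - 1L) %in% idx && tok$pos[v1 - 1L] == "RB") neg_i <- v1 - 1L
    }
  }

  # chunk NPs: maximal runs of DT/JJ/NN/CD outside the verb group
  np_of <- rep(NA_integer_, max(idx))
  nps <- list()
  i <- 1L
  ii <- setdiff(idx, c(aux_i, verb_i, neg_i))
  run <- integer()
  flush_np <- function() {
    if (length(run)) {
      nouns <- run[tok$pos[run] %in% c("NN", "CD")]
      head <- if (length(nouns)) nouns[length(nouns)] else run[length(run)]
      nps[[length(nps) + 1L]] <<- list(toks = run, head = head)
      run <<- integer()
    }
  }
  for (i in idx) {
    if (i %in% ii && tok$pos[i] %in% c("DT", "NN", "CD")) {
      run <- c(run, i)
    } else flush_np()
  }
  flush_np()

  np_nodes <- list()
  for (k in seq_along(nps)) {
    np <- nps[[k]]
    for (t in np$toks) {
      if (t == np$head) next
      lab <- switch(tok$pos[t], DT = "det", CD = "num", "nn")
      add_arc(np$head, t, lab)
    }
    # nest the nominal under the determiner so multi-word entities have
    # an exactly-spanning node ("the colorectal cancer" -> NP over DT+NP)
    dts <- np$toks[tok$pos[np$toks] == "DT"]
    rest <- setdiff(np$toks, dts)
    np_nodes[[k]] <- if (length(dts) && length(rest) && all(dts < min(rest))) {
      const_node("NP", c(lapply(dts, pre),
                         list(const_node("NP", lapply(rest, pre)))))
    } else {
      const_node("NP", lapply(np$toks, pre))
    }
  }
  np_start <- vapply(nps, function(x) x$toks[1], integer(1))
  np_head <- vapply(nps, function(x) x$head, integer(1))

  has_verb <- !is.na(verb_i)
  subj_k <- if (has_verb && any(np_start < verb_i)) max(which(np_start < verb_i)) else NA_integer_
  # actually the subject is the FIRST np before the verb; later pre-verb
  # NPs are PP objects attached below it
  if (has_verb && any(np_start < verb_i)) subj_k <- which(np_start < verb_i)[1]
  obj_k <- if (has_verb) {
    after <- which(np_start > verb_i)
    # object NP = first post-verb NP not introduced by a preposition
    after_noprep <- after[vapply(after, function(k) {
      p <- np_start[k] - 1L
      !(p %in% idx && tok$pos[p] == "IN")
    }, logical(1))]
    if (length(after_noprep)) after_noprep[1] else NA_integer_
  } else NA_integer_

  if (has_verb) {
    if (!is.na(aux_i)) add_arc(verb_i, aux_i, "auxpass")
    if (!is.na(neg_i)) add_arc(verb_i, neg_i, "neg")
    if (!is.na(subj_k)) {
      add_arc(verb_i, np_head[subj_k], if (passive) "nsubjpass" else "nsubj")
    }
    if (!is.na(obj_k)) add_arc(verb_i, np_head[obj_k], "dobj")
  }

  # prepositional attachment: a PP attaches to the current anchor -- the
  # first NP head of its region (pre-verb region anchors at the subject,
  # post-verb region at the object if present, else at the verb)
  cc_pending <- NA_integer_
  for (k in seq_along(nps)) {
    s <- np_start[k]
    p <- s - 1L
    introduced_by_prep <- p %in% idx && tok$pos[p] == "IN"
    introduced_by_cc <- p %in% idx && tok$pos[p] == "CC"
    if (identical(k, subj_k) || identical(k, obj_k)) next
    anchor <- if (!has_verb) {
      if (k > 1L) np_head[1] else NA_integer_
    } else if (s < verb_i) {
      if (!is.na(subj_k)) np_head[subj_k] else NA_integer_
    } else {
      if (!is.na(obj_k) && k != obj_k) np_head[obj_k] else verb_i
    }
    if (introduced_by_prep && !is.na(anchor)) {
      add_arc(anchor, np_head[k], paste0("prep_", tolower(tok$surface[p])))
      add_arc(anchor, p, "prep")  # keep the IN token attached (single-head tree)
    } else if (introduced_by_cc && k > 1L) {
      add_arc(np_head[k - 1L], np_head[k], "conj_and")
      add_arc(np_head[k - 1L], p, "cc")
    } else if (!is.na(anchor)) {
      add_arc(anchor, np_head[k], "dep")
    } else if (k > 1L) {
      add_arc(np_head[1], np_head[k], "dep")
    }
  }

  # assemble constituency: group [NP (PP ...)*] regions
  wrap_pp <- function(k) {
    p <- np_start[k] - 1L
    if (p %in% idx && tok$pos[p] == "IN") {
      const_node("PP", list(pre(p), np_nodes[[k]]))
    } else if (p %in% idx && tok$pos[p] == "CC") {
      list(pre(p), np_nodes[[k]])  # spliced by caller
    } else np_nodes[[k]]
  }
  region_nodes <- function(ks) {
    out <- list()
    for (k in ks) {
      w <- wrap_pp(k)
      if (is.list(w) && !inherits(w, "const_node")) out <- c(out, w)
      else out[[length(out) + 1L]] <- w
    }
    out
  }

  if (!has_verb) {
    kids <- region_nodes(seq_along(nps))
    root_node <- if (length(kids) == 1L) kids[[1]] else const_node("NP", kids)
    root_tok <- if (length(np_head)) np_head[1] else idx[1]
    return(list(arcs = arcs, node = root_node, root = root_tok))
  }

  pre_ks <- which(np_start < verb_i)
  post_ks <- which(np_start > verb_i)
  subj_node <- if (length(pre_ks)) {
    kids <- region_nodes(pre_ks)
    if (length(kids) == 1L) kids[[1]] else const_node("NP", kids)
  } else NULL
  vp_kids <- list()
  if (!is.na(aux_i)) vp_kids[[length(vp_kids) + 1L]] <- pre(aux_i)
  if (!is.na(neg_i)) vp_kids[[length(vp_kids) + 1L]] <- pre(neg_i)
  vp_kids[[length(vp_kids) + 1L]] <- pre(verb_i)
  vp_kids <- c(vp_kids, region_nodes(post_ks))
  s_kids <- c(if (!is.null(subj_node)) list(subj_node), list(const_node("VP", vp_kids)))
  list(arcs = arcs, node = const_node("S", s_kids), root = verb_i)
}

parse_template_sentence <- function(text, verbs) {
  tk <- template_tokenize(text)
  if (!nrow(tk)) stop("no tokens", call. = FALSE)
  tk$pos <- template_tag(tk$surface, verbs)
  tk$index <- seq_len(nrow(tk))
  tk$char_end <- tk$char_start + nchar(tk$surface)
  tk$lemma <- tolower(tk$surface)

  n <- nrow(tk)
  punct <- which(tk$pos == ".")
  final_punct <- if (length(punct) && punct[length(punct)] == n) n else NA_integer_
  body <- setdiff(seq_len(n), final_punct)
  commas <- which(tk$pos == ",")
  body <- setdiff(body, commas)

  # split off one subordinate clause introduced by although/because/...
  sub_i <- which(tolower(tk$surface) %in% TEMPLATE_SUBORD & tk$pos == "IN")
  sub_i <- sub_i[sub_i %in% body]
  main_idx <- body; sub_idx <- integer(); mark_i <- NA_integer_
  if (length(sub_i)) {
    mark_i <- sub_i[1]
    sub_idx <- body[body > mark_i]
    main_idx <- body[body < mark_i]
  }

  main <- parse_template_clause(tk, main_idx)
  arcs <- main$arcs
  s_node <- main$node
  if (length(sub_idx)) {
    sub <- parse_template_clause(tk, sub_idx)
    arcs <- c(arcs, sub$arcs)
    arcs[[length(arcs) + 1L]] <- data.frame(head = main$root, dep = sub$root,
                                            label = "advcl", stringsAsFactors = FALSE)
    arcs[[length(arcs) + 1L]] <- data.frame(head = sub$root, dep = mark_i,
                                            label = "mark", stringsAsFactors = FALSE)
    sbar <- const_node("SBAR", list(const_node(tk$pos[mark_i], word = tk$surface[mark_i]),
                                    sub$node))
    # hang the SBAR inside the main clause's top node
    s_node$children[[length(s_node$children) + 1L]] <- sbar
  }
  for (ci in commas) {
    arcs[[length(arcs) + 1L]] <- data.frame(head = main$root, dep = ci,
                                            label = "punct", stringsAsFactors = FALSE)
    s_node$children[[length(s_node$children) + 1L]] <-
      const_node(",", word = tk$surface[ci])
  }
  if (!is.na(final_punct)) {
    arcs[[length(arcs) + 1L]] <- data.frame(head = main$root, dep = final_punct,
                                            label = "punct", stringsAsFactors = FALSE)
    s_node$children[[length(s_node$children) + 1L]] <-
      const_node(".", word = tk$surface[final_punct])
  }
  arcs_df <- if (length(arcs)) do.call(rbind, arcs) else
    data.frame(head = integer(), dep = integer(), label = character())

  # tree leaves must be in token order: rebuild ordering by sorting
  s_node <- reorder_leaves(s_node, tk)
  parsed_sentence(tk[, c("index", "surface", "lemma", "pos", "char_start", "char_end")],
                  arcs_df, index_tree(s_node))
}

# the clause assembly appends SBAR/punct after object NPs, which keeps
# leaves in order for the templates; as a safety net, verify and fall back
# to a flat tree if leaf order disagrees with the token sequence
reorder_leaves <- function(node, tk) {
  leaves <- character()
  walk <- function(nd) {
    if (length(nd$children) == 0L) leaves <<- c(leaves, nd$word)
    else for (ch in nd$children) walk(ch)
  }
  walk(node)
  if (identical(leaves, tk$surface)) return(node)
  const_node("S", lapply(seq_len(nrow(tk)), function(i)
    const_node(tk$pos[i], word = tk$surface[i])))
}
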