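#' Non-overlapping argument labelling (exact dynamic program)
#'
#' Given per-node probabilities of being an ARG, finds the labelling of
#' constituency-tree nodes to ARG/NONE that maximises the product of
#' per-node label probabilities subject to the non-overlap constraint: no
#' two ARG nodes may stand in an ancestor–descendant relation.  The
#' bottom-up dynamic program is exact.
#'
#' @param tree indexed constituency tree (see [index_tree()]).
#' @param node_probs numeric vector, `node_probs[id]` = P(ARG) for the
#'   node with preorder id `id`; values in \[0, 1\].
#' @return list with `labels` (character vector ARG/NONE per node id) and
#'   `score` (the maximised joint probability).
#' @export
label_arguments_nonoverlap <- function(tree, node_probs) {
  stopifnot(all(node_probs >= 0 & node_probs <= 1))
  n <- attr(tree, "n_nodes") %||% count_nodes(tree)
  stopifnot(length(node_probs) >= n)
  labels <- rep("NONE", n)

  # returns list(all_none = prob of whole subtree labelled NONE,
  #              best = best valid score, pick = labelling of subtree)
  solve <- function(node) {
    p_arg <- node_probs[node$id]
    p_none <- 1 - p_arg
    if (!length(node$children)) {
      if (p_arg > p_none) {
        return(list(all_none = p_none, best = p_arg,
                    pick = stats::setNames("ARG", node$id)))
      }
      return(list(all_none = p_none, best = p_none,
                  pick = stats::setNames("NONE", node$id)))
    }
    subs <- lapply(node$children, solve)
    none_below <- prod(vapply(subs, `[[`, numeric(1), "all_none"))
    opt_arg <- p_arg * none_below
    opt_none <- p_none * prod(vapply(subs, `[[`, numeric(1), "best"))
    if (opt_arg > opt_none) {
      ids <- unlist(lapply(subs, function(s) as.integer(names(s$pick))))
      pick <- stats::setNames(rep("NONE", length(ids) + 1L), c(node$id, ids))
      pick[as.character(node$id)] <- "ARG"
      list(all_none = p_none * none_below, best = opt_arg, pick = pick)
    } else {
      pick <- c(stats::setNames("NONE", node$id),
                do.call(c, lapply(subs, `[[`, "pick")))
      list(all_none = p_none * none_below, best = opt_none, pick = pick)
    }
  }
  res <- solve(tree)
  labels[as.integer(names(res$pick))] <- unname(res$pick)
  list(labels = labels, score = res$best)
}

#' Top-k joint semantic typing by bottom-up re-ranking
#'
#' Extends the non-overlap dynamic program to multi-class semantic types:
#' a labelling assigns each node a type or NONE, a non-NONE node forces
#' all its descendants to NONE, and the k highest-probability joint
#' labellings are kept at every subtree.  Ties are broken towards the
#' lexicographically smallest labelling (in preorder, with alphabetical
#' label order).
#'
#' @param tree indexed constituency tree.
#' @param type_probs numeric matrix, rows = node ids, named columns = types
#'   including `"NONE"`; each row sums to 1.
#' @param k number of joint labellings to keep (>= 1).
#' @return list of up to `k` labellings, each a list with `labels`
#'   (character per node id) and `prob`, sorted by probability descending.
#' @export
topk_joint_semantic_typing <- function(tree, type_probs, k = 5L) {
  stopifnot(k >= 1L, "NONE" %in% colnames(type_probs))
  stopifnot(all(abs(rowSums(type_probs) - 1) < 1e-6))
  types <- colnames(type_probs)
  non_none <- setdiff(types, "NONE")

  # candidate = list(prob, labels = named char vector over subtree ids)
  prune <- function(cands) {
    keys <- vapply(cands, function(c) {
      ids <- as.integer(names(c$labels))
      paste(c$labels[order(ids)], collapse = "\r")
    }, character(1))
    ord <- order(-vapply(cands, `[[`, numeric(1), "prob"), keys)
    cands[ord][seq_len(min(k, length(cands)))]
  }

  none_prob <- function(node) {
    # probability of the whole subtree labelled NONE
    p <- type_probs[node$id, "NONE"]
    for (ch in node$children) p <- p * none_prob(ch)
    p
  }
  all_none_labels <- function(node) {
    ids <- vapply(tree_nodes_sub(node), `[[`, integer(1), "id")
    stats::setNames(rep("NONE", length(ids)), ids)
  }

  solve <- function(node) {
    if (!length(node$children)) {
      cands <- lapply(types, function(t) {
        list(prob = unname(type_probs[node$id, t]),
             labels = stats::setNames(t, node$id))
      })
      return(prune(cands))
    }
    subs <- lapply(node$children, solve)
    cands <- list()
    # scenario 1: node takes a non-NONE type, all descendants NONE
    below_none <- prod(vapply(node$children, none_prob, numeric(1)))
    below_labels <- do.call(c, lapply(node$children, all_none_labels))
    for (t in non_none) {
      cands[[length(cands) + 1L]] <- list(
        prob = unname(type_probs[node$id, t] * below_none),
        labels = c(stats::setNames(t, node$id), below_labels))
    }
    # scenario 2: node is NONE; combine children's top-k lists
    combos <- list(list(prob = unname(type_probs[node$id, "NONE"]),
                        labels = stats::setNames("NONE", node$id)))
    for (s in subs) {
      combos <- unlist(lapply(combos, function(c0) {
        lapply(s, function(c1) {
          list(prob = c0$prob * c1$prob, labels = c(c0$labels, c1$labels))
        })
      }), recursive = FALSE)
      combos <- prune(combos)  # keep the frontier small as we fold children
    }
    prune(c(cands, combos))
  }
  solve(tree)
}

tree_nodes_sub <- function(node) {
  out <- list(node)
  for (ch in node$children) out <- c(out, tree_nodes_sub(ch))
  out
}

#' Propose relation trigger candidates in a sentence
#'
#' Triggers are pre-terminal tokens that lexically introduce a relation.
#' Candidates are the union of verb-lexicon matches, nominalization-lexicon
#' matches, and (when a trigger classifier is supplied) model-scored
#' pre-terminals above `threshold`.
#'
#' @param parsed a `parsed_sentence`.
#' @param cfg a [rule_config()].
#' @param model optional `maxent_model` with labels `TRIGGER`/`NONE`.
#' @param threshold minimum classifier probability (default 0.5).
#' @return data.frame with columns `token`, `source`, `score`, sorted by
#'   score descending (ties by token index).
#' @export
propose_triggers <- function(parsed, cfg = default_rule_config(), model = NULL,
                             threshold = 0.5) {
  toks <- parsed$tokens
  rows <- list()
  verb_hits <- which(toks$lemma %in% names(cfg$verb_lexicon) &
                     startsWith(toks$pos, "VB"))
  for (i in verb_hits) {
    rows[[length(rows) + 1L]] <- data.frame(token = i, source = "verb_lexicon",
                                            score = 1.0, stringsAsFactors = FALSE)
  }
  nom_hits <- which(toks$lemma %in% cfg$nominalization_lexicon)
  for (i in nom_hits) {
    rows[[length(rows) + 1L]] <- data.frame(token = i, source = "nominalization",
                                            score = 1.0, stringsAsFactors = FALSE)
  }
  if (!is.null(model)) {
    feats <- lapply(seq_len(nrow(toks)), function(i) trigger_features(parsed, i))
    P <- predict(model, feats)
    keep <- which(P[, "TRIGGER"] >= threshold)
    for (i in keep) {
      rows[[length(rows) + 1L]] <- data.frame(token = i, source = "classifier",
                                              score = P[i, "TRIGGER"],
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(token = integer(), source = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$token), , drop = FALSE]
  out <- out[order(-out$score, out$token), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# features of one token as a potential trigger; n_args conditions on the
# current argument beliefs during the iterative optimisation
trigger_features <- function(parsed, i, n_args = NA_integer_) {
  toks <- parsed$tokens
  out <- c(paste0("lemma=", toks$lemma[i]),
           paste0("pos=", toks$pos[i]),
           paste0("spos=", toks$simple_pos[i]))
  if (i > 1L) out <- c(out, paste0("prev=", toks$lemma[i - 1L]))
  if (i < nrow(toks)) out <- c(out, paste0("next=", toks$lemma[i + 1L]))
  if (!is.na(n_args)) out <- c(out, paste0("n_args=", min(n_args, 4L)))
  out
}

# features of (node, trigger) for the ARG/NONE argument classifier
argument_features <- function(parsed, node, trigger_tok) {
  toks <- parsed$tokens
  head_tok <- find_head_token(node)
  out <- c(paste0("label=", node$label),
           paste0("head=", toks$lemma[head_tok]),
           paste0("trigger=", toks$lemma[trigger_tok]),
           paste0("dist=", bucket_int(abs(head_tok - trigger_tok))),
           paste0("side=", if (head_tok < trigger_tok) "left"
                  else if (head_tok > trigger_tok) "right" else "self"))
  if (head_tok != trigger_tok) {
    path <- dependency_path(parsed, head_tok, trigger_tok)
    out <- c(out, paste0("path=", paste(paste0(path$label, ":", path$dir),
                                        collapse = "|")))
  }
  out
}

#' Iterative trigger / argument optimisation
#'
#' Alternates between scoring relation triggers (conditioning on the
#' current argument beliefs) and labelling arguments with the
#' non-overlapping dynamic program (conditioning on the current best
#' trigger), for at most `rounds` rounds, stopping early at a fixed point.
#'
#' @param parsed a `parsed_sentence`.
#' @param arg_model `maxent_model` over [argument_features] with labels
#'   `ARG`/`NONE`; `NULL` disables model scoring (lexicon triggers only,
#'   no argument labelling).
#' @param trigger_model optional `maxent_model` over trigger features with
#'   labels `TRIGGER`/`NONE`.
#' @param cfg a [rule_config()].
#' @param rounds maximum alternation rounds (>= 1, default 2).
#' @return list with `triggers` (data.frame as [propose_triggers()]),
#'   `assignment` (output of [label_arguments_nonoverlap()] or NULL), and
#'   `rounds_run`.
#' @export
iterate_trigger_entity <- function(parsed, arg_model = NULL,
                                   trigger_model = NULL,
                                   cfg = default_rule_config(), rounds = 2L) {
  stopifnot(rounds >= 1L)
  nodes <- tree_nodes(parsed$tree)
  n_args <- NA_integer_
  prev_state <- NULL
  triggers <- NULL; assignment <- NULL; r_run <- 0L
  for (r in seq_len(rounds)) {
    r_run <- r
    triggers <- propose_triggers_conditioned(parsed, cfg, trigger_model, n_args)
    if (!nrow(triggers)) { assignment <- NULL; break }
    best_trig <- triggers$token[1]
    if (is.null(arg_model)) { assignment <- NULL; break }
    probs <- vapply(nodes, function(nd) {
      P <- predict(arg_model, list(argument_features(parsed, nd, best_trig)))
      P[1, "ARG"]
    }, numeric(1))
    assignment <- label_arguments_nonoverlap(parsed$tree, probs)
    n_args <- sum(assignment$labels == "ARG")
    state <- list(trig = triggers$token, labels = assignment$labels)
    if (identical(state, prev_state)) break
    prev_state <- state
  }
  list(triggers = triggers, assignment = assignment, rounds_run = r_run)
}

propose_triggers_conditioned <- function(parsed, cfg, model, n_args) {
  if (is.null(model) || is.na(n_args)) {
    return(propose_triggers(parsed, cfg, model))
  }
  toks <- parsed$tokens
  feats <- lapply(seq_len(nrow(toks)), function(i)
    trigger_features(parsed, i, n_args))
  P <- predict(model, feats)
  base <- propose_triggers(parsed, cfg, NULL)
  keep <- which(P[, "TRIGGER"] >= 0.5)
  rows <- data.frame(token = keep, source = rep("classifier", length(keep)),
                     score = P[keep, "TRIGGER"], stringsAsFactors = FALSE)
  out <- rbind(base, rows)
  out <- out[!duplicated(out$token), , drop = FALSE]
  out <- out[order(-out$score, out$token), , drop = FALSE]
  rownames(out) <- NULL
  out
}
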