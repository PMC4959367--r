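#' Constituency trees
#'
#' Trees are plain nested lists: each node has a phrase `label`, a token
#' span `start`..`end` (1-based, inclusive), an ordered `children` list and
#' — for pre-terminals — the covered `word`.  Node ids are assigned in
#' preorder by [index_tree()] so that per-node probability tables can be
#' plain vectors.
#'
#' @name const_tree
NULL

const_node <- function(label, children = list(), word = NULL) {
  structure(list(label = label, children = children, word = word,
                 start = NA_integer_, end = NA_integer_, id = NA_integer_),
            class = "const_node")
}

is_preterminal <- function(node) length(node$children) == 0L

#' Read a Penn-style bracketed tree
#'
#' Parses strings like `"(S (NP (NN EPA)) (VP (VB reduce) (NP (DT the)
#' (NN vasoconstriction))))"` into a [const_tree] with token spans
#' assigned left to right.  Used heavily to hand-build parses in tests.
#'
#' @param s bracket notation; pre-terminals are `(TAG word)`.
#' @return root `const_node` with spans and preorder ids assigned.
#' @export
read_ptb_tree <- function(s) {
  toks <- regmatches(s, gregexpr("\\(|\\)|[^()\\s]+", s, perl = TRUE))[[1]]
  pos <- 1L
  parse_node <- function() {
    stopifnot(toks[pos] == "(")
    pos <<- pos + 1L
    label <- toks[pos]; pos <<- pos + 1L
    children <- list(); word <- NULL
    while (toks[pos] != ")") {
      if (toks[pos] == "(") {
        children[[length(children) + 1L]] <- parse_node()
      } else {
        word <- toks[pos]; pos <<- pos + 1L
      }
    }
    pos <<- pos + 1L
    const_node(label, children, word)
  }
  root <- parse_node()
  index_tree(root)
}

#' Assign token spans and preorder ids to a tree
#'
#' @param root a `const_node`.
#' @return the tree with `start`, `end`, `id` filled in; attribute
#'   `n_nodes` holds the node count.
#' @export
index_tree <- function(root) {
  tok <- 0L; id <- 0L
  walk <- function(node) {
    id <<- id + 1L
    node$id <- id
    if (is_preterminal(node)) {
      tok <<- tok + 1L
      node$start <- node$end <- tok
    } else {
      node$children <- lapply(node$children, walk)
      node$start <- node$children[[1]]$start
      node$end <- node$children[[length(node$children)]]$end
    }
    node
  }
  root <- walk(root)
  attr(root, "n_nodes") <- id
  root
}

#' Flatten a tree to a preorder list of nodes
#'
#' @param root indexed tree.
#' @return list of nodes in preorder (element i has id i).
#' @export
tree_nodes <- function(root) {
  out <- vector("list", attr(root, "n_nodes") %||% count_nodes(root))
  walk <- function(node) {
    out[[node$id]] <<- node
    for (ch in node$children) walk(ch)
  }
  walk(root)
  out
}

count_nodes <- function(node) {
  1L + sum(vapply(node$children, count_nodes, integer(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# leaves (pre-terminals) in order
tree_leaves <- function(root) {
  out <- list()
  walk <- function(node) {
    if (is_preterminal(node)) out[[length(out) + 1L]] <<- node
    else for (ch in node$children) walk(ch)
  }
  walk(root)
  out
}

# ---- Collins head rules -----------------------------------------------

# priority lists; direction "left" scans children left-to-right per
# priority tag, "right" scans right-to-left
collins_table <- list(
  ADJP  = list(dir = "left",  tags = c("NNS","QP","NN","$","ADVP","JJ","VBN","VBG","ADJP","JJR","NP","JJS","DT","FW","RBR","RBS","SBAR","RB")),
  ADVP  = list(dir = "right", tags = c("RB","RBR","RBS","FW","ADVP","TO","CD","JJR","JJ","IN","NP","JJS","NN")),
  CONJP = list(dir = "right", tags = c("CC","RB","IN")),
  FRAG  = list(dir = "right", tags = character()),
  INTJ  = list(dir = "left",  tags = character()),
  LST   = list(dir = "right", tags = c("LS",":")),
  NAC   = list(dir = "left",  tags = c("NN","NNS","NNP","NNPS","NP","NAC","EX","$","CD","QP","PRP","VBG","JJ","JJS","JJR","ADJP","FW")),
  PP    = list(dir = "right", tags = c("IN","TO","VBG","VBN","RP","FW")),
  PRN   = list(dir = "left",  tags = character()),
  PRT   = list(dir = "right", tags = c("RP")),
  QP    = list(dir = "left",  tags = c("$","IN","NNS","NN","JJ","RB","DT","CD","NCD","QP","JJR","JJS")),
  RRC   = list(dir = "right", tags = c("VP","NP","ADVP","ADJP","PP")),
  S     = list(dir = "left",  tags = c("TO","IN","VP","S","SBAR","ADJP","UCP","NP")),
  SBAR  = list(dir = "left",  tags = c("WHNP","WHPP","WHADVP","WHADJP","IN","DT","S","SQ","SINV","SBAR","FRAG")),
  SBARQ = list(dir = "left",  tags = c("SQ","S","SINV","SBARQ","FRAG")),
  SINV  = list(dir = "left",  tags = c("VBZ","VBD","VBP","VB","MD","VP","S","SINV","ADJP","NP")),
  SQ    = list(dir = "left",  tags = c("VBZ","VBD","VBP","VB","MD","VP","SQ")),
  UCP   = list(dir = "right", tags = character()),
  VP    = list(dir = "left",  tags = c("TO","VBD","VBN","MD","VBZ","VB","VBG","VBP","VP","ADJP","NN","NNS","NP")),
  WHADJP = list(dir = "left", tags = c("CC","WRB","JJ","ADJP")),
  WHADVP = list(dir = "right", tags = c("CC","WRB")),
  WHNP  = list(dir = "left",  tags = c("WDT","WP","WP$","WHADJP","WHPP","WHNP")),
  WHPP  = list(dir = "right", tags = c("IN","TO","FW"))
)

collins_np_head_child <- function(children) {
  labs <- vapply(children, `[[`, character(1), "label")
  n <- length(labs)
  if (labs[n] == "POS") return(n)
  for (i in rev(seq_len(n))) if (labs[i] %in% c("NN","NNP","NNPS","NNS","NX","POS","JJR")) return(i)
  for (i in seq_len(n)) if (labs[i] == "NP") return(i)
  for (i in rev(seq_len(n))) if (labs[i] %in% c("$","ADJP","PRN")) return(i)
  for (i in rev(seq_len(n))) if (labs[i] == "CD") return(i)
  for (i in rev(seq_len(n))) if (labs[i] %in% c("JJ","JJS","RB","QP")) return(i)
  n
}

collins_head_child <- function(node) {
  children <- node$children
  labs <- vapply(children, `[[`, character(1), "label")
  n <- length(children)
  if (node$label %in% c("NP", "NX")) {
    i <- collins_np_head_child(children)
  } else {
    rule <- collins_table[[node$label]]
    i <- NULL
    if (!is.null(rule)) {
      idx <- if (rule$dir == "left") seq_len(n) else rev(seq_len(n))
      for (tag in rule$tags) {
        hit <- idx[labs[idx] == tag]
        if (length(hit)) { i <- hit[1]; break }
      }
      if (is.null(i)) i <- if (rule$dir == "left") 1L else n
    }
    if (is.null(i)) i <- n  # unknown phrase label: rightmost child
  }
  # coordination adjustment: head must not be a conjunction when avoidable
  if (labs[i] == "CC" && n > 1L) {
    alt <- which(labs != "CC")
    if (length(alt)) i <- alt[which.min(abs(alt - i))]
  }
  i
}

#' Find the head token of a constituency node (Collins rules)
#'
#' Pre-terminals return their own token.  Internal nodes percolate the head
#' from the child selected by the Collins head-finding table; unknown
#' phrase labels default to the rightmost child.
#'
#' @param node a `const_node` with spans assigned.
#' @return token index (1-based) of the lexical head.
#' @export
find_head_token <- function(node) {
  while (!is_preterminal(node)) {
    node <- node$children[[collins_head_child(node)]]
  }
  node$start
}
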