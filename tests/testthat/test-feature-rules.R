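test_that("verb-in-path rule reproduces the worked regulation example", {
  fv <- extract_feature_vector(epa_context())
  expect_false(fv$no_verb_in_path)
  expect_equal(fv$dep_path, "nsubj:up|dobj:down")
  expect_equal(fv$verb_path_verb, "reduce")
  expect_equal(fv$verb_path_class, "DOWN_REGULATE")
  expect_equal(fv$verb_path_sides, "both")
  expect_false(fv$passive)
  expect_false(fv$negated)
})

test_that("multi-verb paths anchor on the root-most verb", {
  # "X showed that Y reduced Z": path X..Z passes showed (root) and reduced
  tokens <- data.frame(
    index = 1:5, surface = c("X", "showed", "Y", "reduced", "Z"),
    lemma = c("x", "showed", "y", "reduced", "z"),
    pos = c("NN", "VBD", "NN", "VBD", "NN"),
    char_start = c(0L, 2L, 9L, 11L, 19L), char_end = c(1L, 8L, 10L, 18L, 20L),
    stringsAsFactors = FALSE)
  arcs <- data.frame(head = c(2L, 2L, 4L, 4L), dep = c(1L, 4L, 3L, 5L),
                     label = c("nsubj", "ccomp", "nsubj", "dobj"),
                     stringsAsFactors = FALSE)
  tree <- "(S (NP (NN X)) (VP (VBD showed) (SBAR (S (NP (NN Y)) (VP (VBD reduced) (NP (NN Z)))))))"
  p <- parsed_sentence(tokens, arcs, tree)
  ctx <- pair_ctx_from_parsed(p, 1L, 5L)
  fv <- extract_feature_vector(ctx)
  expect_equal(fv$verb_path_verb, "showed")  # depth 0 beats depth 1
})

test_that("no-verb paths gate towards nominalization", {
  # "the mutation of MLH1 in patients" (no verb)
  doc_txt <- "The mutation of MLH1 in patients ."
  ents <- data.frame(id = c("T1", "T2"), type = c("gene", "cohort"),
                     start = c(16L, 24L), end = c(20L, 32L),
                     surface = c("MLH1", "patients"), stringsAsFactors = FALSE)
  d <- segment_and_bind(brat_document("n", doc_txt, ents))
  p <- parse_document(d)[[1]]
  ctx <- entity_pair_context(p, d$entities[1, ], d$entities[2, ],
                             sent_entities = d$entities, sent_start = 0L)
  fv <- extract_feature_vector(ctx)
  expect_true(fv$no_verb_in_path)
  # strict nominalization: "mutation" dominates both entity heads
  expect_true(fv$nominalization)
  expect_false(fv$weak_nominalization)
})

test_that("weak nominalization fires when only one entity fits the pattern", {
  # "the mutation in MLH1 reduced the expression" -- entity pair (MLH1, expression):
  # MLH1 follows a preposition with "mutation" ahead; expression does not
  tokens <- data.frame(
    index = 1:7,
    surface = c("the", "mutation", "in", "MLH1", "reduced", "the", "expression"),
    lemma = c("the", "mutation", "in", "mlh1", "reduced", "the", "expression"),
    pos = c("DT", "NN", "IN", "NN", "VBD", "DT", "NN"),
    char_start = c(0L, 4L, 13L, 16L, 21L, 29L, 33L),
    char_end = c(3L, 12L, 15L, 20L, 28L, 32L, 43L),
    stringsAsFactors = FALSE)
  arcs <- data.frame(head = c(2L, 2L, 5L, 7L, 5L),
                     dep = c(1L, 4L, 2L, 6L, 7L),
                     label = c("det", "prep_in", "nsubj", "det", "dobj"),
                     stringsAsFactors = FALSE)
  tree <- "(S (NP (DT the) (NP (NN mutation)) (PP (IN in) (NP (NN MLH1)))) (VP (VBD reduced) (NP (DT the) (NP (NN expression)))))"
  p <- parsed_sentence(tokens, arcs, tree)
  cfg <- default_rule_config()
  ctx <- pair_ctx_from_parsed(p, 4L, 7L, types = c("gene", "Physiology"))
  fv <- extract_feature_vector(ctx, cfg)
  expect_false(fv$nominalization)
  expect_true(fv$weak_nominalization)
  # empty lexicon: both always false
  cfg0 <- rule_config(3L, cfg$verb_lexicon, character(), cfg$negation_words)
  fv0 <- extract_feature_vector(ctx, cfg0)
  expect_false(fv0$nominalization)
  expect_false(fv0$weak_nominalization)
})

test_that("negation is restricted to the inter-entity path", {
  p <- parse_sentence("The carriers did not develop the adenomas .",
                      template_parser(c("develop", "did")))
  # template parser: "did" aux-ish is tagged NN (unknown) -- hand-build instead
  tokens <- data.frame(
    index = 1:6, surface = c("X", "not", "reduce", "Y", "but", "Z"),
    lemma = c("x", "not", "reduce", "y", "but", "z"),
    pos = c("NN", "RB", "VB", "NN", "CC", "NN"),
    char_start = 0:5 * 2L, char_end = 0:5 * 2L + 1L,
    stringsAsFactors = FALSE)
  arcs <- data.frame(head = c(3L, 3L, 3L, 3L, 4L),
                     dep = c(1L, 2L, 4L, 5L, 6L),
                     label = c("nsubj", "neg", "dobj", "cc", "conj_and"),
                     stringsAsFactors = FALSE)
  tree <- "(S (NP (NN X)) (VP (RB not) (VB reduce) (NP (NN Y)) (CC but) (NP (NN Z))))"
  p <- parsed_sentence(tokens, arcs, tree)
  # pair (X, Y): "reduce" on the path carries the neg arc
  expect_true(extract_feature_vector(pair_ctx_from_parsed(p, 1L, 4L))$negated)
  # pair (Y, Z): path Y -> reduce? no: Y..Z path is dobj(up from Y? ) --
  # Z hangs off Y, so the path avoids the negated verb
  expect_false(extract_feature_vector(pair_ctx_from_parsed(p, 4L, 6L))$negated)
})

test_that("lexicon negation words modifying the path verb count", {
  tokens <- data.frame(
    index = 1:4, surface = c("X", "fails", "reduce", "Y"),
    lemma = c("x", "fails", "reduce", "y"),
    pos = c("NN", "VBZ", "VB", "NN"),
    char_start = 0:3 * 2L, char_end = 0:3 * 2L + 1L,
    stringsAsFactors = FALSE)
  arcs <- data.frame(head = c(2L, 2L, 3L), dep = c(1L, 3L, 4L),
                     label = c("nsubj", "xcomp", "dobj"),
                     stringsAsFactors = FALSE)
  tree <- "(S (NP (NN X)) (VP (VBZ fails) (VP (VB reduce) (NP (NN Y)))))"
  p <- parsed_sentence(tokens, arcs, tree)
  fv <- extract_feature_vector(pair_ctx_from_parsed(p, 1L, 4L))
  expect_true(fv$negated)
})

test_that("voice detects passive through auxpass on the path", {
  p <- passive_parsed()
  fv <- extract_feature_vector(pair_ctx_from_parsed(p, 1L, 5L))
  expect_true(fv$passive)
  # active sentence: false (worked example)
  expect_false(extract_feature_vector(epa_context())$passive)
})

test_that("clause features use SBAR span arithmetic", {
  # no SBAR anywhere
  fv0 <- extract_feature_vector(epa_context())
  expect_false(fv0$contains_clause)
  expect_false(fv0$sbar_between)
  expect_equal(fv0$clause_distance_e1, 999L)
  # "X increases which suggests Y": SBAR over "which suggests Y",
  # X outside, Y inside -> separated
  tokens <- data.frame(
    index = 1:5, surface = c("X", "increases", "which", "suggests", "Y"),
    lemma = c("x", "increases", "which", "suggests", "y"),
    pos = c("NN", "VBZ", "WDT", "VBZ", "NN"),
    char_start = 0:4 * 2L, char_end = 0:4 * 2L + 1L,
    stringsAsFactors = FALSE)
  arcs <- data.frame(head = c(2L, 2L, 4L, 4L), dep = c(1L, 4L, 3L, 5L),
                     label = c("nsubj", "ccomp", "nsubj", "dobj"),
                     stringsAsFactors = FALSE)
  tree <- "(S (NP (NN X)) (VP (VBZ increases) (SBAR (WHNP (WDT which)) (S (VP (VBZ suggests) (NP (NN Y)))))))"
  p <- parsed_sentence(tokens, arcs, tree)
  fv <- extract_feature_vector(pair_ctx_from_parsed(p, 1L, 5L))
  expect_true(fv$contains_clause)
  expect_true(fv$sbar_between)
  expect_equal(fv$clause_distance_e1, -2L)  # X is 2 tokens left of the SBAR
  expect_equal(fv$clause_distance_e2, 0L)   # Y inside the clause
})

test_that("tree-path features: shared parent, label path, zero length", {
  # two multi-token NPs under the same VP anchor at the NPs themselves
  tokens <- data.frame(
    index = 1:5, surface = c("gave", "the", "X", "the", "Y"),
    lemma = c("gave", "the", "x", "the", "y"),
    pos = c("VBD", "DT", "NN", "DT", "NN"),
    char_start = 0:4 * 4L, char_end = 0:4 * 4L + 3L,
    stringsAsFactors = FALSE)
  arcs <- data.frame(head = c(1L, 3L, 1L, 5L), dep = c(3L, 2L, 5L, 4L),
                     label = c("dobj", "det", "iobj", "det"),
                     stringsAsFactors = FALSE)
  p <- parsed_sentence(
    tokens, arcs,
    "(VP (VBD gave) (NP (DT the) (NN X)) (NP (DT the) (NN Y)))")
  tk <- p$tokens
  ents <- data.frame(id = c("T1", "T2"), type = c("a", "b"),
                     start = c(tk$char_start[2], tk$char_start[4]),
                     end = c(tk$char_end[3], tk$char_end[5]),
                     surface = c("the X", "the Y"), stringsAsFactors = FALSE)
  ctx <- entity_pair_context(p, ents[1, ], ents[2, ],
                             sent_entities = ents, sent_start = 0L)
  fv <- extract_feature_vector(ctx)
  expect_true(fv$same_head)
  expect_equal(fv$tree_path, "NP-VP-NP")
  expect_equal(fv$tree_path_length, 2L)
  # identical anchored node (same-span multi-type pair) -> length 0
  doc <- fig4_style_doc()
  p4 <- parse_document(doc)[[1]]
  ctx <- entity_pair_context(p4, doc$entities[3, ], doc$entities[4, ],
                             sent_entities = doc$entities, sent_start = 0L)
  fv4 <- extract_feature_vector(ctx)
  expect_equal(fv4$tree_path_length, 0L)
})

test_that("lexical windows and surface distance follow the definitions", {
  # entities of widths 1 and 2 with 3 tokens between -> distance 6
  tokens <- data.frame(
    index = 1:8,
    surface = c("A", "t1", "t2", "t3", "B1", "B2", "x", "y"),
    lemma = tolower(c("A", "t1", "t2", "t3", "B1", "B2", "x", "y")),
    pos = rep("NN", 8),
    char_start = 0:7 * 3L, char_end = 0:7 * 3L + 2L,
    stringsAsFactors = FALSE)
  arcs <- data.frame(head = rep(1L, 7), dep = 2:8, label = rep("dep", 7),
                     stringsAsFactors = FALSE)
  tree <- paste0("(NP ", paste0("(NN ", tokens$surface, ")", collapse = " "), ")")
  p <- parsed_sentence(tokens, arcs, tree)
  ents <- data.frame(id = c("T1", "T2"), type = c("a", "b"),
                     start = c(0L, 12L), end = c(2L, 17L),
                     surface = c("A", "B1 B2"), stringsAsFactors = FALSE)
  ents$surface <- c("A", "B1 B2")
  ctx <- entity_pair_context(p, ents[1, ], ents[2, ],
                             sent_entities = ents, sent_start = 0L)
  fv <- extract_feature_vector(ctx)
  expect_equal(fv$surface_distance, 6L)
  expect_equal(fv$words_between_tokens, c("t1", "t2", "t3"))
  # window at sentence start is clipped
  expect_equal(fv$window_left_e1, character())
  expect_equal(fv$window_right_e2, c("x/noun", "y/noun"))
  # symmetry: swapping the argument roles keeps the distance
  ctx_sw <- entity_pair_context(p, ents[2, ], ents[1, ],
                                sent_entities = ents, sent_start = 0L)
  fv_sw <- extract_feature_vector(ctx_sw)
  expect_equal(fv_sw$surface_distance, fv$surface_distance)
  expect_equal(fv_sw$entity_order, "arg2_first")
  expect_equal(fv$entity_order, "arg1_first")
})

test_that("adjacent entities have an empty between-sequence", {
  doc <- epa_doc()
  p <- parse_document(doc)[[1]]
  ents <- data.frame(id = c("T1", "T2"), type = c("x", "y"),
                     start = c(0L, 4L), end = c(3L, 10L),
                     surface = c("EPA", "reduce"), stringsAsFactors = FALSE)
  ctx <- entity_pair_context(p, ents[1, ], ents[2, ],
                             sent_entities = ents, sent_start = 0L)
  fv <- extract_feature_vector(ctx)
  expect_equal(fv$words_between_tokens, character())
})

test_that("supplementary features count the sentence's gold mentions", {
  doc <- fig4_style_doc()
  p <- parse_document(doc)[[1]]
  # pair (individuals, colorectal cancers): the nested "cancers" mentions
  # both lie within arg2's span, not strictly between
  ctx <- entity_pair_context(p, doc$entities[1, ], doc$entities[2, ],
                             sent_entities = doc$entities, sent_start = 0L)
  fv <- extract_feature_vector(ctx)
  expect_equal(fv$entity_counts, 4L)
  expect_equal(fv$n_entities_between, 0L)
  expect_equal(fv$arg1_type, "cohort")
  expect_equal(fv$arg2_type, "disease")
})

test_that("feature extraction is pure and schema-stable", {
  ctx <- epa_context()
  expect_identical(extract_feature_vector(ctx), extract_feature_vector(ctx))
  # every rule family is reachable across the fixture battery
  battery <- list(extract_feature_vector(epa_context()),
                  extract_feature_vector(pair_ctx_from_parsed(passive_parsed(), 1L, 5L)))
  doc_txt <- "The mutation of MLH1 in patients ."
  ents <- data.frame(id = c("T1", "T2"), type = c("gene", "cohort"),
                     start = c(16L, 24L), end = c(20L, 32L),
                     surface = c("MLH1", "patients"), stringsAsFactors = FALSE)
  d <- segment_and_bind(brat_document("n", doc_txt, ents))
  pn <- parse_document(d)[[1]]
  battery[[3]] <- extract_feature_vector(
    entity_pair_context(pn, d$entities[1, ], d$entities[2, ],
                        sent_entities = d$entities, sent_start = 0L))
  seen <- unique(unlist(lapply(battery, names)))
  expected <- c("no_verb_in_path", "dep_path", "dep_path_length",
                "verb_path_verb", "verb_path_class", "verb_path_sides",
                "contains_clause", "sbar_between", "clause_distance_e1",
                "clause_distance_e2", "same_head", "tree_path",
                "tree_path_length", "negated", "passive", "words_between",
                "words_between_tokens", "window_left_e1", "window_right_e2",
                "surface_distance", "nominalization", "weak_nominalization",
                "nominalization_side", "nominalization_distance",
                "n_entities_between", "entities_between_types",
                "entity_counts", "entity_order", "arg1_type", "arg2_type")
  expect_setequal(intersect(expected, seen), expected)
})

test_that("unparsed sentences keep supplementary features only", {
  ents <- data.frame(id = c("T1", "T2"), type = c("gene", "disease"),
                     start = c(0L, 10L), end = c(4L, 16L),
                     surface = c("MLH1", "cancer"), stringsAsFactors = FALSE)
  unp <- structure(list(text = "x", reason = "nope"),
                   class = "unparsed_sentence")
  ctx <- entity_pair_context(unp, ents[1, ], ents[2, ],
                             sent_entities = ents, sent_start = 0L)
  fv <- extract_feature_vector(ctx)
  expect_true(fv$unparsed)
  expect_equal(fv$entity_counts, 2L)
  expect_false("dep_path" %in% names(fv))
})
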