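test_that("brat T and R lines are transcribed into mentions", {
  txt <- "TP53 causes cancer."
  ann <- paste(
    "T1\tgene 0 4\tTP53",
    "T2\tdisease 12 18\tcancer",
    "R1\trelatedTo Arg1:T1 Arg2:T2",
    "#1\tAnnotatorNotes T1\tignored line",
    sep = "\n")
  doc <- read_brat_document(txt, ann)
  expect_equal(nrow(doc$entities), 2L)
  expect_equal(nrow(doc$relations), 1L)
  expect_equal(doc$entities$surface, c("TP53", "cancer"))
  expect_equal(doc$relations$predicate, "relatedTo")
  expect_equal(doc$relations[, c("arg1", "arg2")],
               data.frame(arg1 = "T1", arg2 = "T2"))
})

test_that("offset and reference errors are rejected with identifiers", {
  txt <- "TP53 causes cancer."
  expect_error(read_brat_document(txt, "T1\tgene 0 50\tTP53", doc_id = "d1"),
               "T1")
  expect_error(
    read_brat_document(txt, "T1\tgene 0 4\tTP53\nR1\thas Arg1:T1 Arg2:T9"),
    "T9")
})

test_that("discontinuous spans collapse to their envelope", {
  txt <- "abcd efgh ijkl"
  ann <- "T1\tgene 0 4;10 14\tabcd ijkl"
  doc <- read_brat_document(txt, ann)
  expect_equal(doc$entities$start, 0L)
  expect_equal(doc$entities$end, 14L)
  expect_equal(doc$entities$surface, "abcd efgh ijkl")
})

test_that("type_map renames labels and unknown labels pass verbatim", {
  txt <- "aa bb"
  ann <- "T1\tpatient 0 2\taa\nT2\tWeirdType 3 5\tbb"
  doc <- read_brat_document(txt, ann)
  expect_equal(doc$entities$type, c("cohort", "WeirdType"))
})

test_that("write/read round trip is the identity on mentions", {
  txt <- "TP53 causes cancer."
  ann <- "T1\tgene 0 4\tTP53\nT2\tdisease 12 18\tcancer\nR1\trelatedTo Arg1:T1 Arg2:T2"
  doc <- read_brat_document(txt, ann)
  out <- write_brat_document(doc)
  expect_equal(length(strsplit(out$ann, "\n")[[1]]), 3L)
  doc2 <- read_brat_document(out$txt, out$ann)
  expect_identical(doc$entities, doc2$entities)
  expect_identical(doc$relations, doc2$relations)
  # empty document -> empty ann
  expect_equal(write_brat_document(brat_document("e", "x"))$ann, "")
})

test_that("generated corpus round-trips byte-identically through disk", {
  gen <- generate_corpus(synth_config(n_docs = 10L), seed = 1)
  d1 <- file.path(tempdir(), "rt1"); d2 <- file.path(tempdir(), "rt2")
  write_brat_corpus(gen$corpus, d1)
  back <- read_brat_corpus(d1)
  write_brat_corpus(back, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d2, f), warn = FALSE),
                     readLines(file.path(d1, f), warn = FALSE),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("segmentation binds every entity to exactly one sentence", {
  doc <- fig4_style_doc()
  expect_equal(nrow(doc$sentences), 1L)
  expect_true(all(doc$entities$sentence == 1L))

  gen <- generate_corpus(synth_config(n_docs = 8L), seed = 5)
  for (d in gen$corpus) {
    expect_false(anyNA(d$entities$sentence))
    # containment invariant
    for (i in seq_len(nrow(d$entities))) {
      s <- d$sentences[d$entities$sentence[i], ]
      expect_true(s$start <= d$entities$start[i] && d$entities$end[i] <= s$end)
    }
    # spans tile the text
    expect_equal(d$sentences$start[1], 0L)
    expect_equal(d$sentences$end[nrow(d$sentences)], nchar(d$text))
    if (nrow(d$sentences) > 1L) {
      expect_equal(d$sentences$start[-1],
                   d$sentences$end[-nrow(d$sentences)])
    }
  }
})

test_that("entities straddling a proposed boundary force a sentence merge", {
  txt <- "We studied Dr. Smith syndrome here. Another sentence follows."
  ents <- data.frame(id = "T1", type = "disease", start = 11L, end = 27L,
                     surface = "Dr. Smith syndro", stringsAsFactors = FALSE)
  # the naive segmenter splits after "Dr." -- the entity straddles it
  doc <- segment_and_bind(brat_document("m", txt, ents))
  expect_false(anyNA(doc$entities$sentence))
  s <- doc$sentences[doc$entities$sentence[1], ]
  expect_true(s$start <= 11L && 27L <= s$end)
})

test_that("relations with arguments in different sentences are flagged", {
  txt <- "The carriers were examined . The adenomas were observed ."
  ents <- data.frame(id = c("T1", "T2"), type = c("cohort", "disease"),
                     start = c(4L, 33L), end = c(12L, 41L),
                     surface = c("carriers", "adenomas"),
                     stringsAsFactors = FALSE)
  rels <- data.frame(id = "R1", predicate = "has", arg1 = "T1", arg2 = "T2",
                     stringsAsFactors = FALSE)
  doc <- segment_and_bind(brat_document("x", txt, ents, rels))
  expect_equal(nrow(doc$sentences), 2L)
  expect_true(doc$relations$cross_sentence)
})

test_that("studied signatures are counted, thresholded and sorted", {
  mk <- function(id, n_a, n_b) {
    # n_a cohort-has-disease relations and n_b gene-has-mutation relations
    txts <- c(rep("The carriers developed the adenomas .", n_a),
              rep("MLH1 harboured the splice mutation .", n_b))
    text <- paste(txts, collapse = " ")
    ents <- list(); rels <- list(); off <- 0L; t <- 0L
    for (i in seq_len(n_a)) {
      ents[[t + 1L]] <- data.frame(id = paste0("T", t + 1L), type = "cohort",
                                   start = off + 4L, end = off + 12L,
                                   surface = "carriers")
      ents[[t + 2L]] <- data.frame(id = paste0("T", t + 2L), type = "disease",
                                   start = off + 27L, end = off + 35L,
                                   surface = "adenomas")
      rels[[i]] <- data.frame(id = paste0("R", i), predicate = "has",
                              arg1 = paste0("T", t + 1L), arg2 = paste0("T", t + 2L))
      t <- t + 2L; off <- off + 38L
    }
    for (i in seq_len(n_b)) {
      ents[[t + 1L]] <- data.frame(id = paste0("T", t + 1L), type = "gene",
                                   start = off, end = off + 4L, surface = "MLH1")
      ents[[t + 2L]] <- data.frame(id = paste0("T", t + 2L), type = "mutation",
                                   start = off + 19L, end = off + 34L,
                                   surface = "splice mutation")
      rels[[n_a + i]] <- data.frame(id = paste0("R", n_a + i), predicate = "has",
                                    arg1 = paste0("T", t + 1L),
                                    arg2 = paste0("T", t + 2L))
      t <- t + 2L; off <- off + 37L
    }
    brat_document(id, text, do.call(rbind, ents), do.call(rbind, rels))
  }
  corpus <- list(a = mk("a", 5L, 3L))
  tab <- select_studied_signatures(corpus, min_count = 4L)
  expect_equal(tab$signature, "cohort-has-disease")
  expect_equal(tab$count, 5L)
  tab_all <- select_studied_signatures(corpus, min_count = 1L)
  expect_equal(tab_all$signature, c("cohort-has-disease", "gene-has-mutation"))
  expect_equal(tab_all$count, c(5L, 3L))
  expect_equal(tab_all$arg1_type, c("cohort", "gene"))
  expect_equal(tab_all$predicate, c("has", "has"))
})

test_that("characteristic subtypes collapse, merge counts, idempotently", {
  txt <- "The adenomas developed the polyposis ."
  ents <- data.frame(id = c("T1", "T2"), type = c("Physiology", "Disorders"),
                     start = c(4L, 27L), end = c(12L, 36L),
                     surface = c("adenomas", "polyposis"),
                     stringsAsFactors = FALSE)
  rels <- data.frame(id = "R1", predicate = "has", arg1 = "T1", arg2 = "T2",
                     stringsAsFactors = FALSE)
  corpus <- list(d = brat_document("d", txt, ents, rels))
  coll <- collapse_characteristic_subtypes(corpus)
  expect_equal(coll$d$entities$type, c("Characteristic", "Characteristic"))
  tab <- select_studied_signatures(coll, 1L)
  expect_equal(tab$signature, "Characteristic-has-Characteristic")
  expect_equal(tab$count, 1L)
  # idempotent, and total relation count conserved
  expect_identical(collapse_characteristic_subtypes(coll), coll)
  expect_equal(sum(tab$count),
               sum(select_studied_signatures(corpus, 1L)$count))
})
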