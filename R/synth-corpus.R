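#' Configuration for the synthetic corpus generator
#'
#' The generator plants typed entity mentions and relations in templated
#' sentences so that every pipeline stage is testable without downloads.
#' It emulates the structural traits of a variant-curation corpus: typed
#' mentions embedded in sentences, within-sentence relations governed by
#' lexical trigger verbs, a configurable fraction of cross-sentence
#' relations, distractor entities sharing sentences with gold pairs, and
#' same-string multi-type annotations (one surface annotated as both a
#' disease and a metonymic patient cohort).
#'
#' @param n_docs number of documents.
#' @param sentences_per_doc integer range `c(lo, hi)`.
#' @param entity_lexicons named list: entity type -> character vector of
#'   surface forms.
#' @param signatures list of lists with elements `signature` (string
#'   parseable by [parse_signature()]), `trigger` (verb surface) and
#'   `plant_prob` (probability a generated candidate pair is a gold
#'   relation).
#' @param neutral_verbs verbs used in non-relational frames.
#' @param trigger_noise epsilon: probability a positive lacks its trigger
#'   verb, and a negative gains one.
#' @param distractor_rate probability a relational sentence carries an
#'   extra, unrelated entity.
#' @param cross_sentence_fraction fraction of gold relations whose two
#'   arguments are emitted in different sentences.
#' @param same_string_multitype_rate probability a disease mention is
#'   additionally annotated as a cohort on the identical span.
#' @param filler_rate probability a sentence is an entity-free filler.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(
    n_docs = 20L,
    sentences_per_doc = c(4L, 8L),
    entity_lexicons = list(
      cohort = c("patients", "individuals", "families", "probands",
                 "carriers", "participants"),
      disease = c("colorectal cancer", "endometrial cancer", "adenomas",
                  "polyposis", "tumours", "cancers"),
      gene = c("MLH1", "MSH2", "MSH6", "PMS2", "APC", "MUTYH"),
      mutation = c("missense variant", "frameshift deletion",
                   "splice mutation", "truncating variant",
                   "germline mutation")
    ),
    signatures = list(
      list(signature = "cohort-has-disease", trigger = "developed",
           plant_prob = 0.7),
      list(signature = "gene-has-mutation", trigger = "harboured",
           plant_prob = 0.7),
      list(signature = "cohort-has-mutation", trigger = "carried",
           plant_prob = 0.7)
    ),
    neutral_verbs = c("examined", "studied", "assessed"),
    trigger_noise = 0,
    distractor_rate = 0.3,
    cross_sentence_fraction = 0,
    same_string_multitype_rate = 0,
    filler_rate = 0.15) {
  rates <- c(trigger_noise, distractor_rate, cross_sentence_fraction,
             same_string_multitype_rate, filler_rate)
  stopifnot(all(rates >= 0 & rates <= 1))
  for (s in signatures) {
    sig <- parse_signature(s$signature)
    for (t in c(sig$arg1_type, sig$arg2_type)) {
      if (is.null(entity_lexicons[[t]]) || !length(entity_lexicons[[t]])) {
        stop("no surface lexicon for entity type '", t, "'", call. = FALSE)
      }
    }
  }
  structure(list(n_docs = as.integer(n_docs),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 entity_lexicons = entity_lexicons,
                 signatures = signatures,
                 neutral_verbs = neutral_verbs,
                 trigger_noise = trigger_noise,
                 distractor_rate = distractor_rate,
                 cross_sentence_fraction = cross_sentence_fraction,
                 same_string_multitype_rate = same_string_multitype_rate,
                 filler_rate = filler_rate),
            class = "synth_config")
}

#' Generate a synthetic brat corpus with its oracle
#'
#' Deterministic for a fixed `(cfg, seed)`.  The returned `oracle` records
#' exactly the entities and relations planted (relation rows carry their
#' `cross_sentence` flag and trigger word), and always matches what
#' [write_brat_corpus()] would emit.
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed (required).
#' @return list with `corpus` (named list of segmented
#'   [brat_document()]) and `oracle` (data.frame of planted relations).
#' @export
generate_corpus <- function(cfg, seed) {
  stopifnot(inherits(cfg, "synth_config"), !missing(seed))
  with_seed(seed, generate_corpus_impl(cfg))
}

generate_corpus_impl <- function(cfg) {
  docs <- list()
  oracle_rows <- list()
  for (d in seq_len(cfg$n_docs)) {
    doc_id <- sprintf("synth%03d", d)
    n_sent <- sample(seq(cfg$sentences_per_doc[1], cfg$sentences_per_doc[2]), 1L)
    text <- ""
    ents <- list(); rels <- list()
    t_ct <- 0L; r_ct <- 0L
    add_ent <- function(type, start, surface) {
      t_ct <<- t_ct + 1L
      id <- paste0("T", t_ct)
      ents[[length(ents) + 1L]] <<- data.frame(
        id = id, type = type, start = start,
        end = start + nchar(surface), surface = surface,
        sentence = NA_integer_, stringsAsFactors = FALSE)
      id
    }
    append_text <- function(s) {
      if (nzchar(text)) text <<- paste0(text, " ")
      text <<- paste0(text, s)
    }
    s_i <- 0L
    while (s_i < n_sent) {
      s_i <- s_i + 1L
      if (stats::runif(1) < cfg$filler_rate) {
        filler <- sample(c("The screening was confirmed .",
                           "The records were assessed although the cohort was small .",
                           "The registry was examined ."), 1L)
        append_text(filler)
        next
      }
      spec_s <- cfg$signatures[[sample(length(cfg$signatures), 1L)]]
      sig <- parse_signature(spec_s$signature)
      a1 <- sample(cfg$entity_lexicons[[sig$arg1_type]], 1L)
      a2 <- sample(cfg$entity_lexicons[[sig$arg2_type]], 1L)
      is_rel <- stats::runif(1) < spec_s$plant_prob
      flip <- stats::runif(1) < cfg$trigger_noise
      # a positive keeps its trigger unless flipped; a negative gains one
      use_trigger <- if (is_rel) !flip else flip
      verb <- if (use_trigger) spec_s$trigger else sample(cfg$neutral_verbs, 1L)
      cross <- is_rel && stats::runif(1) < cfg$cross_sentence_fraction

      if (!cross) {
        base <- nchar(text) + (if (nzchar(text)) 1L else 0L)
        pre1 <- "The "
        s1_start <- base + nchar(pre1)
        mid <- paste0(pre1, a1, " ", verb, " the ")
        s2_start <- base + nchar(mid)
        sent <- paste0(mid, a2)
        id1 <- add_ent(sig$arg1_type, s1_start, a1)
        id2 <- add_ent(sig$arg2_type, s2_start, a2)
        if (sig$arg2_type == "disease" &&
            stats::runif(1) < cfg$same_string_multitype_rate) {
          add_ent("cohort", s2_start, a2)
        }
        # distractors share the sentence with the gold pair (creating
        # baseline false positives) but take a type outside the frame's
        # signature so the trigger stays a perfect separator at zero noise
        d_types <- setdiff(names(cfg$entity_lexicons),
                           c(sig$arg1_type, sig$arg2_type))
        if (length(d_types) && stats::runif(1) < cfg$distractor_rate) {
          dtype <- sample(d_types, 1L)
          dsurf <- sample(cfg$entity_lexicons[[dtype]], 1L)
          d_start <- base + nchar(sent) + nchar(" in the ")
          sent <- paste0(sent, " in the ", dsurf)
          add_ent(dtype, d_start, dsurf)
        }
        sent <- paste0(sent, " .")
        append_text(sent)
      } else {
        # argument pair split over two adjacent sentences
        base <- nchar(text) + (if (nzchar(text)) 1L else 0L)
        pre1 <- "The "
        s1_start <- base + nchar(pre1)
        sent1 <- paste0(pre1, a1, " was examined .")
        id1 <- add_ent(sig$arg1_type, s1_start, a1)
        append_text(sent1)
        base2 <- nchar(text) + 1L
        s2_start <- base2 + nchar(pre1)
        sent2 <- paste0(pre1, a2, " was observed .")
        id2 <- add_ent(sig$arg2_type, s2_start, a2)
        append_text(sent2)
        s_i <- s_i + 1L  # consumed an extra sentence slot
      }
      if (is_rel) {
        r_ct <- r_ct + 1L
        rid <- paste0("R", r_ct)
        rels[[length(rels) + 1L]] <- data.frame(
          id = rid, predicate = sig$predicate, arg1 = id1, arg2 = id2,
          cross_sentence = NA, stringsAsFactors = FALSE)
        oracle_rows[[length(oracle_rows) + 1L]] <- data.frame(
          doc_id = doc_id, rel_id = rid, signature = spec_s$signature,
          arg1 = id1, arg2 = id2, cross_sentence = cross,
          trigger = if (use_trigger && !cross) spec_s$trigger else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
    entities <- if (length(ents)) do.call(rbind, ents) else empty_entities()
    relations <- if (length(rels)) do.call(rbind, rels) else empty_relations()
    doc <- brat_document(doc_id, text, entities, relations)
    docs[[doc_id]] <- segment_and_bind(doc)
  }
  oracle <- if (length(oracle_rows)) do.call(rbind, oracle_rows) else
    data.frame(doc_id = character(), rel_id = character(),
               signature = character(), arg1 = character(),
               arg2 = character(), cross_sentence = logical(),
               trigger = character(), stringsAsFactors = FALSE)
  list(corpus = docs, oracle = oracle)
}

#' Summarise a corpus
#'
#' Per-signature relation counts, per-type entity counts and the
#' cross-sentence fraction; on generated corpora this agrees exactly with
#' the generator's oracle.
#'
#' @param corpus list of segmented [brat_document()].
#' @return list with data.frames `signatures`, `entities`, and scalar
#'   `cross_sentence_fraction`.
#' @export
describe_corpus <- function(corpus) {
  sigs <- unlist(lapply(corpus, relation_signature_strings), use.names = FALSE)
  types <- unlist(lapply(corpus, function(d) d$entities$type), use.names = FALSE)
  cross <- unlist(lapply(corpus, function(d) d$relations$cross_sentence),
                  use.names = FALSE)
  sig_df <- if (length(sigs)) {
    tab <- table(sigs)
    data.frame(signature = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  } else data.frame(signature = character(), count = integer())
  ent_df <- if (length(types)) {
    tab <- table(types)
    data.frame(type = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  } else data.frame(type = character(), count = integer())
  list(signatures = sig_df, entities = ent_df,
       cross_sentence_fraction = if (length(cross)) mean(cross) else 0)
}
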