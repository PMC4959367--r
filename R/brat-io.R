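#' Annotated documents in brat standoff form
#'
#' An `brat_document` bundles the raw text of one document with its typed
#' entity mentions, binary relation mentions, and (after
#' [segment_and_bind()]) its sentence spans.  Character offsets are 0-based
#' and half-open, exactly as in the brat `.ann` files the corpus ships in.
#'
#' @param doc_id document identifier (usually the file stem).
#' @param text full document text.
#' @param entities data.frame with columns `id`, `type`, `start`, `end`,
#'   `surface`.
#' @param relations data.frame with columns `id`, `predicate`, `arg1`,
#'   `arg2`.
#' @param sentences optional data.frame with columns `index`, `start`,
#'   `end`; normally produced by [segment_and_bind()].
#' @return an object of class `brat_document`.
#' @export
brat_document <- function(doc_id, text, entities = empty_entities(),
                          relations = empty_relations(), sentences = NULL) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L,
            is.character(text), length(text) == 1L)
  entities <- as.data.frame(entities, stringsAsFactors = FALSE)
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)
  if (is.null(entities$sentence)) entities$sentence <- NA_integer_
  if (is.null(relations$cross_sentence)) relations$cross_sentence <- NA
  doc <- structure(
    list(doc_id = doc_id, text = text, entities = entities,
         relations = relations, sentences = sentences),
    class = "brat_document"
  )
  validate_brat_document(doc)
  doc
}

empty_entities <- function() {
  data.frame(id = character(), type = character(), start = integer(),
             end = integer(), surface = character(),
             sentence = integer(), stringsAsFactors = FALSE)
}

empty_relations <- function() {
  data.frame(id = character(), predicate = character(), arg1 = character(),
             arg2 = character(), cross_sentence = logical(),
             stringsAsFactors = FALSE)
}

# 0-based half-open slice of document text
text_slice <- function(text, start, end) substring(text, start + 1L, end)

validate_brat_document <- function(doc) {
  n <- nchar(doc$text)
  ents <- doc$entities
  if (nrow(ents)) {
    bad <- which(!(ents$start >= 0L & ents$start < ents$end & ents$end <= n))
    if (length(bad)) {
      stop(sprintf("document '%s': entity %s has offsets [%d,%d) outside text of length %d",
                   doc$doc_id, ents$id[bad[1]], ents$start[bad[1]],
                   ents$end[bad[1]], n), call. = FALSE)
    }
    mism <- which(ents$surface != text_slice(doc$text, ents$start, ents$end))
    if (length(mism)) {
      stop(sprintf("document '%s': entity %s surface does not match the text slice",
                   doc$doc_id, ents$id[mism[1]]), call. = FALSE)
    }
    if (anyDuplicated(ents$id)) {
      stop(sprintf("document '%s': duplicate entity id", doc$doc_id), call. = FALSE)
    }
  }
  rels <- doc$relations
  if (nrow(rels)) {
    missing <- setdiff(c(rels$arg1, rels$arg2), ents$id)
    if (length(missing)) {
      stop(sprintf("document '%s': relation argument '%s' does not resolve to an entity",
                   doc$doc_id, missing[1]), call. = FALSE)
    }
    if (any(rels$arg1 == rels$arg2)) {
      stop(sprintf("document '%s': relation with identical argument mentions",
                   doc$doc_id), call. = FALSE)
    }
  }
  invisible(doc)
}

#' @export
print.brat_document <- function(x, ...) {
  cat(sprintf("<brat_document> %s: %d chars, %d entities, %d relations, %s sentences\n",
              x$doc_id, nchar(x$text), nrow(x$entities), nrow(x$relations),
              if (is.null(x$sentences)) "unsegmented" else nrow(x$sentences)))
  invisible(x)
}

#' Default entity-type normalisation map
#'
#' The corpus annotates the study-population type as `patient`; downstream
#' it is referred to simply as `cohort`, so the default map folds the two
#' labels together.
#'
#' @return named character vector: raw label -> canonical label.
#' @export
default_type_map <- function() {
  c(patient = "cohort", Patient = "cohort", Cohort = "cohort")
}

#' Read one brat standoff document
#'
#' Parses the paired `.txt` / `.ann` contents.  `T` lines become entity
#' mentions (discontinuous fragment spans are collapsed to their envelope,
#' and the surface is re-derived from the text so the mention invariant
#' holds); `R` lines become binary relation mentions.  All other line kinds
#' (`A`, `#`, `E`, ...) are ignored.
#'
#' @param txt_content document text (character scalar).
#' @param ann_content contents of the `.ann` file (character scalar or
#'   vector of lines).
#' @param doc_id document identifier.
#' @param type_map named character vector renaming entity labels; unknown
#'   labels are kept verbatim.
#' @return a [brat_document()].
#' @export
read_brat_document <- function(txt_content, ann_content, doc_id = "doc",
                               type_map = default_type_map()) {
  lines <- if (length(ann_content) == 1L) {
    strsplit(ann_content, "\n", fixed = TRUE)[[1]]
  } else as.character(ann_content)
  lines <- lines[nzchar(trimws(lines))]
  n <- nchar(txt_content)

  ent_rows <- list(); rel_rows <- list()
  for (line in lines) {
    kind <- substr(line, 1L, 1L)
    if (kind == "T") {
      fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(fields) < 2L) stop("malformed T line: ", line, call. = FALSE)
      head_parts <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
      etype <- head_parts[1]
      # fragments are ';'-separated "start end" pairs; envelope = min..max
      frag <- strsplit(paste(head_parts[-1], collapse = " "), ";", fixed = TRUE)[[1]]
      offs <- lapply(strsplit(trimws(frag), " +"), as.integer)
      start <- min(vapply(offs, `[`, integer(1), 1L))
      end <- max(vapply(offs, `[`, integer(1), 2L))
      if (is.na(start) || is.na(end) || start < 0L || start >= end || end > n) {
        stop(sprintf("document '%s': entity %s span [%s,%s) outside text of length %d (line: %s)",
                     doc_id, fields[1], start, end, n, line), call. = FALSE)
      }
      if (etype %in% names(type_map)) etype <- unname(type_map[[etype]])
      ent_rows[[length(ent_rows) + 1L]] <- data.frame(
        id = fields[1], type = etype, start = start, end = end,
        surface = text_slice(txt_content, start, end),
        sentence = NA_integer_, stringsAsFactors = FALSE)
    } else if (kind == "R") {
      fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
      parts <- strsplit(fields[2], " +")[[1]]
      args <- parts[grepl("^Arg[12]:", parts)]
      a1 <- sub("^Arg1:", "", args[grepl("^Arg1:", args)])
      a2 <- sub("^Arg2:", "", args[grepl("^Arg2:", args)])
      if (length(a1) != 1L || length(a2) != 1L) {
        stop("malformed R line: ", line, call. = FALSE)
      }
      rel_rows[[length(rel_rows) + 1L]] <- data.frame(
        id = fields[1], predicate = parts[1], arg1 = a1, arg2 = a2,
        cross_sentence = NA, stringsAsFactors = FALSE)
    } # else: ignorable annotation kinds
  }
  entities <- if (length(ent_rows)) do.call(rbind, ent_rows) else empty_entities()
  relations <- if (length(rel_rows)) do.call(rbind, rel_rows) else empty_relations()
  if (nrow(relations)) {
    missing <- setdiff(c(relations$arg1, relations$arg2), entities$id)
    if (length(missing)) {
      stop(sprintf("document '%s': relation references missing entity %s",
                   doc_id, missing[1]), call. = FALSE)
    }
  }
  brat_document(doc_id, txt_content, entities, relations)
}

#' Write a document back to brat standoff form
#'
#' @param doc a [brat_document()].
#' @return list with elements `txt` and `ann` (character scalars); reading
#'   them back reproduces entities and relations exactly.
#' @export
write_brat_document <- function(doc) {
  validate_brat_document(doc)
  t_lines <- if (nrow(doc$entities)) {
    sprintf("%s\t%s %d %d\t%s", doc$entities$id, doc$entities$type,
            doc$entities$start, doc$entities$end, doc$entities$surface)
  } else character()
  r_lines <- if (nrow(doc$relations)) {
    sprintf("%s\t%s Arg1:%s Arg2:%s", doc$relations$id, doc$relations$predicate,
            doc$relations$arg1, doc$relations$arg2)
  } else character()
  list(txt = doc$text, ann = paste(c(t_lines, r_lines), collapse = "\n"))
}

#' Read / write a directory of paired .txt/.ann files
#'
#' @param dir corpus directory.
#' @param type_map see [read_brat_document()].
#' @return named list of [brat_document()] (a "corpus").
#' @export
read_brat_corpus <- function(dir, type_map = default_type_map()) {
  txts <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  docs <- lapply(txts, function(f) {
    stem <- sub("\\.txt$", "", basename(f))
    annf <- file.path(dir, paste0(stem, ".ann"))
    ann <- if (file.exists(annf)) readChar(annf, file.size(annf)) else ""
    read_brat_document(readChar(f, file.size(f)), ann, doc_id = stem,
                       type_map = type_map)
  })
  names(docs) <- vapply(docs, `[[`, character(1), "doc_id")
  docs
}

#' @rdname read_brat_corpus
#' @param corpus named list of documents.
#' @export
write_brat_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (doc in corpus) {
    out <- write_brat_document(doc)
    writeLines(out$txt, file.path(dir, paste0(doc$doc_id, ".txt")), sep = "")
    writeLines(out$ann, file.path(dir, paste0(doc$doc_id, ".ann")), sep = "\n")
  }
  invisible(dir)
}

#' Default sentence segmenter
#'
#' Splits on `.`, `!` or `?` followed by whitespace (or end of text).
#' Returns 0-based half-open spans that tile the text: each span extends to
#' the start of the next sentence so no character is orphaned.
#'
#' @param text document text.
#' @return data.frame with columns `start`, `end`.
#' @export
default_segmenter <- function(text) {
  n <- nchar(text)
  if (n == 0L) stop("cannot segment empty text", call. = FALSE)
  m <- gregexpr("[.!?](\\s+|$)", text, perl = TRUE)[[1]]
  ends <- if (m[1] == -1L) integer() else
    as.integer(m) + attr(m, "match.length") - 1L  # 1-based inclusive end
  starts0 <- c(0L, ends)
  starts0 <- starts0[starts0 < n]
  ends0 <- c(starts0[-1], n)
  data.frame(start = starts0, end = ends0)
}

#' Segment a document and bind entities to sentences
#'
#' Sentence spans partition the text.  Every entity is assigned to the
#' unique sentence that contains it; if an entity straddles a proposed
#' boundary the two sentences are merged (gold entities are taken as given,
#' so they are never truncated).  Relations whose arguments end up in
#' different sentences are flagged `cross_sentence`.
#'
#' @param doc a [brat_document()].
#' @param segmenter function(text) -> data.frame(start, end) with 0-based
#'   half-open spans tiling the text.
#' @return the document with `sentences`, `entities$sentence` and
#'   `relations$cross_sentence` populated.
#' @export
segment_and_bind <- function(doc, segmenter = default_segmenter) {
  spans <- segmenter(doc$text)
  spans <- spans[order(spans$start), , drop = FALSE]
  # merge sentences until no entity straddles a boundary
  repeat {
    straddle <- FALSE
    for (i in seq_len(nrow(doc$entities))) {
      e <- doc$entities[i, ]
      inside <- which(spans$start <= e$start & e$end <= spans$end)
      if (!length(inside)) {
        first <- max(which(spans$start <= e$start))
        last <- min(which(spans$end >= e$end))
        spans <- rbind(
          spans[seq_len(first - 1L), , drop = FALSE],
          data.frame(start = spans$start[first], end = spans$end[last]),
          if (last < nrow(spans)) spans[seq(last + 1L, nrow(spans)), , drop = FALSE]
        )
        straddle <- TRUE
        break
      }
    }
    if (!straddle) break
  }
  spans$index <- seq_len(nrow(spans))
  doc$sentences <- spans[, c("index", "start", "end")]
  if (nrow(doc$entities)) {
    doc$entities$sentence <- vapply(seq_len(nrow(doc$entities)), function(i) {
      which(spans$start <= doc$entities$start[i] & doc$entities$end[i] <= spans$end)[1]
    }, integer(1))
  }
  if (nrow(doc$relations)) {
    sent_of <- stats::setNames(doc$entities$sentence, doc$entities$id)
    doc$relations$cross_sentence <-
      sent_of[doc$relations$arg1] != sent_of[doc$relations$arg2]
  }
  doc
}

# signature string for each relation mention in a bound or unbound document
relation_signature_strings <- function(doc) {
  if (!nrow(doc$relations)) return(character())
  type_of <- stats::setNames(doc$entities$type, doc$entities$id)
  paste(type_of[doc$relations$arg1], doc$relations$predicate,
        type_of[doc$relations$arg2], sep = "-")
}

#' Tabulate relation signatures attested in a corpus
#'
#' Counts every relation mention under its signature (arg1 type, predicate,
#' arg2 type) and keeps signatures attested at least `min_count` times.
#' The study protocol uses `min_count = 100` on the real corpus.
#'
#' @param corpus list of [brat_document()].
#' @param min_count minimum attestation count (>= 1).
#' @return data.frame with columns `signature`, `arg1_type`, `predicate`,
#'   `arg2_type`, `count`, sorted by count descending (ties alphabetical).
#' @export
select_studied_signatures <- function(corpus, min_count = 100L) {
  stopifnot(min_count >= 1L)
  sigs <- unlist(lapply(corpus, relation_signature_strings), use.names = FALSE)
  if (!length(sigs)) {
    return(data.frame(signature = character(), arg1_type = character(),
                      predicate = character(), arg2_type = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  tab <- table(sigs)
  df <- data.frame(signature = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[df$count >= min_count, , drop = FALSE]
  df <- df[order(-df$count, df$signature), , drop = FALSE]
  parsed <- lapply(df$signature, parse_signature)
  df$arg1_type <- vapply(parsed, `[[`, character(1), "arg1_type")
  df$predicate <- vapply(parsed, `[[`, character(1), "predicate")
  df$arg2_type <- vapply(parsed, `[[`, character(1), "arg2_type")
  rownames(df) <- NULL
  df[, c("signature", "arg1_type", "predicate", "arg2_type", "count")]
}

#' Collapse the Characteristics subtypes into one category
#'
#' The fine-grained `Concepts&Ideas` / `Disorders` / `Physiology` /
#' `Phenomena` subtypes (UMLS Semantic Groups) are relabelled to a single
#' `Characteristic` type; relation signatures involving them merge and
#' their counts sum.  Idempotent.
#'
#' @param x a [brat_document()] or a corpus (list of documents).
#' @param subtypes labels to collapse.
#' @param to replacement label.
#' @export
collapse_characteristic_subtypes <- function(
    x,
    subtypes = c("Concepts&Ideas", "ConceptIdeas", "Disorders",
                 "Physiology", "Phenomena"),
    to = "Characteristic") {
  if (inherits(x, "brat_document")) {
    x$entities$type[x$entities$type %in% subtypes] <- to
    return(x)
  }
  lapply(x, collapse_characteristic_subtypes, subtypes = subtypes, to = to)
}
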