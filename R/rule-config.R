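#' Rule configuration for feature extraction
#'
#' Bundles the tunable inputs of the feature rules: the window width `k`
#' for entity context windows, the relation-verb lexicon (verb lemma ->
#' class, e.g. reduce -> DOWN_REGULATE), the biomedical nominalization
#' lexicon, and the semantically negative word list.  The shipped defaults
#' live under `inst/extdata/` as editable tab-separated files.
#'
#' @param window_k window width in tokens (>= 1).
#' @param verb_lexicon named character vector: verb lemma -> class.
#' @param nominalization_lexicon character vector of nominalized forms.
#' @param negation_words character vector of semantically negative words.
#' @return object of class `rule_config`.
#' @export
rule_config <- function(window_k = 3L,
                        verb_lexicon = character(),
                        nominalization_lexicon = character(),
                        negation_words = character()) {
  stopifnot(window_k >= 1L)
  structure(list(window_k = as.integer(window_k),
                 verb_lexicon = verb_lexicon,
                 nominalization_lexicon = tolower(nominalization_lexicon),
                 negation_words = tolower(negation_words)),
            class = "rule_config")
}

read_lexicon_tsv <- function(path) {
  if (!file.exists(path)) return(character())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (all(lengths(parts) >= 2L)) {
    stats::setNames(vapply(parts, `[`, character(1), 2L),
                    tolower(vapply(parts, `[`, character(1), 1L)))
  } else {
    tolower(vapply(parts, `[`, character(1), 1L))
  }
}

#' Default rule configuration with the shipped lexicons
#'
#' @param window_k window width, default 3.
#' @return a [rule_config()].
#' @export
default_rule_config <- function(window_k = 3L) {
  ext <- function(f) system.file("extdata", f, package = "bratrelex")
  rule_config(
    window_k = window_k,
    verb_lexicon = read_lexicon_tsv(ext("verb_lexicon.tsv")),
    nominalization_lexicon = read_lexicon_tsv(ext("nominalizations.tsv")),
    negation_words = read_lexicon_tsv(ext("negation_words.tsv"))
  )
}
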