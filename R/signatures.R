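#' Relation signatures
#'
#' A relation signature is the ordered triple `<arg1 type, predicate,
#' arg2 type>` that defines a distinct relation: `Gene-has-Mutation` is a
#' different relation from `Cohort-has-Mutation`, and argument order is
#' meaningful.
#'
#' @param arg1_type,arg2_type entity type labels.
#' @param predicate relation predicate, one of `"has"` or `"relatedTo"`.
#' @return an object of class `relation_signature`.
#' @examples
#' sig <- relation_signature("cohort", "has", "disease")
#' format(sig)
#' @export
relation_signature <- function(arg1_type, predicate, arg2_type) {
  stopifnot(is.character(arg1_type), length(arg1_type) == 1L, nzchar(arg1_type),
            is.character(arg2_type), length(arg2_type) == 1L, nzchar(arg2_type))
  predicate <- match.arg(predicate, c("has", "relatedTo"))
  structure(
    list(arg1_type = arg1_type, predicate = predicate, arg2_type = arg2_type),
    class = "relation_signature"
  )
}

#' @export
format.relation_signature <- function(x, ...) {
  paste(x$arg1_type, x$predicate, x$arg2_type, sep = "-")
}

#' @export
print.relation_signature <- function(x, ...) {
  cat("<relation_signature> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.relation_signature` <- function(e1, e2) {
  identical(unclass(e1), unclass(e2))
}

#' Parse a signature string such as "Cohort-has-Disease"
#'
#' The predicate token (`has` or `relatedTo`, matched case-insensitively)
#' splits the string; type labels may themselves contain hyphens as long as
#' they do not equal a predicate name.
#'
#' @param x a character scalar like `"cohort-has-disease"`.
#' @return a [relation_signature()].
#' @export
parse_signature <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  parts <- strsplit(x, "-", fixed = TRUE)[[1]]
  pred_idx <- which(tolower(parts) %in% c("has", "relatedto"))
  if (length(pred_idx) != 1L || pred_idx == 1L || pred_idx == length(parts)) {
    stop("cannot parse relation signature: ", x, call. = FALSE)
  }
  pred <- if (tolower(parts[pred_idx]) == "has") "has" else "relatedTo"
  relation_signature(
    paste(parts[seq_len(pred_idx - 1L)], collapse = "-"),
    pred,
    paste(parts[seq(pred_idx + 1L, length(parts))], collapse = "-")
  )
}
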