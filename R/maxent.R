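#' Maximum-entropy (multinomial logistic) classifier
#'
#' The classifiers used throughout the pipeline are maximum-entropy models:
#' conditional multinomial logistic models over sparse indicator features,
#' fitted by maximising the L2-penalised log-likelihood with the L-BFGS
#' quasi-Newton optimiser.  Training is deterministic: weights start at
#' zero and the objective is convex.
#'
#' @param examples list of character vectors, one per example, each the
#'   active indicator features of that example (see [feature_strings()]);
#'   alternatively a sparse `Matrix::dgCMatrix` design matrix.
#' @param y character vector of labels, one per example.
#' @param labels the full label set; every label must be attested in `y`.
#' @param l2 L2 regularisation strength (default 1.0).
#' @param tol convergence tolerance on the objective (default 1e-6).
#' @param max_iter maximum L-BFGS iterations (default 500).
#' @return object of class `maxent_model` with elements `labels`,
#'   `features` (feature name inventory), `weights` (features+bias x
#'   labels matrix), `converged`, `iterations`, `objective_trace`.
#' @export
train_maxent <- function(examples, y, labels = sort(unique(y)), l2 = 1.0,
                         tol = 1e-6, max_iter = 500L) {
  stopifnot(length(examples) == length(y) || inherits(examples, "Matrix"))
  missing_lab <- setdiff(labels, unique(y))
  if (length(missing_lab)) {
    stop("label(s) absent from training examples: ",
         paste(missing_lab, collapse = ", "), call. = FALSE)
  }
  if (any(!(y %in% labels))) stop("example label outside declared label set", call. = FALSE)

  if (inherits(examples, "Matrix") || is.matrix(examples)) {
    X <- methods::as(examples, "CsparseMatrix")
    feat_names <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  } else {
    feat_names <- sort(unique(unlist(examples, use.names = FALSE)))
    X <- sparse_design(examples, feat_names)
  }
  if (length(X@x) && any(!is.finite(X@x))) {
    stop("non-finite feature value", call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X); K <- length(labels)
  X <- cbind(X, Matrix::sparseMatrix(i = seq_len(n), j = rep(1L, n), x = 1,
                                     dims = c(n, 1L)))  # bias column
  Y <- Matrix::sparseMatrix(i = seq_len(n), j = match(y, labels), x = 1,
                            dims = c(n, K))

  trace_env <- new.env()
  trace_env$obj <- numeric()
  nll <- function(w) {
    W <- matrix(w, nrow = p + 1L, ncol = K)
    S <- as.matrix(X %*% W)
    m <- apply(S, 1L, max)
    logZ <- m + log(rowSums(exp(S - m)))
    ll <- sum(S[cbind(seq_len(n), match(y, labels))]) - sum(logZ)
    val <- -ll + 0.5 * l2 * sum(w^2)
    trace_env$obj <- c(trace_env$obj, val)
    val
  }
  grad <- function(w) {
    W <- matrix(w, nrow = p + 1L, ncol = K)
    S <- as.matrix(X %*% W)
    m <- apply(S, 1L, max)
    P <- exp(S - m); P <- P / rowSums(P)
    G <- as.matrix(Matrix::crossprod(X, P - Y))
    as.numeric(G) + l2 * w
  }
  fit <- stats::optim(rep(0, (p + 1L) * K), nll, grad, method = "L-BFGS-B",
                      control = list(maxit = max_iter, factr = tol / .Machine$double.eps))
  W <- matrix(fit$par, nrow = p + 1L, ncol = K,
              dimnames = list(c(feat_names, "(bias)"), labels))
  structure(list(labels = labels, features = feat_names, weights = W,
                 l2 = l2, converged = fit$convergence == 0L,
                 iterations = fit$counts[["function"]],
                 objective_trace = trace_env$obj),
            class = "maxent_model")
}

sparse_design <- function(examples, feat_names) {
  ij <- lapply(seq_along(examples), function(i) {
    j <- match(examples[[i]], feat_names)
    j <- j[!is.na(j)]
    if (length(j)) cbind(i = i, j = unique(j)) else NULL
  })
  ij <- do.call(rbind, ij)
  if (is.null(ij)) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(length(examples), length(feat_names)),
                                dimnames = list(NULL, feat_names)))
  }
  Matrix::sparseMatrix(i = ij[, "i"], j = ij[, "j"], x = 1,
                       dims = c(length(examples), length(feat_names)),
                       dimnames = list(NULL, feat_names))
}

#' Predict label probabilities from a maxent model
#'
#' @param object a `maxent_model`.
#' @param newdata list of feature-string vectors (unknown features are
#'   ignored) or a design matrix over `object$features`.
#' @param ... unused.
#' @return matrix of probabilities, one row per example, columns =
#'   `object$labels`; rows sum to 1.
#' @export
predict.maxent_model <- function(object, newdata, ...) {
  p <- length(object$features)
  X <- if (inherits(newdata, "Matrix") || is.matrix(newdata)) {
    methods::as(newdata, "CsparseMatrix")
  } else {
    sparse_design(newdata, object$features)
  }
  n <- nrow(X)
  X <- cbind(X, Matrix::sparseMatrix(i = seq_len(n), j = rep(1L, n), x = 1,
                                     dims = c(n, 1L)))
  S <- as.matrix(X %*% object$weights)
  m <- apply(S, 1L, max)
  P <- exp(S - m)
  P <- P / rowSums(P)
  colnames(P) <- object$labels
  P
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model> %d labels (%s), %d features, %sconverged in %d evals\n",
              length(x$labels), paste(x$labels, collapse = ","),
              length(x$features), if (x$converged) "" else "NOT ",
              x$iterations))
  invisible(x)
}

#' Save / load maxent models as versioned plain text
#'
#' @param model a `maxent_model`.
#' @param path file path.
#' @export
write_maxent_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("bratrelex-maxent v1",
               paste0("labels\t", paste(model$labels, collapse = "\t")),
               paste0("l2\t", format(model$l2, digits = 17))), con)
  w <- model$weights
  for (i in seq_len(nrow(w))) {
    writeLines(paste(c(rownames(w)[i], format(w[i, ], digits = 17)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_maxent_model
#' @export
read_maxent_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stopifnot(lines[1] == "bratrelex-maxent v1")
  labels <- strsplit(lines[2], "\t", fixed = TRUE)[[1]][-1]
  l2 <- as.numeric(strsplit(lines[3], "\t", fixed = TRUE)[[1]][2])
  rows <- strsplit(lines[-(1:3)], "\t", fixed = TRUE)
  feat <- vapply(rows, `[`, character(1), 1L)
  W <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(labels))))
  dimnames(W) <- list(feat, labels)
  structure(list(labels = labels, features = setdiff(feat, "(bias)"),
                 weights = W, l2 = l2, converged = TRUE, iterations = NA_integer_,
                 objective_trace = numeric()),
            class = "maxent_model")
}
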