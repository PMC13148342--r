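#' Score matrices
#'
#' An `ousio_scores` object holds an N x D matrix of term scores in a named
#' framework (VAD, GAS, or PDS), one row per term, columns in framework
#' order.
#'
#' @param terms Character vector of terms (row labels).
#' @param values Numeric matrix, one row per term, finite throughout.
#' @param framework Framework name, e.g. `"VAD"`, `"GAS"`, `"PDS"`.
#' @param dims Column (dimension) names; defaults follow the framework.
#' @return An object of class `ousio_scores` with fields `terms`, `values`,
#'   `framework`.
#' @export
score_matrix <- function(terms, values, framework,
                         dims = default_dims(framework)) {
  values <- as.matrix(values)
  if (length(terms) != nrow(values)) {
    stop_contract("number of terms must equal number of score rows")
  }
  if (any(!is.finite(values))) stop_validation("scores must all be finite")
  if (!is.null(dims)) {
    if (length(dims) != ncol(values)) {
      stop_contract("dims length must match score columns")
    }
    colnames(values) <- dims
  }
  structure(
    list(terms = as.character(terms), values = values, framework = framework),
    class = "ousio_scores"
  )
}

default_dims <- function(framework) {
  switch(toupper(framework),
    VAD = c("Va", "Ar", "Dm"),
    GAS = c("Gd", "Ag", "St"),
    PDS = c("Pw", "Dg", "St"),
    NULL
  )
}

#' @export
print.ousio_scores <- function(x, ...) {
  cat(sprintf(
    "<ousio_scores> %d terms x %d dims (%s: %s)\n",
    length(x$terms), ncol(x$values), x$framework,
    paste(colnames(x$values), collapse = ", ")
  ))
  invisible(x)
}

#' Convert a centered lexicon to a VAD score matrix
#'
#' @param lex A centered `ousio_lexicon`.
#' @return An `ousio_scores` in the VAD framework.
#' @export
as_score_matrix <- function(lex) {
  stopifnot(inherits(lex, "ousio_lexicon"))
  if (!isTRUE(attr(lex, "centered"))) {
    stop_contract("score matrices are built from centered lexicons; call center_scores() first")
  }
  score_matrix(lex$term, as.matrix(as.data.frame(lex)[, c("va", "ar", "dm")]),
    framework = "VAD"
  )
}

# Pull one named dimension as a named numeric vector.
score_dimension <- function(scores, dimension) {
  stopifnot(inherits(scores, "ousio_scores"))
  j <- match(dimension, colnames(scores$values))
  if (is.na(j)) {
    stop_contract(sprintf(
      "dimension %s not in framework %s (%s)", dimension, scores$framework,
      paste(colnames(scores$values), collapse = ", ")
    ))
  }
  stats::setNames(scores$values[, j], scores$terms)
}
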