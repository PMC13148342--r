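#' Frequency distributions
#'
#' An `ousio_freq` maps terms to nonnegative weights (raw counts or merged
#' probabilities) and records how many sub-corpora contributed.
#'
#' @param weights Named nonnegative numeric vector (term -> weight).
#' @param n_subcorpora Number of sub-corpora merged into these weights.
#' @param label Free-text label.
#' @return An object of class `ousio_freq`.
#' @export
frequency_distribution <- function(weights, n_subcorpora = 1L, label = "") {
  if (length(weights) == 0L) {
    weights <- stats::setNames(numeric(0), character(0))
  }
  if (is.null(names(weights)) && length(weights) > 0L) {
    stop_contract("weights must be a named vector")
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop_validation("weights must be finite and nonnegative")
  }
  structure(
    list(
      weights = weights, n_subcorpora = as.integer(n_subcorpora),
      label = label
    ),
    class = "ousio_freq"
  )
}

#' @export
print.ousio_freq <- function(x, ...) {
  cat(sprintf(
    "<ousio_freq> %d types, total weight %.6g, %d sub-corpora%s\n",
    length(x$weights), sum(x$weights), x$n_subcorpora,
    if (nzchar(x$label)) paste0(" (", x$label, ")") else ""
  ))
  invisible(x)
}

#' Normalized-probability view of a frequency distribution
#'
#' @param dist An `ousio_freq` with positive total weight.
#' @return Named numeric vector of probabilities summing to 1.
#' @export
as_probabilities <- function(dist) {
  stopifnot(inherits(dist, "ousio_freq"))
  if (length(dist$weights) == 0L || sum(dist$weights) <= 0) {
    stop_contract("distribution has no positive weight")
  }
  dist$weights / sum(dist$weights)
}

#' Read a term-count frequency file
#'
#' Tab-separated rows of `term<TAB>count`. Duplicate terms are summed; rows
#' with negative or non-numeric counts are rejected and counted.
#'
#' @param path Path to a UTF-8 TSV file.
#' @param label Label for the distribution (defaults to the file name).
#' @return An `ousio_freq` with `n_subcorpora = 1` and attribute
#'   `rows_rejected`.
#' @export
read_frequency_tsv <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop_io(sprintf("frequency file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_io(sprintf("frequency file is empty: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  term <- vapply(fields, function(f) if (length(f) >= 2L) f[[1L]] else NA_character_, "")
  count <- suppressWarnings(vapply(
    fields, function(f) if (length(f) >= 2L) as.numeric(f[[2L]]) else NA_real_, 0
  ))
  bad <- is.na(term) | is.na(count) | !is.finite(count) | count < 0
  if (all(bad)) stop_io(sprintf("no valid rows in frequency file: %s", path))
  term <- normalize_term(term[!bad])
  count <- count[!bad]
  w <- vapply(split(count, term), sum, 0)
  # restore first-appearance order of terms
  w <- w[unique(term)]
  fd <- frequency_distribution(w, n_subcorpora = 1L, label = label)
  attr(fd, "rows_rejected") <- sum(bad)
  fd
}

#' Merge sub-corpora with equal weight
#'
#' Each input distribution is normalized to probabilities and the
#' probabilities are averaged with weight 1/k, so that sub-corpora of very
#' different sizes (years, days) contribute equally. The result has total
#' weight 1.
#'
#' @param dists A list of `ousio_freq`, each with positive total weight.
#' @param label Label for the merged distribution.
#' @return An `ousio_freq` with `n_subcorpora` equal to the number of inputs.
#' @export
merge_equal_weight <- function(dists, label = "merged") {
  if (inherits(dists, "ousio_freq")) dists <- list(dists)
  if (length(dists) < 1L) stop_validation("need at least one distribution")
  for (d in dists) {
    stopifnot(inherits(d, "ousio_freq"))
    if (sum(d$weights) <= 0) stop_validation("cannot merge a distribution with zero total weight")
  }
  k <- length(dists)
  terms <- unique(unlist(lapply(dists, function(d) names(d$weights)), use.names = FALSE))
  out <- stats::setNames(numeric(length(terms)), terms)
  for (d in dists) {
    p <- as_probabilities(d)
    out[names(p)] <- out[names(p)] + p / k
  }
  frequency_distribution(out, n_subcorpora = k, label = label)
}

#' Frequency ranks with tie averaging
#'
#' Rank 1 is the most frequent term; terms with tied weights share the
#' arithmetic mean of the ranks they would span if untied.
#'
#' @param dist An `ousio_freq` with positive total weight.
#' @return Named numeric vector of ranks.
#' @export
#' @examples
#' rank_with_tie_averaging(frequency_distribution(c(a = 5, b = 5, c = 2)))
rank_with_tie_averaging <- function(dist) {
  stopifnot(inherits(dist, "ousio_freq"))
  if (sum(dist$weights) <= 0) stop_contract("distribution has no positive weight")
  rank(-dist$weights, ties.method = "average")
}

#' Apply the lexical lens
#'
#' Restricts a frequency distribution to the terms present in a lexicon,
#' preserving their weights, and reports how much of the input survived.
#'
#' @param dist An `ousio_freq`.
#' @param lex An `ousio_lexicon` or an `ousio_scores` (its term set is used).
#' @param min_token_coverage Warn (never error) when token coverage falls
#'   below this fraction.
#' @return A list with `dist` (the lensed `ousio_freq`) and `coverage`, a list
#'   with `tokens_total`, `tokens_matched`, `type_coverage`, `token_coverage`.
#' @export
lexical_lens <- function(dist, lex, min_token_coverage = 0.25) {
  stopifnot(inherits(dist, "ousio_freq"))
  lex_terms <- if (inherits(lex, "ousio_scores")) lex$terms else lex$term
  inside <- names(dist$weights) %in% lex_terms
  lensed <- frequency_distribution(dist$weights[inside],
    n_subcorpora = dist$n_subcorpora,
    label = paste0(dist$label, " [lensed]")
  )
  tot <- sum(dist$weights)
  coverage <- list(
    tokens_total = tot,
    tokens_matched = sum(dist$weights[inside]),
    type_coverage = if (length(inside)) mean(inside) else 0,
    token_coverage = if (tot > 0) sum(dist$weights[inside]) / tot else 0
  )
  if (coverage$token_coverage < min_token_coverage) {
    warning(sprintf(
      "token coverage %.1f%% is below %.0f%%; statistics may be unreliable",
      100 * coverage$token_coverage, 100 * min_token_coverage
    ), call. = FALSE)
  }
  list(dist = lensed, coverage = coverage)
}

#' Token-weighted average of one essential dimension
#'
#' The probability-weighted mean sum(p_tau * M_tau) of the named dimension
#' over a lensed frequency distribution. Invariant under positive rescaling
#' of all weights.
#'
#' @param dist An `ousio_freq` whose terms are all present in `scores`
#'   (apply [lexical_lens()] first).
#' @param scores An `ousio_scores`.
#' @param dimension Name of the dimension to average.
#' @return A single number bounded by the min and max score present.
#' @export
ousiometric_average <- function(dist, scores, dimension) {
  stopifnot(inherits(dist, "ousio_freq"))
  if (length(dist$weights) == 0L || sum(dist$weights) <= 0) {
    stop_contract("distribution has no positive weight; lens the corpus first and check coverage")
  }
  v <- score_dimension(scores, dimension)
  idx <- match(names(dist$weights), names(v))
  if (anyNA(idx)) {
    stop_contract("distribution contains terms absent from the score matrix; apply lexical_lens() first")
  }
  sum(as_probabilities(dist) * v[idx])
}

#' Per-dimension bias summary of a corpus
#'
#' Token-weighted mean, median, and skewness for every dimension of a score
#' matrix. The median is the smallest score whose cumulative probability
#' reaches 0.5 (no interpolation); skewness is the probability-weighted
#' moment ratio m3/m2^(3/2). Pass uniform weights over the lexicon terms for
#' type-level summaries.
#'
#' @inheritParams ousiometric_average
#' @return A list of class `bias_summary`: `framework`, per-dimension
#'   `mean`, `median`, `skewness`, plus `median_convention`.
#' @export
bias_summary <- function(dist, scores) {
  stopifnot(inherits(dist, "ousio_freq"), inherits(scores, "ousio_scores"))
  if (length(dist$weights) == 0L || sum(dist$weights) <= 0) {
    stop_contract("distribution has no positive weight")
  }
  idx <- match(names(dist$weights), scores$terms)
  if (anyNA(idx)) {
    stop_contract("distribution contains terms absent from the score matrix; apply lexical_lens() first")
  }
  w <- dist$weights
  dims <- colnames(scores$values)
  stat <- function(f) {
    vapply(dims, function(d) f(scores$values[idx, d], w), 0)
  }
  structure(
    list(
      framework = scores$framework,
      mean = stat(weighted_mean),
      median = stat(weighted_median),
      skewness = stat(weighted_skewness),
      median_convention = "lower (cumulative probability >= 0.5, no interpolation)"
    ),
    class = "bias_summary"
  )
}

#' Uniform weights over the terms of a score matrix
#'
#' Convenience for type-level statistics: every term gets weight 1.
#'
#' @param scores An `ousio_scores`.
#' @param label Label for the distribution.
#' @return An `ousio_freq`.
#' @export
uniform_weights <- function(scores, label = "type-level (uniform)") {
  stopifnot(inherits(scores, "ousio_scores"))
  frequency_distribution(
    stats::setNames(rep(1, length(scores$terms)), scores$terms),
    label = label
  )
}

#' @export
print.bias_summary <- function(x, ...) {
  cat(sprintf("<bias_summary> framework %s\n", x$framework))
  print(round(rbind(mean = x$mean, median = x$median, skewness = x$skewness), 4))
  invisible(x)
}

#' Export a bias summary or coverage report as JSON
#'
#' @param x A `bias_summary` or the `coverage` list from [lexical_lens()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_summary_json <- function(x, path) {
  if (inherits(x, "bias_summary")) {
    x <- unclass(x)
    # keep dimension names in the JSON (objects, not bare arrays)
    for (field in c("mean", "median", "skewness")) x[[field]] <- as.list(x[[field]])
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
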