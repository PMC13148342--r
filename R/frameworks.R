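#' Framework bases
#'
#' A `framework_basis` is a named orthonormal change of basis from source
#' dimensions (typically Va, Ar, Dm) to target dimensions. Row i of `matrix`
#' gives the weights expressing target dimension i as a linear combination of
#' the source dimensions. SVD-derived bases also carry singular values;
#' explained-variance fractions are carried whenever known.
#'
#' @param matrix Square numeric matrix, rows approximately orthonormal.
#' @param source_dims,target_dims Character vectors of dimension names.
#' @param name Framework name (e.g. `"GAS"`, `"PDS"`).
#' @param singular_values Optional nonincreasing nonnegative values (only for
#'   SVD-derived bases).
#' @param explained_variance Optional fractions summing to 1.
#' @param degenerate Logical, `TRUE` when the deriving data was rank
#'   deficient.
#' @param derivation Free-text derivation tag (`"svd"`, `"rotation"`,
#'   `"reference"`).
#' @param orthonormal_tol Largest allowed deviation of `matrix %*% t(matrix)`
#'   from the identity (reference matrices printed to two decimals need a
#'   loose tolerance).
#' @return An object of class `framework_basis`.
#' @export
framework_basis <- function(matrix, source_dims, target_dims, name,
                            singular_values = NULL,
                            explained_variance = NULL,
                            degenerate = FALSE,
                            derivation = "manual",
                            orthonormal_tol = 0.05) {
  m <- as.matrix(matrix)
  d <- nrow(m)
  if (ncol(m) != d) stop_contract("basis matrix must be square")
  if (length(source_dims) != d || length(target_dims) != d) {
    stop_contract("dimension name lengths must match the matrix")
  }
  dev <- max(abs(m %*% t(m) - diag(d)))
  if (dev > orthonormal_tol) {
    stop_validation(sprintf(
      "basis rows are not orthonormal (max deviation %.3g)", dev
    ))
  }
  if (!is.null(singular_values)) {
    if (any(singular_values < 0) || is.unsorted(rev(singular_values))) {
      stop_contract("singular values must be nonnegative and nonincreasing")
    }
  }
  if (!is.null(explained_variance) &&
      abs(sum(explained_variance) - 1) > 1e-6) {
    stop_contract("explained_variance must sum to 1")
  }
  dimnames(m) <- list(target_dims, source_dims)
  structure(
    list(
      name = name, matrix = m,
      source_dims = source_dims, target_dims = target_dims,
      singular_values = singular_values,
      explained_variance = explained_variance,
      degenerate = isTRUE(degenerate),
      derivation = derivation,
      orthonormal_deviation = dev
    ),
    class = "framework_basis"
  )
}

#' @export
print.framework_basis <- function(x, ...) {
  cat(sprintf(
    "<framework_basis> %s: (%s) <- (%s)%s\n", x$name,
    paste(x$target_dims, collapse = ", "),
    paste(x$source_dims, collapse = ", "),
    if (x$degenerate) " [degenerate]" else ""
  ))
  print(round(x$matrix, 3))
  if (!is.null(x$singular_values)) {
    cat("singular values:", paste(signif(x$singular_values, 4), collapse = ", "), "\n")
  }
  if (!is.null(x$explained_variance)) {
    cat(
      "explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "), "\n"
    )
  }
  invisible(x)
}

#' Derive the GAS basis from centered VAD scores by SVD
#'
#' Performs a singular value decomposition of the N x D centered score
#' matrix. The target dimensions are the right-singular directions ordered by
#' descending singular value, with the sign ambiguity fixed by convention:
#' goodness has positive weight on valence, aggression positive weight on
#' arousal, and structure negative weight on dominance. Explained-variance
#' fractions are the squared singular values over their sum.
#'
#' The core does not assume three columns; for D other than 3 the sign
#' convention defaults to a positive diagonal weight for every dimension but
#' the last, which is negative.
#'
#' @param scores An `ousio_scores` in the VAD framework (centered scores).
#' @param sign_convention Numeric vector of +-1, one per target dimension;
#'   entry i constrains the sign of the weight of target dimension i on
#'   source dimension i.
#' @return A `framework_basis` named `"GAS"`. Rank-deficient input (a zero
#'   singular value) still returns a basis, flagged `degenerate`.
#' @export
#' @examples
#' lex <- generate_synthetic_lexicon(synthetic_lexicon_spec(n_terms = 500, seed = 3))
#' derive_gas_basis(as_score_matrix(lex))
derive_gas_basis <- function(scores,
                             sign_convention = NULL) {
  stopifnot(inherits(scores, "ousio_scores"))
  x <- scores$values
  d <- ncol(x)
  if (nrow(x) < d) stop_contract("need at least as many terms as dimensions")
  if (all(apply(x, 2L, function(c) max(c) == min(c)))) {
    stop_validation("all score columns are constant; no basis can be derived")
  }
  if (is.null(sign_convention)) sign_convention <- c(rep(1, d - 1L), -1)
  if (length(sign_convention) != d || any(abs(sign_convention) != 1)) {
    stop_contract("sign_convention must be +-1, one entry per dimension")
  }
  sv <- svd(x)
  m <- t(sv$v) # rows = right-singular directions, descending singular value
  for (i in seq_len(d)) {
    pivot <- m[i, i]
    if (pivot == 0) pivot <- m[i, which(m[i, ] != 0)[1L]] * sign_convention[i]
    if (sign(pivot) != sign_convention[i]) m[i, ] <- -m[i, ]
  }
  sing <- sv$d
  degenerate <- any(sing <= max(sing) * 1e-12)
  target <- if (d == 3L && identical(colnames(x), c("Va", "Ar", "Dm"))) {
    c("Gd", "Ag", "St")
  } else {
    sprintf("S%d", seq_len(d))
  }
  framework_basis(m,
    source_dims = colnames(x), target_dims = target, name = "GAS",
    singular_values = sing,
    explained_variance = explained_variances(sing),
    degenerate = degenerate, derivation = "svd",
    orthonormal_tol = 1e-9
  )
}

#' Rotate the GAS basis into the PDS basis
#'
#' Applies the -pi/4 rotation of the goodness-aggression plane:
#' power = (goodness + aggression)/sqrt(2) and
#' danger = (aggression - goodness)/sqrt(2); structure is unchanged.
#' Explained variance is recomputed for the rotated dimensions: with
#' goodness and aggression uncorrelated (as SVD guarantees), power and danger
#' each carry the mean of the two plane fractions.
#'
#' @param gas A `framework_basis` with target dimensions Gd, Ag, St.
#' @return A `framework_basis` named `"PDS"` with target dimensions
#'   Pw, Dg, St.
#' @export
rotate_gas_to_pds <- function(gas) {
  stopifnot(inherits(gas, "framework_basis"))
  if (!identical(gas$target_dims, c("Gd", "Ag", "St"))) {
    stop_contract("rotate_gas_to_pds requires a basis with dims Gd, Ag, St")
  }
  r <- 1 / sqrt(2)
  rot <- matrix(c(
    r, r, 0,
    -r, r, 0,
    0, 0, 1
  ), 3, 3, byrow = TRUE)
  m <- rot %*% gas$matrix
  ev <- gas$explained_variance
  if (!is.null(ev)) ev <- c(mean(ev[1:2]), mean(ev[1:2]), ev[3])
  framework_basis(m,
    source_dims = gas$source_dims, target_dims = c("Pw", "Dg", "St"),
    name = "PDS",
    explained_variance = ev,
    degenerate = gas$degenerate, derivation = "rotation",
    orthonormal_tol = max(1e-9, 4 * gas$orthonormal_deviation)
  )
}

#' Transform scores into another framework
#'
#' Row-wise matrix product of the scores with the transpose of the basis
#' matrix; term order is preserved.
#'
#' @param scores An `ousio_scores` whose dimensions match the basis source
#'   dimensions.
#' @param basis A `framework_basis`.
#' @return An `ousio_scores` in the basis target framework.
#' @export
apply_basis <- function(scores, basis) {
  stopifnot(inherits(scores, "ousio_scores"), inherits(basis, "framework_basis"))
  if (!identical(colnames(scores$values), basis$source_dims)) {
    stop_contract(sprintf(
      "score dimensions (%s) do not match basis source dimensions (%s)",
      paste(colnames(scores$values), collapse = ", "),
      paste(basis$source_dims, collapse = ", ")
    ))
  }
  score_matrix(scores$terms, scores$values %*% t(basis$matrix),
    framework = basis$name, dims = basis$target_dims
  )
}

#' Pairwise Pearson correlations of score dimensions
#'
#' Unweighted by default (type level); with a frequency distribution the
#' correlations are token weighted, using normalized probabilities as
#' frequency weights in the means and covariances. A zero-variance column
#' yields `NA` correlations (flagged missing, never zero).
#'
#' @param scores An `ousio_scores`.
#' @param weights Optional `ousio_freq`; every weighted term must be present
#'   in `scores`.
#' @return Symmetric D x D correlation matrix with unit diagonal.
#' @export
pairwise_correlations <- function(scores, weights = NULL) {
  stopifnot(inherits(scores, "ousio_scores"))
  x <- scores$values
  if (nrow(x) < 2L) stop_contract("need at least two terms")
  if (is.null(weights)) {
    w <- rep(1, nrow(x))
  } else {
    stopifnot(inherits(weights, "ousio_freq"))
    idx <- match(names(weights$weights), scores$terms)
    if (anyNA(idx)) {
      stop_validation("weights contain terms absent from the score matrix")
    }
    w <- numeric(nrow(x))
    w[idx] <- weights$weights
  }
  d <- ncol(x)
  r <- diag(1, d)
  dimnames(r) <- list(colnames(x), colnames(x))
  for (i in seq_len(d - 1L)) {
    for (j in (i + 1L):d) {
      r[i, j] <- r[j, i] <- weighted_pearson(x[, i], x[, j], w)
    }
  }
  r
}

#' Explained-variance fractions from singular values
#'
#' @param singular_values Nonnegative singular values.
#' @return Fractions `sigma_i^2 / sum(sigma_j^2)`, summing to 1.
#' @export
#' @examples
#' round(explained_variances(c(34.1, 27.2, 13.8)), 3)
explained_variances <- function(singular_values) {
  if (any(singular_values < 0)) stop_contract("singular values must be nonnegative")
  tot <- sum(singular_values^2)
  if (tot == 0) stop_contract("singular values must not all be zero")
  singular_values^2 / tot
}

#' One-sigma SVD ellipse of a score plane
#'
#' Centers the chosen coordinate pair on its (weighted) mean and reports the
#' principal directions and one-sigma radii of the (weighted) covariance,
#' equivalent to the 2D singular directions with singular values scaled by
#' 1/sqrt(N).
#'
#' @param scores An `ousio_scores`.
#' @param dim_pair Character vector of two dimension names.
#' @param weights Optional `ousio_freq` of token weights.
#' @return A list with `center`, `axes` (columns are unit directions, major
#'   first), `radii`, `degenerate`, and `scaling = "one-sigma"`.
#' @export
plane_svd_ellipse <- function(scores, dim_pair, weights = NULL) {
  stopifnot(inherits(scores, "ousio_scores"), length(dim_pair) == 2L)
  x <- score_dimension(scores, dim_pair[1L])
  y <- score_dimension(scores, dim_pair[2L])
  if (length(x) < 2L) stop_contract("need at least two terms")
  if (is.null(weights)) {
    w <- rep(1, length(x))
  } else {
    stopifnot(inherits(weights, "ousio_freq"))
    idx <- match(names(weights$weights), scores$terms)
    if (anyNA(idx)) stop_validation("weights contain terms absent from the score matrix")
    w <- numeric(length(x))
    w[idx] <- weights$weights
  }
  p <- normalize_weights(w)
  center <- c(sum(p * x), sum(p * y))
  dx <- x - center[1L]
  dy <- y - center[2L]
  cov <- matrix(c(
    sum(p * dx * dx), sum(p * dx * dy),
    sum(p * dx * dy), sum(p * dy * dy)
  ), 2, 2)
  eig <- eigen(cov, symmetric = TRUE)
  radii <- sqrt(pmax(eig$values, 0))
  axes <- eig$vectors
  for (k in 1:2) { # deterministic orientation
    nz <- which(abs(axes[, k]) > 1e-12)[1L]
    if (!is.na(nz) && axes[nz, k] < 0) axes[, k] <- -axes[, k]
  }
  list(
    center = stats::setNames(center, dim_pair),
    axes = axes, radii = radii,
    degenerate = all(radii <= 0),
    scaling = "one-sigma"
  )
}

#' Default cone half-angle
#'
#' Half of `acos(2/sqrt(6))`, about 17.6 degrees: the widest half-angle for
#' which cones around the 13 axes of a meaning cube do not overlap.
#'
#' @return Half-angle in radians.
#' @export
#' @examples
#' default_cone_half_angle() * 180 / pi
default_cone_half_angle <- function() {
  0.5 * acos(2 / sqrt(6))
}

#' Rank terms inside a cone around an axis
#'
#' Restricts terms to those whose full score vector makes an angle of at most
#' `half_angle` with `axis` (zero vectors excluded), ranked by descending
#' scalar projection onto the unit axis.
#'
#' @param scores An `ousio_scores`.
#' @param axis Nonzero numeric vector in framework coordinates.
#' @param half_angle Cone half-angle in radians.
#' @param top_n Maximum number of terms returned.
#' @return A list of class `cone_ranking` with `axis` (unit), `half_angle`,
#'   and `ranked`, a data frame of term and component.
#' @export
rank_terms_in_cone <- function(scores, axis,
                               half_angle = default_cone_half_angle(),
                               top_n = 20L) {
  stopifnot(inherits(scores, "ousio_scores"))
  axis <- as.numeric(axis)
  if (length(axis) != ncol(scores$values)) {
    stop_contract("axis length must match the number of score dimensions")
  }
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop_contract("axis must be nonzero")
  u <- axis / nrm
  proj <- as.vector(scores$values %*% u)
  mag <- sqrt(rowSums(scores$values^2))
  cosang <- ifelse(mag > 0, pmin(1, pmax(-1, proj / mag)), NA_real_)
  inside <- !is.na(cosang) & acos(cosang) <= half_angle + 1e-12
  o <- order(proj[inside], decreasing = TRUE)
  keep <- which(inside)[o]
  if (length(keep) > top_n) keep <- keep[seq_len(top_n)]
  structure(
    list(
      axis = u, half_angle = half_angle,
      ranked = data.frame(
        rank = seq_along(keep),
        term = scores$terms[keep],
        component = proj[keep],
        stringsAsFactors = FALSE
      )
    ),
    class = "cone_ranking"
  )
}

#' Write a cone ranking as TSV
#'
#' @param ranking A `cone_ranking`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cone_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "cone_ranking"))
  utils::write.table(ranking$ranked, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Export / import a framework basis as JSON
#'
#' @param basis A `framework_basis`.
#' @param path JSON file path.
#' @return `write_basis_json` returns `path` invisibly; `read_basis_json`
#'   returns a `framework_basis`.
#' @export
write_basis_json <- function(basis, path) {
  stopifnot(inherits(basis, "framework_basis"))
  payload <- list(
    name = basis$name,
    source_dims = basis$source_dims,
    target_dims = basis$target_dims,
    matrix = as.vector(t(basis$matrix)), # row-major
    singular_values = basis$singular_values,
    explained_variance = basis$explained_variance,
    degenerate = basis$degenerate,
    derivation = basis$derivation,
    sign_convention = "Gd.Va>0, Ag.Ar>0, St.Dm<0"
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_basis_json
#' @export
read_basis_json <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("basis file not found: %s", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- length(p$target_dims)
  framework_basis(
    matrix(p$matrix, d, d, byrow = TRUE),
    source_dims = p$source_dims, target_dims = p$target_dims,
    name = p$name,
    singular_values = p$singular_values,
    explained_variance = p$explained_variance,
    degenerate = isTRUE(p$degenerate),
    derivation = p$derivation %||% "imported"
  )
}

#' Reference GAS and PDS bases
#'
#' The two-decimal GAS and PDS transformation matrices reported for the
#' ~20,000-term best-worst-scaled VAD lexicon, together with its singular
#' values (34.1, 27.2, 13.8). Useful for arithmetic checks and for scoring
#' text when the deriving lexicon is not at hand; rows are orthonormal only
#' to the printed precision.
#'
#' @return A `framework_basis`.
#' @export
#' @examples
#' gas_reference_basis()
gas_reference_basis <- function() {
  m <- matrix(c(
    +0.86, -0.15, +0.48,
    -0.16, +0.83, +0.54,
    +0.48, +0.55, -0.69
  ), 3, 3, byrow = TRUE)
  sv <- c(34.1, 27.2, 13.8)
  framework_basis(m,
    source_dims = c("Va", "Ar", "Dm"), target_dims = c("Gd", "Ag", "St"),
    name = "GAS", singular_values = sv,
    explained_variance = explained_variances(sv),
    derivation = "reference"
  )
}

#' @rdname gas_reference_basis
#' @export
pds_reference_basis <- function() {
  m <- matrix(c(
    +0.50, +0.48, +0.72,
    -0.72, +0.69, +0.04,
    +0.48, +0.55, -0.69
  ), 3, 3, byrow = TRUE)
  ev <- explained_variances(c(34.1, 27.2, 13.8))
  framework_basis(m,
    source_dims = c("Va", "Ar", "Dm"), target_dims = c("Pw", "Dg", "St"),
    name = "PDS",
    explained_variance = c(mean(ev[1:2]), mean(ev[1:2]), ev[3]),
    derivation = "reference"
  )
}
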