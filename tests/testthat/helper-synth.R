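# Deterministic builders used across the suite.

# Scores with exactly zero-mean, mutually orthogonal columns of the given
# Euclidean norms (center-then-QR construction); SVD of the result is exact.
make_orthogonal_scores <- function(n, norms, framework = "VAD",
                                   dims = default_dims_for(framework),
                                   seed = 42) {
  z <- withr::with_seed(seed, matrix(rnorm(n * length(norms)), n))
  z <- scale(z, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(z))
  x <- q %*% diag(norms)
  score_matrix(sprintf("t%05d", seq_len(n)), x, framework, dims = dims)
}

default_dims_for <- function(framework) {
  switch(framework,
    VAD = c("Va", "Ar", "Dm"), GAS = c("Gd", "Ag", "St"),
    PDS = c("Pw", "Dg", "St")
  )
}

# Scores generated as Z diag(s) Q for a known orthogonal mixing Q (rows are
# the directions SVD should recover).
make_mixed_scores <- function(n, s, q_rows, seed = 7) {
  z <- withr::with_seed(seed, matrix(rnorm(n * length(s)), n))
  x <- z %*% diag(s) %*% q_rows
  score_matrix(sprintf("t%05d", seq_len(n)), x, "VAD",
    dims = c("Va", "Ar", "Dm")
  )
}

random_orthogonal3 <- function(seed = 11) {
  m <- withr::with_seed(seed, matrix(rnorm(9), 3))
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  t(q)
}

write_lexicon_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(rows, path, useBytes = TRUE)
  path
}

random_plane_scores <- function(n, framework = "PDS", seed = 5, sd = 0.2) {
  x <- withr::with_seed(seed, matrix(rnorm(n * 2, sd = sd), n))
  score_matrix(sprintf("t%04d", seq_len(n)), x, framework,
    dims = default_dims_for(framework)[1:2]
  )
}
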