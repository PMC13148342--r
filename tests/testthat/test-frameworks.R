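test_that("axis-aligned data yields a signed permutation of the identity", {
  sc <- make_orthogonal_scores(2000, norms = sqrt(c(3, 2, 1)) * 10, seed = 21)
  b <- derive_gas_basis(sc)
  expect_equal(abs(b$matrix), diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  expect_gt(b$matrix[1, 1], 0) # Gd weight on Va > 0
  expect_gt(b$matrix[2, 2], 0) # Ag weight on Ar > 0
  expect_lt(b$matrix[3, 3], 0) # St weight on Dm < 0
  expect_equal(sort(b$singular_values, decreasing = TRUE), b$singular_values)
})

test_that("SVD recovers a known orthonormal mixing within 0.02 at n = 20000", {
  q <- random_orthogonal3(seed = 31)
  s <- c(3, 2.2, 1) # gaps >= 20%
  sc <- make_mixed_scores(20000, s, q, seed = 8)
  b <- derive_gas_basis(sc)
  for (i in 1:3) {
    err <- min(
      max(abs(b$matrix[i, ] - q[i, ])),
      max(abs(b$matrix[i, ] + q[i, ]))
    )
    expect_lt(err, 0.02)
  }
})

test_that("basis derivation is deterministic and orthonormal, variances account for total SS", {
  lex <- generate_synthetic_lexicon(synthetic_lexicon_spec(n_terms = 3000, seed = 17))
  sc <- as_score_matrix(lex)
  b1 <- derive_gas_basis(sc)
  b2 <- derive_gas_basis(sc)
  expect_identical(b1$matrix, b2$matrix) # sign convention is idempotent
  expect_lt(max(abs(b1$matrix %*% t(b1$matrix) - diag(3))), 1e-9)
  expect_equal(sum(b1$explained_variance), 1, tolerance = 1e-9)
  expect_equal(sum(b1$singular_values^2), sum(sc$values^2), tolerance = 1e-6)
  # GAS-frame scores are decorrelated by construction
  gas_scores <- apply_basis(sc, b1)
  r <- pairwise_correlations(gas_scores)
  # correlations center on the (tiny) sample mean, SVD decorrelates about 0
  expect_lt(max(abs(r - diag(3))), 1e-2)
  # with exactly mean-zero columns the decorrelation is machine exact
  sc0 <- make_orthogonal_scores(1500, c(6, 4, 2), seed = 23)
  r0 <- pairwise_correlations(apply_basis(sc0, derive_gas_basis(sc0)))
  expect_lt(max(abs(r0 - diag(3))), 1e-9)
})

test_that("rank-deficient input still returns a basis flagged degenerate", {
  x <- withr::with_seed(3, matrix(rnorm(200), 100, 2))
  sc <- score_matrix(sprintf("t%d", 1:100), cbind(x, x[, 1] + x[, 2]),
    "VAD", dims = c("Va", "Ar", "Dm")
  )
  b <- derive_gas_basis(sc)
  expect_true(b$degenerate)
  expect_lt(b$singular_values[3], 1e-10)
})

test_that("the -pi/4 rotation maps the reference GAS matrix onto the reference PDS matrix", {
  pds <- rotate_gas_to_pds(gas_reference_basis())
  expect_identical(pds$target_dims, c("Pw", "Dg", "St"))
  expect_lt(max(abs(pds$matrix - pds_reference_basis()$matrix)), 0.01)
  # spot checks of the arithmetic
  expect_equal(pds$matrix["Pw", "Dm"], (0.48 + 0.54) / sqrt(2), tolerance = 1e-12)
  expect_equal(pds$matrix["Dg", "Ar"], (0.15 + 0.83) / sqrt(2), tolerance = 1e-12)
})

test_that("rotating by -pi/4 then +pi/4 restores the original basis", {
  gas <- derive_gas_basis(make_orthogonal_scores(500, c(5, 3, 1), seed = 2))
  pds <- rotate_gas_to_pds(gas)
  r <- 1 / sqrt(2)
  inv <- matrix(c(r, -r, 0, r, r, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_equal(inv %*% pds$matrix, unclass(gas$matrix),
    tolerance = 1e-12, ignore_attr = TRUE
  )
  expect_error(rotate_gas_to_pds(pds), class = "ousio_contract_error")
})

test_that("closed-form variance rotation law holds through the matrix pipeline", {
  # uncorrelated Gd, Ag with variance fractions 55.6 / 35.3 (St carries 9.1)
  sc <- make_orthogonal_scores(4000, sqrt(c(55.6, 35.3, 9.1)),
    framework = "GAS", seed = 13
  )
  identity_gas <- framework_basis(diag(3),
    source_dims = c("Gd", "Ag", "St"),
    target_dims = c("Gd", "Ag", "St"), name = "GAS",
    explained_variance = c(0.556, 0.353, 0.091)
  )
  pds <- rotate_gas_to_pds(identity_gas)
  rotated <- apply_basis(
    score_matrix(sc$terms, sc$values, "GAS", dims = c("Gd", "Ag", "St")), pds
  )
  v <- colSums(rotated$values^2)
  frac <- v / sum(v)
  expect_equal(unname(frac[1:2]), rep((55.6 + 35.3) / 2 / 100, 2), tolerance = 1e-9)
  r <- pairwise_correlations(rotated)
  expect_equal(r["Pw", "Dg"], (35.3 - 55.6) / (55.6 + 35.3), tolerance = 1e-9)
  expect_equal(pds$explained_variance[1:2], rep(0.4545, 2), tolerance = 1e-4)
})

test_that("apply_basis is linear, order preserving, and contract checked", {
  b <- pds_reference_basis()
  sc <- score_matrix(c("zero", "one"), rbind(c(0, 0, 0), c(0.1, -0.2, 0.3)), "VAD")
  out <- apply_basis(sc, b)
  expect_identical(out$terms, sc$terms)
  expect_equal(unname(out$values[1, ]), c(0, 0, 0))
  gas_sc <- score_matrix("x", matrix(1:3, 1), "GAS")
  expect_error(apply_basis(gas_sc, b), class = "ousio_contract_error")
})

test_that("pairwise correlations handle perfect, weighted, and degenerate cases", {
  x <- seq(-0.4, 0.4, length.out = 9)
  sc <- score_matrix(letters[1:9], cbind(x, 2 * x, rev(x)), "VAD")
  r <- pairwise_correlations(sc)
  expect_equal(unname(r["Va", "Ar"]), 1)
  expect_equal(unname(r["Va", "Dm"]), -1)
  expect_equal(diag(r), c(Va = 1, Ar = 1, Dm = 1))
  expect_identical(r, t(r))
  # weights concentrated on a single term -> undefined, flagged NA not zero
  w <- frequency_distribution(c(a = 5))
  r1 <- pairwise_correlations(sc, w)
  expect_true(is.na(r1["Va", "Ar"]))
  # weighted term missing from scores is a validation error
  expect_error(
    pairwise_correlations(sc, frequency_distribution(c(zzz = 1))),
    class = "ousio_validation_error"
  )
})

test_that("explained variances follow sigma^2 / sum sigma^2", {
  ev <- explained_variances(c(34.1, 27.2, 13.8))
  expect_equal(round(ev, 3), c(0.556, 0.353, 0.091))
  expect_equal(explained_variances(c(2, 2, 2)), rep(1 / 3, 3))
  expect_equal(explained_variances(c(5, 0, 0)), c(1, 0, 0))
  expect_error(explained_variances(c(0, 0, 0)), class = "ousio_contract_error")
})

test_that("plane SVD ellipse matches covariance eigenstructure", {
  # collinear points: major axis along (1,1)/sqrt(2), zero minor radius
  x <- seq(-0.3, 0.3, length.out = 11)
  sc <- score_matrix(sprintf("t%d", 1:11), cbind(x, x, 0 * x), "VAD")
  e <- plane_svd_ellipse(sc, c("Va", "Ar"))
  expect_equal(abs(e$axes[, 1]), rep(1 / sqrt(2), 2), tolerance = 1e-12)
  expect_equal(e$radii[2], 0, tolerance = 1e-12)

  # isotropic cloud: radii ratio within 5% of 1 at n = 10000
  iso <- random_plane_scores(10000, seed = 9)
  ei <- plane_svd_ellipse(iso, c("Pw", "Dg"))
  expect_lt(ei$radii[1] / ei$radii[2], 1.05)
  # one-sigma scaling: radii^2 equal covariance eigenvalues (divisor N)
  cv <- crossprod(scale(iso$values, scale = FALSE)) / nrow(iso$values)
  expect_equal(sort(ei$radii^2), sort(eigen(cv)$values), tolerance = 1e-9)
})

test_that("GAS-frame ellipse aligns with the plot axes", {
  lex <- generate_synthetic_lexicon(synthetic_lexicon_spec(n_terms = 2000, seed = 6))
  vad <- as_score_matrix(lex)
  gas_scores <- apply_basis(vad, derive_gas_basis(vad))
  e <- plane_svd_ellipse(gas_scores, c("Gd", "Ag"))
  ang <- atan2(e$axes[2, 1], e$axes[1, 1])
  # SVD decorrelation holds about the zero design mean; the ellipse centers
  # on the small sample mean, so alignment is near- but not machine-exact
  expect_lt(min(abs(ang), abs(abs(ang) - pi / 2), abs(abs(ang) - pi)), 0.05)
})

test_that("cone rankings obey the half-angle and projection order", {
  expect_equal(default_cone_half_angle() * 180 / pi, 17.63, tolerance = 0.005)
  on_axis <- c(0.3, 0, 0)
  thirty_deg <- 0.4 * c(cos(pi / 6), sin(pi / 6), 0)
  inside <- 0.2 * c(cos(pi / 18), sin(pi / 18), 0)
  sc <- score_matrix(
    c("axis", "thirty", "inside"),
    rbind(on_axis, thirty_deg, inside), "PDS"
  )
  cr <- rank_terms_in_cone(sc, axis = c(1, 0, 0))
  expect_identical(cr$ranked$term, c("axis", "inside")) # 30 deg excluded
  expect_equal(cr$ranked$component[1], 0.3, tolerance = 1e-12) # = magnitude
  expect_false(is.unsorted(rev(cr$ranked$component)))
  expect_error(rank_terms_in_cone(sc, c(0, 0, 0)), class = "ousio_contract_error")
})

test_that("basis JSON export round-trips", {
  gas <- derive_gas_basis(make_orthogonal_scores(300, c(4, 2, 1), seed = 15))
  f <- tempfile(fileext = ".json")
  write_basis_json(gas, f)
  back <- read_basis_json(f)
  expect_equal(back$matrix, gas$matrix, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$singular_values, gas$singular_values, tolerance = 1e-12)
  expect_identical(back$target_dims, gas$target_dims)
})
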