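test_that("single-term grids put all mass in one bin at the term's coordinates", {
  sc <- score_matrix("solo", matrix(c(0.21, -0.37, 0), 1), "PDS")
  g <- build_ousiogram(sc, c("Pw", "Dg"),
    weights = frequency_distribution(c(solo = 7))
  )
  expect_equal(sum(g$counts), 7)
  expect_equal(g$max_bin, 7)
  expect_equal(g$median_x, 0.21)
  expect_equal(g$median_y, -0.37)
  expect_equal(sum(g$counts > 0), 1L)
})

test_that("histogram mass is conserved and marginals are consistent", {
  for (seed in c(2, 14, 30)) {
    sc <- random_plane_scores(400, seed = seed)
    w <- withr::with_seed(seed, stats::setNames(rexp(400), sc$terms))
    g <- build_ousiogram(
      score_matrix(sc$terms, cbind(sc$values, St = 0), "PDS"),
      c("Pw", "Dg"),
      weights = frequency_distribution(w)
    )
    expect_equal(sum(g$counts), sum(w), tolerance = 1e-9)
    expect_equal(g$marginal_x, rowSums(g$counts))
    expect_equal(g$marginal_y, colSums(g$counts))
    expect_equal(dim(g$counts), c(60L, 60L))
  }
})

test_that("binning follows the half-open floor convention with inward edges", {
  sc <- score_matrix(
    c("origin", "topedge"),
    rbind(c(0, 0, 0), c(1, 1, 0)), "PDS"
  )
  g <- build_ousiogram(sc, c("Pw", "Dg"))
  # index oracle: floor((v + 1) / bin_width), zero-based
  expect_equal(floor((0 + 1) / g$bin_width), 30)
  expect_equal(g$counts[31, 31], 1) # zero-based (30, 30)
  expect_equal(g$counts[60, 60], 1) # value at +1 kept in the closed last bin
})

test_that("out-of-extent values are clipped into boundary bins and counted", {
  sc <- score_matrix(c("wild", "tame"), rbind(c(1.4, -1.2, 0), c(0, 0, 0)), "PDS")
  expect_warning(g <- build_ousiogram(sc, c("Pw", "Dg")), "clipped")
  expect_equal(g$clipped, 1)
  expect_equal(sum(g$counts), 2)
  expect_equal(g$counts[60, 1], 1)
})

test_that("boundary annotations pick the extremal corner terms of a quadrilateral", {
  # corners are deliberately asymmetric so no two share a projection
  pts <- rbind(c(-0.5, -0.55), c(-0.55, 0.5), c(0.5, 0.55), c(0.55, -0.5))
  sc <- score_matrix(c("sw", "nw", "ne", "se"), cbind(pts, 0), "PDS")
  g <- build_ousiogram(sc, c("Pw", "Dg"))
  ann <- annotate_boundary(g, sc, spacing = 2) # one segment per side
  expect_equal(nrow(ann), 4L)
  expect_setequal(ann$term, c("sw", "nw", "ne", "se"))
  # each annotated term maximizes projection onto its outward normal
  for (k in seq_len(nrow(ann))) {
    nrm <- c(cos(ann$normal_angle[k]), sin(ann$normal_angle[k]))
    proj <- pts[, 1] * nrm[1] + pts[, 2] * nrm[2]
    prior <- ann$term[seq_len(k - 1)]
    allowed <- setdiff(sc$terms, prior)
    best <- allowed[which.max(proj[match(allowed, sc$terms)])]
    expect_identical(ann$term[k], best)
  }
})

test_that("boundary annotations agree with a brute-force projection oracle", {
  sc2 <- random_plane_scores(300, seed = 8)
  sc <- score_matrix(sc2$terms, cbind(sc2$values, St = 0), "PDS")
  g <- build_ousiogram(sc, c("Pw", "Dg"))
  ann <- annotate_boundary(g, sc, spacing = 0.1)
  expect_gt(nrow(ann), 3L)
  expect_false(any(duplicated(ann$term)))
  x <- sc$values[, 1]
  y <- sc$values[, 2]
  used <- character()
  for (k in seq_len(nrow(ann))) {
    nrm <- c(cos(ann$normal_angle[k]), sin(ann$normal_angle[k]))
    proj <- x * nrm[1] + y * nrm[2]
    proj[sc$terms %in% used] <- -Inf
    expect_identical(ann$term[k], sc$terms[which.max(proj)])
    used <- c(used, ann$term[k])
  }
  # annotated terms are data points, hence inside or on the hull of the data
  hull <- grDevices::chull(x, y)
  expect_true(all(ann$term %in% sc$terms))
})

test_that("degenerate occupancy yields an empty boundary set with a warning", {
  sc <- score_matrix("one", matrix(c(0.1, 0.1, 0), 1), "PDS")
  g <- build_ousiogram(sc, c("Pw", "Dg"))
  expect_warning(ann <- annotate_boundary(g, sc), "non-collinear")
  expect_equal(nrow(ann), 0L)
  # collinear occupied bins are also degenerate
  line <- score_matrix(sprintf("t%d", 1:5),
    cbind(seq(-0.4, 0.4, length.out = 5), 0, 0), "PDS")
  gl <- build_ousiogram(line, c("Pw", "Dg"))
  expect_warning(annl <- annotate_boundary(gl, line), "non-collinear")
  expect_equal(nrow(annl), 0L)
})

test_that("internal annotations choose nearest unused terms along the eight rays", {
  sc2 <- random_plane_scores(200, seed = 19)
  # plant a term exactly on the first ray target
  vals <- rbind(sc2$values, c(0.1 + (0.4 - 0.1) / 2, 0))
  sc <- score_matrix(c(sc2$terms, "planted"), cbind(vals, 0), "PDS")
  # give the planted term a generous extent match: compute via the function
  ann <- annotate_internal(sc, c("Pw", "Dg"), n_per_ray = 2, origin_exclusion = 0.1)
  expect_false(any(duplicated(ann$term)))
  x <- sc$values[, 1]
  y <- sc$values[, 2]
  used <- character()
  for (k in seq_len(nrow(ann))) {
    d <- sqrt((x - ann$target_x[k])^2 + (y - ann$target_y[k])^2)
    d[sc$terms %in% used] <- Inf
    expect_identical(ann$term[k], sc$terms[which.min(d)])
    used <- c(used, ann$term[k])
  }
  # a term exactly at a target is chosen for that target
  exact <- score_matrix(c("bull", "far"),
    rbind(c(0.3, 0), c(-0.45, 0.1)) |> cbind(0), "PDS")
  ann2 <- annotate_internal(exact, c("Pw", "Dg"),
    n_per_ray = 1, origin_exclusion = 0.0)
  east <- ann2[ann2$ray_angle == 0, ]
  expect_identical(east$term, "bull")
  expect_equal(east$distance, 0)

  expect_equal(nrow(annotate_internal(sc, c("Pw", "Dg"), n_per_ray = 0)), 0L)
})

test_that("combined annotation sets never reuse a term", {
  sc2 <- random_plane_scores(150, seed = 4)
  sc <- score_matrix(sc2$terms, cbind(sc2$values, St = 0), "PDS")
  g <- build_ousiogram(sc, c("Pw", "Dg"))
  ann <- annotate_ousiogram(g, sc, spacing = 0.12, n_per_ray = 3)
  all_terms <- c(ann$boundary$term, ann$internal$term)
  expect_false(any(duplicated(all_terms)))
})

test_that("rendered sidecars mirror the grid and are byte-deterministic", {
  sc2 <- random_plane_scores(120, seed = 27)
  sc <- score_matrix(sc2$terms, cbind(sc2$values, St = 0), "PDS")
  w <- frequency_distribution(stats::setNames(rep(1:2, 60), sc$terms))
  g <- build_ousiogram(sc, c("Pw", "Dg"), weights = w)
  ann <- annotate_ousiogram(g, sc, spacing = 0.2, n_per_ray = 2)
  out <- file.path(tempdir(), "ousiogram_test.png")
  res <- render_ousiogram(g, ann, out)
  expect_true(file.exists(res$sidecar))
  side <- jsonlite::read_json(res$sidecar, simplifyVector = TRUE)
  expect_equal(side$median_x, g$median_x)
  expect_equal(side$median_y, g$median_y)
  expect_equal(side$max_bin, max(g$counts))
  expect_equal(sum(side$bins$weight), sum(g$counts), tolerance = 1e-9)
  expect_identical(side$schema_version, "1.0")
  # regeneration is byte-identical
  out2 <- file.path(tempdir(), "ousiogram_test2.png")
  res2 <- render_ousiogram(g, ann, out2, write_figure = FALSE)
  expect_identical(
    readBin(res$sidecar, "raw", file.size(res$sidecar)),
    readBin(res2$sidecar, "raw", file.size(res2$sidecar))
  )
  # figure written (device available in this build)
  if (!is.na(res$figure)) expect_gt(file.size(res$figure), 0)
})
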