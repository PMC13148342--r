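#' Build an ousiogram grid
#'
#' Bins two essential dimensions into a weighted 2D histogram on a fixed
#' extent (default \[-1,1\] x \[-1,1\], bin width 1/30), with marginal
#' distributions, weighted medians, and the plane SVD ellipse. Without
#' weights every term counts once (type level). Binning is half-open
#' \[lo, hi) with the final bin closed; values outside the extent are clipped
#' into the boundary bins and counted.
#'
#' @param scores An `ousio_scores`.
#' @param dim_pair Character vector of two dimension names (x then y).
#' @param weights Optional `ousio_freq`; terms absent from it get weight 0.
#' @param bin_width Bin width in score units.
#' @param extent Numeric `c(lo, hi)` applied to both axes.
#' @return A list of class `ousiogram_grid` with fields `dim_pair`,
#'   `bin_width`, `extent`, `counts` (x-bins by y-bins), `marginal_x`,
#'   `marginal_y`, `median_x`, `median_y`, `ellipse`, `max_bin`,
#'   `clipped` (count of clipped points), and `breaks`.
#' @export
build_ousiogram <- function(scores, dim_pair, weights = NULL,
                            bin_width = 1 / 30, extent = c(-1, 1)) {
  stopifnot(inherits(scores, "ousio_scores"), length(dim_pair) == 2L)
  if (length(scores$terms) == 0L) stop_contract("empty score set")
  x <- unname(score_dimension(scores, dim_pair[1L]))
  y <- unname(score_dimension(scores, dim_pair[2L]))
  if (is.null(weights)) {
    w <- rep(1, length(x))
  } else {
    stopifnot(inherits(weights, "ousio_freq"))
    w <- stats::setNames(numeric(length(x)), scores$terms)
    hit <- intersect(names(weights$weights), scores$terms)
    w[hit] <- weights$weights[hit]
    w <- unname(w)
  }
  if (sum(w) <= 0) stop_contract("no positive weight falls on the score terms")
  lo <- extent[1L]
  hi <- extent[2L]
  nbins <- as.integer(ceiling((hi - lo) / bin_width - 1e-9))
  clipped <- sum((x < lo | x > hi | y < lo | y > hi) & w > 0)
  bin_index <- function(v) {
    i <- floor((v - lo) / bin_width) + 1L
    pmin.int(pmax.int(i, 1L), nbins) # upper edge and clipped values inward
  }
  ix <- bin_index(x)
  iy <- bin_index(y)
  counts <- matrix(0, nbins, nbins)
  flat <- (iy - 1L) * nbins + ix
  sums <- vapply(split(w, flat), sum, 0)
  counts[as.integer(names(sums))] <- sums
  grid <- structure(
    list(
      dim_pair = dim_pair, bin_width = bin_width, extent = extent,
      counts = counts,
      marginal_x = rowSums(counts), marginal_y = colSums(counts),
      median_x = weighted_median(x, w), median_y = weighted_median(y, w),
      ellipse = if (length(x) >= 2L) {
        plane_svd_ellipse(scores, dim_pair, weights)
      } else { # a single point has no spread: degenerate ellipse at the point
        list(
          center = stats::setNames(c(x, y), dim_pair), axes = diag(2),
          radii = c(0, 0), degenerate = TRUE, scaling = "one-sigma"
        )
      },
      max_bin = max(counts),
      clipped = clipped,
      breaks = lo + bin_width * 0:nbins,
      total_weight = sum(w)
    ),
    class = "ousiogram_grid"
  )
  if (clipped > 0) {
    warning(sprintf("%d weighted points outside the extent were clipped into boundary bins", clipped),
      call. = FALSE
    )
  }
  grid
}

#' @export
print.ousiogram_grid <- function(x, ...) {
  cat(sprintf(
    "<ousiogram_grid> %s vs %s, %dx%d bins (width %.4g), total weight %.6g\n",
    x$dim_pair[1L], x$dim_pair[2L], nrow(x$counts), ncol(x$counts),
    x$bin_width, x$total_weight
  ))
  cat(sprintf(
    "medians: %s = %.4g, %s = %.4g; max bin %.6g\n",
    x$dim_pair[1L], x$median_x, x$dim_pair[2L], x$median_y, x$max_bin
  ))
  invisible(x)
}

occupied_bin_centers <- function(grid) {
  idx <- which(grid$counts > 0, arr.ind = TRUE)
  cbind(
    grid$extent[1L] + (idx[, 1L] - 0.5) * grid$bin_width,
    grid$extent[1L] + (idx[, 2L] - 0.5) * grid$bin_width
  )
}

# Orient polygon vertex indices clockwise (screen convention used for
# outward normals (-dy, dx)).
orient_clockwise <- function(pts, idx) {
  p <- pts[idx, , drop = FALSE]
  n <- nrow(p)
  area2 <- sum(p[, 1L] * p[c(2:n, 1L), 2L] - p[c(2:n, 1L), 1L] * p[, 2L])
  if (area2 > 0) rev(idx) else idx
}

#' Boundary annotations along the histogram's convex hull
#'
#' Computes the convex hull of occupied-bin centers, subdivides its perimeter
#' into segments of arc length about `spacing`, takes the outward normal at
#' each segment midpoint, and annotates each segment with the not-yet-used
#' term whose plane coordinates maximize the scalar projection onto that
#' normal. Every term is used at most once. With `method = "midpoint"`,
#' the nearest unused term to the segment midpoint is chosen instead.
#'
#' @param grid An `ousiogram_grid`.
#' @param scores The `ousio_scores` the grid was built from (label
#'   candidates).
#' @param labels Optional character vector restricting candidate terms.
#' @param spacing Target arc length between annotations, in plot units.
#' @param method `"projection"` (default) or `"midpoint"`.
#' @param exclude Terms already used elsewhere (never annotated again).
#' @return A data frame (class `ousio_annotations`, kind "boundary") with
#'   columns `term`, `x`, `y` (term coordinates), `anchor_x`, `anchor_y`,
#'   `normal_angle` (radians). Empty, with a warning, when fewer than 3
#'   non-collinear bins are occupied.
#' @export
annotate_boundary <- function(grid, scores, labels = NULL, spacing = 0.15,
                              method = c("projection", "midpoint"),
                              exclude = character()) {
  stopifnot(inherits(grid, "ousiogram_grid"), inherits(scores, "ousio_scores"))
  method <- match.arg(method)
  empty <- data.frame(
    term = character(), x = numeric(), y = numeric(),
    anchor_x = numeric(), anchor_y = numeric(), normal_angle = numeric(),
    stringsAsFactors = FALSE
  )
  centers <- occupied_bin_centers(grid)
  hull_ok <- nrow(centers) >= 3L
  if (hull_ok) {
    h <- grDevices::chull(centers[, 1L], centers[, 2L])
    hull_ok <- length(h) >= 3L
    if (hull_ok) {
      p <- centers[h, , drop = FALSE]
      n <- nrow(p)
      area2 <- abs(sum(p[, 1L] * p[c(2:n, 1L), 2L] - p[c(2:n, 1L), 1L] * p[, 2L]))
      hull_ok <- area2 > 1e-12
    }
  }
  if (!hull_ok) {
    warning("fewer than 3 non-collinear occupied bins; no boundary annotations",
      call. = FALSE
    )
    return(structure(empty, class = c("ousio_annotations", "data.frame"), kind = "boundary"))
  }
  h <- orient_clockwise(centers, h)
  poly <- centers[h, , drop = FALSE]
  nxt <- rbind(poly[-1L, , drop = FALSE], poly[1L, , drop = FALSE])

  cand_terms <- scores$terms
  if (!is.null(labels)) cand_terms <- intersect(cand_terms, labels)
  cand_terms <- setdiff(cand_terms, exclude)
  cx <- score_dimension(scores, grid$dim_pair[1L])[cand_terms]
  cy <- score_dimension(scores, grid$dim_pair[2L])[cand_terms]
  used <- rep(FALSE, length(cand_terms))

  rows <- list()
  for (e in seq_len(nrow(poly))) {
    d <- nxt[e, ] - poly[e, ]
    len <- sqrt(sum(d^2))
    if (len == 0) next
    nrm <- c(-d[2L], d[1L]) / len # outward for clockwise orientation
    nseg <- max(1L, as.integer(round(len / spacing)))
    for (j in seq_len(nseg)) {
      if (all(used)) break
      mid <- poly[e, ] + d * (j - 0.5) / nseg
      score <- if (method == "projection") {
        cx * nrm[1L] + cy * nrm[2L]
      } else {
        -sqrt((cx - mid[1L])^2 + (cy - mid[2L])^2)
      }
      score[used] <- -Inf
      k <- which.max(score)
      used[k] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        term = cand_terms[k], x = unname(cx[k]), y = unname(cy[k]),
        anchor_x = mid[1L], anchor_y = mid[2L],
        normal_angle = atan2(nrm[2L], nrm[1L]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  structure(out, class = c("ousio_annotations", "data.frame"), kind = "boundary")
}

#' Internal annotations along the eight rays
#'
#' Places `n_per_ray` target points on each of the eight rays leaving the
#' origin at multiples of pi/4 (the cardinal axes and the two diagonals),
#' evenly spaced between an origin-exclusion radius and the ray's data
#' extent, and annotates each target with the nearest unused term in
#' Euclidean plane distance.
#'
#' @param scores An `ousio_scores`.
#' @param dim_pair Two dimension names (x then y).
#' @param n_per_ray Number of targets per ray.
#' @param origin_exclusion Radius around the origin left unannotated.
#' @param exclude Terms never to use (e.g. boundary annotations).
#' @return A data frame (class `ousio_annotations`, kind "internal") with
#'   columns `term`, `x`, `y`, `ray_angle`, `target_x`, `target_y`,
#'   `distance`. If fewer unused terms exist than targets, as many targets as
#'   possible are annotated.
#' @export
annotate_internal <- function(scores, dim_pair, n_per_ray = 4L,
                              origin_exclusion = 0.1,
                              exclude = character()) {
  stopifnot(inherits(scores, "ousio_scores"), length(dim_pair) == 2L)
  if (length(scores$terms) == 0L) stop_contract("empty score set")
  cand_terms <- setdiff(scores$terms, exclude)
  empty <- data.frame(
    term = character(), x = numeric(), y = numeric(), ray_angle = numeric(),
    target_x = numeric(), target_y = numeric(), distance = numeric(),
    stringsAsFactors = FALSE
  )
  if (n_per_ray < 1L || length(cand_terms) == 0L) {
    return(structure(empty, class = c("ousio_annotations", "data.frame"), kind = "internal"))
  }
  cx <- score_dimension(scores, dim_pair[1L])[cand_terms]
  cy <- score_dimension(scores, dim_pair[2L])[cand_terms]
  used <- rep(FALSE, length(cand_terms))
  rows <- list()
  for (k in 0:7) {
    ang <- k * pi / 4
    u <- c(cos(ang), sin(ang))
    ext <- max(cx * u[1L] + cy * u[2L])
    if (!is.finite(ext) || ext <= origin_exclusion) next
    radii <- origin_exclusion + seq_len(n_per_ray) * (ext - origin_exclusion) / n_per_ray
    for (r in radii) {
      if (all(used)) break
      tx <- r * u[1L]
      ty <- r * u[2L]
      dist <- sqrt((cx - tx)^2 + (cy - ty)^2)
      dist[used] <- Inf
      i <- which.min(dist)
      used[i] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        term = cand_terms[i], x = unname(cx[i]), y = unname(cy[i]),
        ray_angle = ang, target_x = tx, target_y = ty,
        distance = unname(dist[i]), stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  structure(out, class = c("ousio_annotations", "data.frame"), kind = "internal")
}

#' Combined boundary and internal annotations
#'
#' Runs [annotate_boundary()] then [annotate_internal()], guaranteeing that
#' no term appears twice across the two sets.
#'
#' @inheritParams annotate_boundary
#' @inheritParams annotate_internal
#' @return A list with elements `boundary` and `internal`.
#' @export
annotate_ousiogram <- function(grid, scores, spacing = 0.15, n_per_ray = 4L,
                               origin_exclusion = 0.1,
                               method = "projection") {
  boundary <- annotate_boundary(grid, scores, spacing = spacing, method = method)
  internal <- annotate_internal(scores, grid$dim_pair,
    n_per_ray = n_per_ray,
    origin_exclusion = origin_exclusion,
    exclude = boundary$term
  )
  list(boundary = boundary, internal = internal)
}

ousiogram_style <- function(style = list()) {
  defaults <- list(
    colormap = "magma", annotation_size = 2.2, base_size = 10,
    median_color = "grey20", ellipse_color = "white"
  )
  utils::modifyList(defaults, style)
}

#' Read an ousiogram style configuration from YAML
#'
#' @param path Path to a YAML file with any of the keys `colormap`,
#'   `annotation_size`, `base_size`, `median_color`, `ellipse_color`,
#'   `bin_width`, `spacing`, `n_per_ray`.
#' @return A named list.
#' @export
read_style_yaml <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("style file not found: %s", path))
  yaml::read_yaml(path)
}

ellipse_path <- function(ellipse, n = 120L) {
  t <- seq(0, 2 * pi, length.out = n)
  pts <- ellipse$axes %*% rbind(
    ellipse$radii[1L] * cos(t),
    ellipse$radii[2L] * sin(t)
  )
  data.frame(x = ellipse$center[1L] + pts[1L, ], y = ellipse$center[2L] + pts[2L, ])
}

#' Render an ousiogram
#'
#' Writes a figure (main histogram with top/right marginals, median
#' triangles, one-sigma SVD ellipse, boundary and internal word labels, color
#' map linearly normalized to the highest-count bin) plus a sidecar JSON file
#' describing every plotted element, so downstream checks never need to parse
#' the image.
#'
#' @param grid An `ousiogram_grid`.
#' @param annotations Optional list from [annotate_ousiogram()].
#' @param path Output figure path; the extension selects the device
#'   (`.png` or `.svg`). The sidecar is written at `paste0(path, ".json")`.
#' @param style Named list of style overrides (see [read_style_yaml()]).
#' @param write_figure Set `FALSE` to write the sidecar only.
#' @return Invisibly, a list with `figure` and `sidecar` paths.
#' @export
render_ousiogram <- function(grid, annotations = NULL, path,
                             style = list(), write_figure = TRUE) {
  stopifnot(inherits(grid, "ousiogram_grid"))
  st <- ousiogram_style(style)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io(sprintf("output directory does not exist: %s", dir))

  occ <- which(grid$counts > 0, arr.ind = TRUE)
  sidecar <- list(
    schema_version = "1.0",
    dim_pair = grid$dim_pair,
    bin_width = grid$bin_width,
    extent = grid$extent,
    bins = list(
      ix = unname(occ[, 1L]), iy = unname(occ[, 2L]),
      weight = unname(grid$counts[occ])
    ),
    marginal_x = grid$marginal_x,
    marginal_y = grid$marginal_y,
    median_x = grid$median_x,
    median_y = grid$median_y,
    ellipse = list(
      center = unname(grid$ellipse$center),
      axes = as.vector(grid$ellipse$axes),
      radii = grid$ellipse$radii,
      scaling = grid$ellipse$scaling
    ),
    max_bin = grid$max_bin,
    clipped = grid$clipped,
    annotations = if (is.null(annotations)) NULL else {
      list(
        boundary = as.data.frame(annotations$boundary),
        internal = as.data.frame(annotations$internal)
      )
    },
    style = st
  )
  sidecar_path <- paste0(path, ".json")
  jsonlite::write_json(sidecar, sidecar_path,
    auto_unbox = TRUE, digits = NA,
    dataframe = "columns", null = "null"
  )

  if (write_figure) {
    fig <- ousiogram_plot(grid, annotations, st)
    ok <- tryCatch(
      {
        ggplot2::ggsave(path, fig, width = 7, height = 7, dpi = 150)
        TRUE
      },
      error = function(e) {
        warning(sprintf("figure device failed (%s); sidecar still written", conditionMessage(e)),
          call. = FALSE
        )
        FALSE
      }
    )
    if (!ok) path <- NA_character_
  } else {
    path <- NA_character_
  }
  invisible(list(figure = path, sidecar = sidecar_path))
}

# Assemble the ggplot/patchwork figure: main tile panel + two marginal bar
# panels. Kept separate from render_ousiogram so the layout can be inspected
# without touching a graphics device.
ousiogram_plot <- function(grid, annotations, st) {
  nb <- nrow(grid$counts)
  mids <- grid$extent[1L] + (seq_len(nb) - 0.5) * grid$bin_width
  occ <- which(grid$counts > 0, arr.ind = TRUE)
  tiles <- data.frame(
    x = mids[occ[, 1L]], y = mids[occ[, 2L]],
    w = grid$counts[occ] / grid$max_bin
  )
  main <- ggplot2::ggplot(tiles, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$w)) +
    ggplot2::geom_tile(width = grid$bin_width, height = grid$bin_width) +
    ggplot2::scale_fill_viridis_c(
      option = st$colormap, limits = c(0, 1),
      name = sprintf("weight / %.3g", grid$max_bin)
    ) +
    ggplot2::coord_fixed(xlim = grid$extent, ylim = grid$extent, expand = FALSE) +
    ggplot2::labs(x = grid$dim_pair[1L], y = grid$dim_pair[2L]) +
    ggplot2::theme_minimal(base_size = st$base_size) +
    ggplot2::annotate("point",
      x = grid$median_x, y = grid$extent[1L],
      shape = 17, size = 3, color = st$median_color
    ) +
    ggplot2::annotate("point",
      x = grid$extent[1L], y = grid$median_y,
      shape = 17, size = 3, color = st$median_color
    )
  if (!grid$ellipse$degenerate) {
    ep <- ellipse_path(grid$ellipse)
    main <- main + ggplot2::geom_path(
      data = ep, ggplot2::aes(x = .data$x, y = .data$y),
      inherit.aes = FALSE, color = st$ellipse_color, linewidth = 0.4
    )
  }
  if (!is.null(annotations)) {
    b <- annotations$boundary
    if (NROW(b)) {
      main <- main + ggplot2::geom_text(
        data = b,
        ggplot2::aes(x = .data$anchor_x, y = .data$anchor_y, label = .data$term,
                     angle = .data$normal_angle * 180 / pi),
        inherit.aes = FALSE, size = st$annotation_size, color = "grey30"
      )
    }
    i <- annotations$internal
    if (NROW(i)) {
      main <- main + ggplot2::geom_text(
        data = i,
        ggplot2::aes(x = .data$target_x, y = .data$target_y, label = .data$term),
        inherit.aes = FALSE, size = st$annotation_size, color = "grey70"
      )
    }
  }
  marg_x <- ggplot2::ggplot(
    data.frame(x = mids, w = grid$marginal_x),
    ggplot2::aes(x = .data$x, y = .data$w)
  ) +
    ggplot2::geom_col(width = grid$bin_width, fill = "grey40") +
    ggplot2::coord_cartesian(xlim = grid$extent, expand = FALSE) +
    ggplot2::theme_void()
  marg_y <- ggplot2::ggplot(
    data.frame(y = mids, w = grid$marginal_y),
    ggplot2::aes(x = .data$y, y = .data$w)
  ) +
    ggplot2::geom_col(width = grid$bin_width, fill = "grey40") +
    ggplot2::coord_flip(xlim = grid$extent, expand = FALSE) +
    ggplot2::theme_void()
  patchwork::wrap_plots(
    marg_x, patchwork::plot_spacer(), main, marg_y,
    ncol = 2, widths = c(4, 1), heights = c(1, 4)
  )
}
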