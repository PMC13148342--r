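#' Run configuration
#'
#' Validates and normalizes the settings shared by the pipeline runners and
#' the command-line interface. The configuration is serialized verbatim into
#' every run manifest.
#'
#' @param lexicon Path to a VAD lexicon TSV, or `NULL` to use a synthetic
#'   lexicon generated from `seed`.
#' @param dialect A [vad_dialect()] (or list coercible to one).
#' @param framework One of `"VAD"`, `"GAS"`, `"PDS"`, `"GPADS"`.
#' @param bin_width Ousiogram bin width.
#' @param spacing Boundary-annotation spacing (plot units).
#' @param n_per_ray Internal annotations per ray.
#' @param W,s Meter window size and step, in tokens.
#' @param epochs Number of trajectory epochs.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed driving all randomness (synthetic generators).
#' @param n_synthetic_terms Number of terms when generating synthetically.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(lexicon = NULL, dialect = vad_dialect(),
                       framework = "PDS",
                       bin_width = 1 / 30, spacing = 0.15, n_per_ray = 4L,
                       W = 10000L, s = 100L, epochs = 10L,
                       out_dir = ".", seed = 1L,
                       n_synthetic_terms = 20000L) {
  framework <- toupper(framework)
  if (!framework %in% c("VAD", "GAS", "PDS", "GPADS")) {
    stop_validation("framework must be one of VAD, GAS, PDS, GPADS")
  }
  if (!is.null(lexicon) && !file.exists(lexicon)) {
    stop_io(sprintf("lexicon file not found: %s", lexicon))
  }
  if (bin_width <= 0 || spacing <= 0) {
    stop_validation("bin_width and spacing must be positive")
  }
  if (W < 1L || s < 1L || epochs < 1L) {
    stop_validation("W, s and epochs must be positive integers")
  }
  if (!inherits(dialect, "vad_dialect")) dialect <- do.call(vad_dialect, dialect)
  structure(
    list(
      lexicon = lexicon, dialect = dialect, framework = framework,
      bin_width = bin_width, spacing = spacing,
      n_per_ray = as.integer(n_per_ray),
      W = as.integer(W), s = as.integer(s), epochs = as.integer(epochs),
      out_dir = out_dir, seed = as.integer(seed),
      n_synthetic_terms = as.integer(n_synthetic_terms)
    ),
    class = "run_config"
  )
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @param overrides Named list applied on top of the file's values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop_io(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path) %||% list()
  vals <- utils::modifyList(vals, overrides)
  do.call(run_config, vals)
}

ensure_out_dir <- function(config) {
  if (!dir.exists(config$out_dir)) {
    ok <- dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_io(sprintf("cannot create output directory %s", config$out_dir))
  }
  config$out_dir
}

log_msg <- function(...) {
  # computational results go to stdout/files; logging stays on stderr
  message(sprintf(...))
}

manifest_config <- function(config) {
  c <- unclass(config)
  c$dialect <- unclass(c$dialect)
  c
}

write_manifest <- function(config, inputs, path, extra = list()) {
  hashes <- lapply(inputs, function(p) {
    if (!is.null(p) && file.exists(p)) unname(tools::md5sum(p)) else NULL
  })
  payload <- c(
    list(
      package_version = as.character(utils::packageVersion("ousiometrics")),
      tokenizer_version = TOKENIZER_VERSION,
      schema_version = "1.0",
      config = manifest_config(config),
      input_hashes = hashes
    ),
    extra
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# Load (or synthesize) the centered lexicon and derive both bases.
load_pipeline_inputs <- function(config) {
  if (is.null(config$lexicon)) {
    log_msg("no lexicon given; generating a synthetic lexicon (seed %d)", config$seed)
    lex <- generate_synthetic_lexicon(synthetic_lexicon_spec(
      n_terms = config$n_synthetic_terms, seed = config$seed
    ))
  } else {
    lex <- center_scores(read_vad_lexicon(config$lexicon, config$dialect))
  }
  vad <- as_score_matrix(lex)
  gas <- derive_gas_basis(vad)
  pds <- rotate_gas_to_pds(gas)
  list(lexicon = lex, vad = vad, gas = gas, pds = pds)
}

scores_for <- function(inputs, framework) {
  switch(framework,
    VAD = inputs$vad,
    GAS = apply_basis(inputs$vad, inputs$gas),
    PDS = ,
    GPADS = apply_basis(inputs$vad, inputs$pds)
  )
}

default_dim_pair <- function(framework) {
  switch(framework,
    VAD = c("Va", "Dm"), GAS = c("Gd", "Ag"),
    PDS = , GPADS = c("Pw", "Dg")
  )
}

#' Derive pipeline: bases, correlations, explained variances
#'
#' Reads (or synthesizes) a lexicon, centers it, derives the GAS basis by
#' SVD and the PDS basis by rotation, and writes basis JSON files, the VAD
#' correlation matrix, and a human-readable report under the configured
#' output directory.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the derived objects and output paths.
#' @export
run_derive <- function(config) {
  out <- ensure_out_dir(config)
  inputs <- load_pipeline_inputs(config)
  paths <- list(
    gas = file.path(out, "basis_gas.json"),
    pds = file.path(out, "basis_pds.json"),
    correlations = file.path(out, "vad_correlations.json"),
    report = file.path(out, "derive_report.txt"),
    manifest = file.path(out, "derive_manifest.json")
  )
  write_basis_json(inputs$gas, paths$gas)
  write_basis_json(inputs$pds, paths$pds)
  r <- pairwise_correlations(inputs$vad)
  jsonlite::write_json(
    list(dims = colnames(r), matrix = as.vector(t(r))),
    paths$correlations, auto_unbox = TRUE, digits = NA
  )
  sv <- inputs$gas$singular_values
  report <- c(
    sprintf("terms: %d", length(inputs$lexicon$term)),
    sprintf("VAD correlations: r(Va,Ar)=%.3f r(Ar,Dm)=%.3f r(Va,Dm)=%.3f",
      r["Va", "Ar"], r["Ar", "Dm"], r["Va", "Dm"]),
    sprintf("singular values: %s", paste(sprintf("%.3f", sv), collapse = ", ")),
    sprintf("explained variance: %s",
      paste(sprintf("%.1f%%", 100 * inputs$gas$explained_variance), collapse = ", ")),
    "GAS matrix (rows Gd, Ag, St over Va, Ar, Dm):",
    utils::capture.output(print(round(inputs$gas$matrix, 3))),
    "PDS matrix (rows Pw, Dg, St over Va, Ar, Dm):",
    utils::capture.output(print(round(inputs$pds$matrix, 3)))
  )
  writeLines(report, paths$report)
  write_manifest(config, list(lexicon = config$lexicon), paths$manifest)
  invisible(c(inputs, list(paths = paths, correlations = r)))
}

#' Score pipeline: write transformed score tables
#'
#' @param config A [run_config()].
#' @return Invisibly, the output paths.
#' @export
run_score <- function(config) {
  out <- ensure_out_dir(config)
  inputs <- load_pipeline_inputs(config)
  frameworks <- if (config$framework == "GPADS") c("GAS", "PDS") else config$framework
  paths <- character()
  for (fw in frameworks) {
    p <- file.path(out, sprintf("scores_%s.tsv", tolower(fw)))
    write_scores(scores_for(inputs, fw), p)
    paths <- c(paths, p)
  }
  write_manifest(config, list(lexicon = config$lexicon),
    file.path(out, "score_manifest.json"))
  invisible(paths)
}

read_frequency_inputs <- function(frequency_paths) {
  if (length(frequency_paths) == 1L && dir.exists(frequency_paths)) {
    frequency_paths <- sort(list.files(frequency_paths,
      pattern = "\\.tsv$",
      full.names = TRUE
    ))
    if (length(frequency_paths) == 0L) {
      stop_io("frequency directory contains no .tsv files")
    }
  }
  lapply(frequency_paths, read_frequency_tsv)
}

#' Ousiogram pipeline: figure plus sidecar
#'
#' Type-level (uniform weights) when no frequency files are given; otherwise
#' sub-corpus files are merged with equal weight and passed through the
#' lexical lens before weighting the histogram.
#'
#' @param config A [run_config()].
#' @param frequency_paths Optional TSV files or a directory of them.
#' @param dim_pair Dimension pair to plot (defaults per framework).
#' @param write_figure Set `FALSE` to emit the sidecar JSON only.
#' @return Invisibly, a list with grid, annotations, coverage, and paths.
#' @export
run_ousiogram <- function(config, frequency_paths = NULL, dim_pair = NULL,
                          write_figure = TRUE) {
  out <- ensure_out_dir(config)
  inputs <- load_pipeline_inputs(config)
  fw <- if (config$framework == "GPADS") "PDS" else config$framework
  scores <- scores_for(inputs, fw)
  dim_pair <- dim_pair %||% default_dim_pair(fw)

  weights <- NULL
  coverage <- NULL
  n_sub <- 0L
  if (!is.null(frequency_paths)) {
    dists <- read_frequency_inputs(frequency_paths)
    n_sub <- length(dists)
    merged <- merge_equal_weight(dists)
    lensed <- lexical_lens(merged, scores)
    weights <- lensed$dist
    coverage <- lensed$coverage
  }
  grid <- build_ousiogram(scores, dim_pair,
    weights = weights,
    bin_width = config$bin_width
  )
  ann <- annotate_ousiogram(grid, scores,
    spacing = config$spacing,
    n_per_ray = config$n_per_ray
  )
  fig_path <- file.path(out, sprintf(
    "ousiogram_%s_%s.png",
    tolower(dim_pair[1L]), tolower(dim_pair[2L])
  ))
  res <- render_ousiogram(grid, ann, fig_path, write_figure = write_figure)
  write_manifest(config, list(lexicon = config$lexicon),
    file.path(out, "ousiogram_manifest.json"),
    extra = list(n_subcorpora = n_sub, coverage = coverage)
  )
  invisible(list(
    grid = grid, annotations = ann, coverage = coverage,
    figure = res$figure, sidecar = res$sidecar
  ))
}

#' Corpus-statistics pipeline: bias summary and coverage
#'
#' @param config A [run_config()].
#' @param frequency_paths TSV files or a directory of them.
#' @return Invisibly, a list with the bias summary, coverage, and paths.
#' @export
run_corpus_stats <- function(config, frequency_paths) {
  out <- ensure_out_dir(config)
  inputs <- load_pipeline_inputs(config)
  fw <- if (config$framework == "GPADS") "PDS" else config$framework
  scores <- scores_for(inputs, fw)
  dists <- read_frequency_inputs(frequency_paths)
  merged <- merge_equal_weight(dists)
  lensed <- lexical_lens(merged, scores)
  if (sum(lensed$dist$weights) <= 0) {
    stop_validation("no corpus terms matched the lexicon; cannot compute statistics")
  }
  summary <- bias_summary(lensed$dist, scores)
  paths <- list(
    bias = file.path(out, "bias_summary.json"),
    coverage = file.path(out, "coverage.json"),
    manifest = file.path(out, "corpus_stats_manifest.json")
  )
  write_summary_json(summary, paths$bias)
  write_summary_json(lensed$coverage, paths$coverage)
  write_manifest(config, list(lexicon = config$lexicon), paths$manifest,
    extra = list(n_subcorpora = length(dists))
  )
  invisible(list(summary = summary, coverage = lensed$coverage, paths = paths))
}

#' Meter pipeline: windowed series and trajectory CSVs
#'
#' @param config A [run_config()].
#' @param text_path Path to a UTF-8 plain-text file with at least `W` tokens.
#' @return Invisibly, a list with the series, trajectory, and paths.
#' @export
run_meter <- function(config, text_path) {
  out <- ensure_out_dir(config)
  inputs <- load_pipeline_inputs(config)
  fw <- if (config$framework == "GPADS") "PDS" else config$framework
  scores <- scores_for(inputs, fw)
  stream <- read_token_stream(text_path)
  series <- windowed_scores(stream, scores, W = config$W, s = config$s)
  pair <- default_dim_pair(fw)
  traj <- build_trajectory(series, dim_pair = pair, n_epochs = config$epochs)
  paths <- list(
    series = file.path(out, "meter_series.csv"),
    trajectory = file.path(out, "meter_trajectory.csv"),
    manifest = file.path(out, "meter_manifest.json")
  )
  export_series(series, paths$series)
  export_series(traj, paths$trajectory)
  write_manifest(config, list(lexicon = config$lexicon, text = text_path),
    paths$manifest,
    extra = list(W = config$W, s = config$s, epochs = config$epochs,
      n_tokens = length(stream$tokens))
  )
  invisible(list(series = series, trajectory = traj, paths = paths))
}

#' Synthesis pipeline: write a synthetic lexicon and corpus
#'
#' @param config A [run_config()].
#' @param n_tokens Number of Zipf corpus tokens to emit.
#' @return Invisibly, the output paths.
#' @export
run_synth <- function(config, n_tokens = 100000L) {
  out <- ensure_out_dir(config)
  lex <- generate_synthetic_lexicon(synthetic_lexicon_spec(
    n_terms = config$n_synthetic_terms, seed = config$seed
  ))
  lex_path <- file.path(out, "synthetic_lexicon.tsv")
  write_scores(lex, lex_path)
  fd <- generate_zipf_corpus(lex$term, n_tokens, seed = config$seed + 1L)
  corpus_path <- file.path(out, "synthetic_corpus.tsv")
  utils::write.table(
    data.frame(term = names(fd$weights), count = unname(fd$weights)),
    corpus_path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE,
    fileEncoding = "UTF-8"
  )
  write_manifest(config, list(), file.path(out, "synth_manifest.json"),
    extra = list(n_tokens = n_tokens)
  )
  invisible(list(lexicon = lex_path, corpus = corpus_path))
}
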