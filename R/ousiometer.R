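# Tokenizer rules are versioned so that meter output is reproducible across
# releases; bump TOKENIZER_VERSION whenever the rules change.
TOKENIZER_VERSION <- "1.0"

#' Tokenize text into 1-grams
#'
#' Splits UTF-8 text on whitespace with punctuation separated into its own
#' tokens; every token (words, numbers, punctuation, other nonword elements)
#' is retained so that narrative time counts everything. Word-internal
#' apostrophes and hyphens are kept ("don't", "well-known"). Tokens are
#' emitted lowercase; the lexicon is matched against this folded form.
#' Tokenization is idempotent on its own space-joined output.
#'
#' @param text A nonempty character scalar (or vector, concatenated in
#'   order).
#' @param source_label Free-text label carried on the stream.
#' @return A list of class `token_stream` with `tokens` (character vector,
#'   narrative time indexed from 1) and `source_label`.
#' @export
#' @examples
#' tokenize_1grams("Good, bad.")$tokens
tokenize_1grams <- function(text, source_label = "") {
  text <- paste(text, collapse = "\n")
  if (!nzchar(trimws(text))) stop_validation("text is empty or whitespace-only")
  text <- tolower(normalize_term(text))
  pattern <- "[\\p{L}\\p{N}_]+(?:['’-][\\p{L}\\p{N}]+)*|[^\\p{L}\\p{N}\\s]"
  tokens <- regmatches(text, gregexpr(pattern, text, perl = TRUE))[[1L]]
  if (length(tokens) == 0L) stop_validation("text contains no tokens")
  structure(list(tokens = tokens, source_label = source_label),
    class = "token_stream"
  )
}

#' Read and tokenize a plain-text file
#'
#' @param path Path to a UTF-8 text file.
#' @return A `token_stream`.
#' @export
read_token_stream <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("text file not found: %s", path))
  tokenize_1grams(readLines(path, encoding = "UTF-8", warn = FALSE),
    source_label = basename(path)
  )
}

#' @export
print.token_stream <- function(x, ...) {
  cat(sprintf(
    "<token_stream> %d tokens%s\n", length(x$tokens),
    if (nzchar(x$source_label)) paste0(" from ", x$source_label) else ""
  ))
  invisible(x)
}

#' Windowed ousiometric time series
#'
#' Slides a window of `W` tokens in steps of `s` tokens over the stream.
#' Each window is lensed to the single-word (1-gram) entries of the score
#' matrix and the probability-weighted mean score is computed per dimension;
#' windows with no matched tokens yield `NA` (zero is a meaningful score,
#' never a stand-in). Window k covers tokens (k-1)s+1 .. (k-1)s+W and is
#' plotted at center index W/2 + (k-1)s.
#'
#' @param stream A `token_stream`.
#' @param scores An `ousio_scores`; multi-word entries are ignored by the
#'   meter.
#' @param W Window size in tokens (default 10000).
#' @param s Step in tokens (default 100).
#' @param dimensions Dimensions to evaluate (default: all in `scores`).
#' @return A data frame of class `ousio_timeseries` with columns `center`,
#'   one per dimension, and `coverage` (matched fraction per window);
#'   attributes `W`, `s`, `T_total`, `framework`.
#' @export
windowed_scores <- function(stream, scores, W = 10000L, s = 100L,
                            dimensions = colnames(scores$values)) {
  stopifnot(inherits(stream, "token_stream"), inherits(scores, "ousio_scores"))
  if (W < 1L || s < 1L) stop_contract("W and s must be positive")
  T_total <- length(stream$tokens)
  if (T_total < W) {
    stop_validation(sprintf(
      "text has %d tokens but the window is %d; lower W (e.g. W <= %d)",
      T_total, W, T_total
    ))
  }
  one_grams <- !grepl(" ", scores$terms, fixed = TRUE)
  idx <- match(stream$tokens, scores$terms)
  idx[!is.na(idx) & !one_grams[pmax(idx, 1L)]] <- NA_integer_
  matched <- !is.na(idx)

  n_win <- (T_total - W) %/% s + 1L
  starts <- (seq_len(n_win) - 1L) * s + 1L
  ends <- starts + W - 1L

  cum_m <- cumsum(matched)
  win_sum <- function(cum) cum[ends] - c(0, cum)[starts]
  n_matched <- win_sum(cum_m)

  out <- data.frame(center = W / 2 + (seq_len(n_win) - 1L) * s)
  for (d in dimensions) {
    v <- numeric(T_total)
    v[matched] <- score_dimension(scores, d)[idx[matched]]
    sums <- win_sum(cumsum(v))
    out[[d]] <- ifelse(n_matched > 0, sums / n_matched, NA_real_)
  }
  out$coverage <- n_matched / W
  structure(out,
    class = c("ousio_timeseries", "data.frame"),
    W = as.integer(W), s = as.integer(s), T_total = T_total,
    framework = scores$framework
  )
}

#' Paired-dimension trajectory with epoch labels
#'
#' Pairs two dimensions of a windowed series in window order and partitions
#' narrative time into `n_epochs` equal blocks (sizes differing by at most
#' one window).
#'
#' @param series An `ousio_timeseries`.
#' @param dim_pair Two dimension names, default power and danger.
#' @param n_epochs Number of equal epochs (default 10).
#' @return A data frame of class `ousio_trajectory` with columns `center`,
#'   the two dimensions, `coverage`, and `epoch`.
#' @export
build_trajectory <- function(series, dim_pair = c("Pw", "Dg"), n_epochs = 10L) {
  stopifnot(inherits(series, "ousio_timeseries"))
  if (!all(dim_pair %in% names(series))) {
    stop_contract(sprintf(
      "series lacks dimension(s) %s",
      paste(setdiff(dim_pair, names(series)), collapse = ", ")
    ))
  }
  n <- nrow(series)
  if (n < n_epochs) {
    stop_validation(sprintf(
      "series has %d points but %d epochs requested; lower n_epochs or W/s",
      n, n_epochs
    ))
  }
  b <- floor(n * (0:n_epochs) / n_epochs)
  epoch <- rep(seq_len(n_epochs), diff(b))
  out <- data.frame(
    center = series$center,
    series[, dim_pair, drop = FALSE],
    coverage = series$coverage,
    epoch = epoch
  )
  structure(out,
    class = c("ousio_trajectory", "data.frame"),
    W = attr(series, "W"), s = attr(series, "s"),
    framework = attr(series, "framework"), n_epochs = as.integer(n_epochs)
  )
}

#' Export a time series or trajectory as CSV
#'
#' Columns are the window center index, per-dimension values, coverage, and
#' (for trajectories) the epoch label. Missing-value windows are written as
#' empty fields, never zeros. Round-trips losslessly at 6-decimal precision
#' via [read_series()].
#'
#' @param x An `ousio_timeseries` or `ousio_trajectory`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
export_series <- function(x, path) {
  stopifnot(inherits(x, c("ousio_timeseries", "ousio_trajectory")))
  df <- as.data.frame(x)
  num <- vapply(df, is.double, TRUE) & names(df) != "center"
  df[num] <- lapply(df[num], function(v) ifelse(is.na(v), NA, sprintf("%.6f", v)))
  ok <- tryCatch(
    {
      utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
        fileEncoding = "UTF-8")
      TRUE
    },
    error = function(e) FALSE, warning = function(w) FALSE
  )
  if (!ok) stop_io(sprintf("cannot write series to %s", path))
  invisible(path)
}

#' @rdname export_series
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("series file not found: %s", path))
  utils::read.csv(path, na.strings = "", fileEncoding = "UTF-8")
}
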