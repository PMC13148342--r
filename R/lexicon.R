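#' Column dialect for lexicon files
#'
#' Describes how a tab-separated lexicon file is laid out: the order of its
#' columns and whether a header line is present. The default matches the
#' common term/valence/arousal/dominance layout.
#'
#' @param columns Character vector naming, in file order, where the fields
#'   live. Must contain `"term"`, `"valence"`, `"arousal"`, `"dominance"`;
#'   other names are read and ignored.
#' @param header One of `FALSE`, `TRUE`, or `"auto"`. With `"auto"` the first
#'   row is treated as a header when its score fields do not parse as
#'   numbers.
#' @return A list of class `vad_dialect`.
#' @export
#' @examples
#' vad_dialect(c("term", "valence", "arousal", "dominance"), header = "auto")
vad_dialect <- function(columns = c("term", "valence", "arousal", "dominance"),
                        header = "auto") {
  needed <- c("term", "valence", "arousal", "dominance")
  if (!all(needed %in% columns)) {
    stop_validation("dialect columns must include term, valence, arousal, dominance")
  }
  if (!(isTRUE(header) || isFALSE(header) || identical(header, "auto"))) {
    stop_validation("header must be TRUE, FALSE or \"auto\"")
  }
  structure(list(columns = columns, header = header), class = "vad_dialect")
}

new_lexicon <- function(term, scores, centered, provenance = "",
                        parse_report = NULL) {
  colnames(scores) <- if (centered) c("va", "ar", "dm") else c("va", "ar", "dm")
  df <- data.frame(term = term, scores, stringsAsFactors = FALSE)
  structure(df,
    class = c("ousio_lexicon", "data.frame"),
    centered = centered, provenance = provenance,
    parse_report = parse_report
  )
}

#' @export
print.ousio_lexicon <- function(x, ...) {
  kind <- if (attr(x, "centered")) "centered [-1/2, 1/2]" else "raw [0, 1]"
  cat(sprintf(
    "<ousio_lexicon> %d terms, %s scale%s\n", nrow(x), kind,
    if (nzchar(attr(x, "provenance") %||% "")) {
      paste0(", source: ", attr(x, "provenance"))
    } else ""
  ))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Parse report of a lexicon read
#'
#' @param lex A lexicon returned by [read_vad_lexicon()].
#' @return A list with `rows_read`, `rows_kept`, `rows_rejected`, and a named
#'   integer vector `reasons`.
#' @export
parse_report <- function(lex) {
  attr(lex, "parse_report")
}

# Unicode NFC term normalization; single internal spaces of n-grams are
# preserved, case is untouched (the lexicon layer never folds case).
normalize_term <- function(x) {
  if (requireNamespace("stringi", quietly = TRUE)) {
    stringi::stri_trans_nfc(x)
  } else {
    enc2utf8(x)
  }
}

#' Read a tab-separated VAD lexicon
#'
#' Reads one term per row with three real-valued scores in \[0,1\] on the
#' best-worst-scaling survey scale. Invalid rows (non-numeric or
#' out-of-range scores, too few fields) are rejected and counted; duplicate
#' terms keep their first occurrence. Row order is preserved.
#'
#' @param path Path to a UTF-8, tab-separated file.
#' @param dialect A [vad_dialect()] describing column order and header.
#' @return An `ousio_lexicon` on the raw \[0,1\] scale with a parse report
#'   attached (see [parse_report()]).
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("calm\t0.7\t0.1\t0.5", "battle\t0.3\t0.9\t0.7"), f)
#' lex <- read_vad_lexicon(f)
#' parse_report(lex)$rows_kept
read_vad_lexicon <- function(path, dialect = vad_dialect()) {
  if (!inherits(dialect, "vad_dialect")) dialect <- do.call(vad_dialect, dialect)
  if (!file.exists(path)) stop_io(sprintf("lexicon file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_io(sprintf("lexicon file is empty: %s", path))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- length(dialect$columns)
  idx <- match(c("term", "valence", "arousal", "dominance"), dialect$columns)

  parse_row_scores <- function(f) {
    if (length(f) < ncols) return(NULL)
    suppressWarnings(as.numeric(f[idx[2:4]]))
  }

  start <- 1L
  if (isTRUE(dialect$header)) {
    start <- 2L
  } else if (identical(dialect$header, "auto")) {
    s1 <- parse_row_scores(fields[[1L]])
    if (is.null(s1) || anyNA(s1)) start <- 2L
  }
  if (start > length(fields)) stop_io("lexicon file contains a header but no data rows")
  fields <- fields[start:length(fields)]

  reasons <- c(too_few_fields = 0L, bad_score = 0L, duplicate = 0L)
  n <- length(fields)
  terms <- character(n)
  scores <- matrix(NA_real_, n, 3L)
  keep <- logical(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < ncols) {
      reasons[["too_few_fields"]] <- reasons[["too_few_fields"]] + 1L
      next
    }
    s <- suppressWarnings(as.numeric(f[idx[2:4]]))
    if (anyNA(s) || any(!is.finite(s)) || any(s < 0) || any(s > 1)) {
      reasons[["bad_score"]] <- reasons[["bad_score"]] + 1L
      next
    }
    terms[i] <- normalize_term(f[idx[1L]])
    scores[i, ] <- s
    keep[i] <- TRUE
  }
  if (any(keep)) {
    dup <- keep & duplicated(ifelse(keep, terms, NA_character_), incomparables = NA)
    reasons[["duplicate"]] <- sum(dup)
    keep <- keep & !dup
  }
  if (!any(keep)) {
    stop_io(sprintf("no valid rows in lexicon file: %s", path))
  }
  report <- list(
    rows_read = n, rows_kept = sum(keep),
    rows_rejected = n - sum(keep), reasons = reasons
  )
  new_lexicon(terms[keep], scores[keep, , drop = FALSE],
    centered = FALSE, provenance = basename(path), parse_report = report
  )
}

#' Center lexicon scores from \[0,1\] to \[-1/2, 1/2\]
#'
#' Subtracts exactly one half from every score. Best-worst scaling fixes the
#' design mean of each dimension at 1/2, so the shift is a constant, never
#' the empirical column mean; the singular-value decomposition downstream
#' depends on this convention.
#'
#' @param lex An `ousio_lexicon` on the raw scale.
#' @return An `ousio_lexicon` with every score in \[-1/2, 1/2\], identical
#'   term set and order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines("middle\t0.5\t0.5\t0.5", f)
#' center_scores(read_vad_lexicon(f))
center_scores <- function(lex) {
  stopifnot(inherits(lex, "ousio_lexicon"))
  if (isTRUE(attr(lex, "centered"))) {
    stop_contract("lexicon is already centered")
  }
  out <- lex
  out$va <- lex$va - 0.5
  out$ar <- lex$ar - 0.5
  out$dm <- lex$dm - 0.5
  attr(out, "centered") <- TRUE
  out
}

#' Write a lexicon or score table as TSV
#'
#' Writes a header row naming the dimensions and one term per row with
#' fixed 6-decimal scores. `read_vad_lexicon()` round-trips raw lexicons
#' written this way within that precision.
#'
#' @param x An `ousio_lexicon` or an `ousio_scores` matrix
#'   (see [as_score_matrix()]).
#' @param path Output file path.
#' @param framework Optional framework name used for the header when `x` does
#'   not carry one.
#' @return Invisibly, `path`.
#' @export
write_scores <- function(x, path, framework = NULL) {
  if (inherits(x, "ousio_lexicon")) {
    dims <- c("valence", "arousal", "dominance")
    m <- as.matrix(as.data.frame(x)[, c("va", "ar", "dm")])
    terms <- x$term
  } else if (inherits(x, "ousio_scores")) {
    dims <- colnames(x$values)
    m <- x$values
    terms <- x$terms
  } else {
    stop_contract("write_scores expects an ousio_lexicon or ousio_scores")
  }
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
    error = function(e) stop_io(sprintf("cannot open %s for writing", path))
  )
  on.exit(close(con))
  writeLines(paste(c("term", dims), collapse = "\t"), con)
  if (length(terms)) {
    body <- paste(
      terms,
      apply(m, 1L, function(r) paste(sprintf("%.6f", r), collapse = "\t")),
      sep = "\t"
    )
    writeLines(body, con)
  }
  invisible(path)
}
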