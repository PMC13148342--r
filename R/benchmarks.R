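#' Locate a user-supplied copy of the NRC VAD lexicon
#'
#' The ~20,000-term best-worst-scaled VAD lexicon is distributed by its
#' authors under terms that do not allow redistribution here, so the package
#' never ships it. To run the lexicon-dependent benchmarks, download the
#' lexicon once and either set
#' `options(ousiometrics.nrc_path = "/path/to/NRC-VAD-Lexicon.txt")` or place
#' the file at `tools::R_user_dir("ousiometrics", "data")` under the name
#' `NRC-VAD-Lexicon.txt`.
#'
#' @return The path if a copy is found, otherwise `NULL`.
#' @export
nrc_lexicon_path <- function() {
  p <- getOption("ousiometrics.nrc_path")
  if (!is.null(p) && file.exists(p)) return(p)
  p <- file.path(
    tools::R_user_dir("ousiometrics", "data"),
    "NRC-VAD-Lexicon.txt"
  )
  if (file.exists(p)) p else NULL
}

#' Benchmark quantities from a real VAD lexicon
#'
#' Runs the full derivation pipeline on a real term-scored lexicon and
#' returns the quantities most useful for checking a run against published
#' reference values for the ~20,000-term best-worst-scaled lexicon: the
#' singular values, explained variances, GAS and PDS matrices, PDS
#' coordinates of "success" and "murderer", type-level power/danger medians,
#' and the power range.
#'
#' @param path Path to the lexicon TSV (see [nrc_lexicon_path()]).
#' @param dialect A [vad_dialect()].
#' @return A list with elements `singular_values`, `explained_variance`,
#'   `gas_matrix`, `pds_matrix`, `correlations`, `success_pds`,
#'   `murderer_pds`, `median_pw`, `median_dg`, `pw_range`, `n_terms`.
#' @export
reproduce_lexicon_benchmarks <- function(path, dialect = vad_dialect()) {
  lex <- center_scores(read_vad_lexicon(path, dialect))
  vad <- as_score_matrix(lex)
  gas <- derive_gas_basis(vad)
  pds <- rotate_gas_to_pds(gas)
  pds_scores <- apply_basis(vad, pds)
  type_summary <- bias_summary(uniform_weights(pds_scores), pds_scores)
  pick <- function(term) {
    i <- match(term, pds_scores$terms)
    if (is.na(i)) rep(NA_real_, 3L) else unname(pds_scores$values[i, ])
  }
  list(
    n_terms = length(lex$term),
    singular_values = gas$singular_values,
    explained_variance = gas$explained_variance,
    gas_matrix = gas$matrix,
    pds_matrix = pds$matrix,
    correlations = pairwise_correlations(vad),
    success_pds = pick("success"),
    murderer_pds = pick("murderer"),
    median_pw = unname(type_summary$median["Pw"]),
    median_dg = unname(type_summary$median["Dg"]),
    pw_range = range(pds_scores$values[, "Pw"])
  )
}
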