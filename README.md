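# ousiometrics

Tools for analyzing the *essential meaning* of words: deriving a
power–danger–structure (PDS) coordinate system from valence–arousal–dominance
(VAD) lexicon scores, building annotated 2-D "ousiogram" histograms of a
corpus's lexical distribution, and measuring how the essential tone of a long
text moves over narrative time with a sliding-window "ousiometer".

## The scientific problem

Large human-rated lexicons score tens of thousands of words on three affective
dimensions — valence (good–bad), arousal (active–passive), and dominance
(powerful–weak) — each on a \[0, 1\] scale centered on a neutral design
midpoint of 0.5. Although the VAD axes are the traditional framework, they are
substantially correlated with each other (for the reference lexicon,
r(valence, dominance) ≈ 0.49), which means they are not the natural axes of
how raters actually organize meaning.

This package re-derives the natural axes empirically:

1. **Center**: subtract the design midpoint 0.5 from every score (never the
   empirical column means — the instrument's neutral point is part of the
   measurement model).
2. **Decompose**: take the singular value decomposition of the centered
   N×3 score matrix. The right-singular directions form an orthonormal basis
   ordered by explained variance. With a fixed sign convention, these are the
   **goodness–agitation–structure (GAS)** axes.
3. **Rotate**: the first two GAS axes, rotated by −45° in their plane, give
   **power** Pw = (Gd + Ag)/√2 and **danger** Dg = (−Gd + Ag)/√2, with
   structure unchanged. The PDS frame splits the dominant plane's variance
   equally between power and danger.

For the reference lexicon the first two axes explain 55.6% and 35.3% of the
variance (90.9% cumulative), so the essential plane rotation yields a
45.5/45.5 split with a plane correlation of exactly
(35.3 − 55.6)/90.9 ≈ −0.22 — a closed-form consequence of rotating two
uncorrelated axes by 45°.

On top of the frame derivation the package provides:

- **Lexicon I/O** with per-row validation, duplicate handling, and a
  configurable column dialect.
- **Corpus tools**: reading term-frequency tables, equal-weight merging of
  sub-corpora, tie-averaged ranks, the *lexical lens* (restricting a corpus
  to scored terms, with coverage accounting), and token-probability-weighted
  averages, medians, and skewness of any essential dimension.
- **Ousiograms**: 60×60 weighted 2-D histograms on \[−1, 1\]² with marginal
  distributions, weighted medians, a one-sigma SVD ellipse, and automatic
  word annotations — extremal terms along the convex-hull boundary plus
  nearest terms along eight interior rays — rendered with ggplot2/patchwork
  and always accompanied by a deterministic JSON sidecar.
- **Ousiometer**: a tokenizer-stable sliding-window time series (default
  window 10,000 tokens, stride 100) of windowed power/danger/structure with
  per-window coverage, plus epoch-partitioned trajectories.
- **Synthetic study generator**: Gaussian lexicons reproducing the reference
  VAD correlation structure and Zipf-distributed corpora, so the entire
  pipeline is exercisable offline with no redistributable-data concerns.
- A pipeline layer (`run_derive()`, `run_ousiogram()`, `run_corpus_stats()`,
  `run_meter()`, `run_synth()`) with YAML configs, manifests, and a thin
  command-line front end in `inst/cli/ousiometrics.R`.

## Worked example

Generate a synthetic lexicon under the default study conditions (20,000
terms, the reference VAD correlation structure), derive the GAS and PDS
bases, and inspect the essential statistics:

```r
library(ousiometrics)

lex <- generate_synthetic_lexicon(synthetic_lexicon_spec(n_terms = 20000, seed = 1))
scores <- as_score_matrix(lex)

pairwise_correlations(scores)
#>            Va         Ar        Dm
#> Va  1.0000000 -0.2762042 0.4772637
#> Ar -0.2762042  1.0000000 0.3036195
#> Dm  0.4772637  0.3036195 1.0000000

gas <- derive_gas_basis(scores)
gas
#> <framework_basis> GAS: (Gd, Ag, St) <- (Va, Ar, Dm)
#>        Va     Ar     Dm
#> Gd  0.855 -0.156  0.495
#> Ag -0.166  0.822  0.545
#> St  0.492  0.548 -0.677
#> singular values: 25.45, 20.81, 10.5
#> explained variance: 54.4%, 36.3%, 9.3%

pds <- rotate_gas_to_pds(gas)
pds
#> <framework_basis> PDS: (Pw, Dg, St) <- (Va, Ar, Dm)
#>        Va    Ar     Dm
#> Pw  0.487 0.471  0.735
#> Dg -0.722 0.691  0.035
#> St  0.492 0.548 -0.677
#> explained variance: 45.4%, 45.4%, 9.3%

pds_scores <- apply_basis(scores, pds)
bias_summary(uniform_weights(pds_scores), pds_scores)
#> <bias_summary> framework PDS
#>               Pw     Dg     St
#> mean     -0.0010 0.0008  4e-04
#> median   -0.0010 0.0011 -3e-04
#> skewness -0.0094 0.0052  5e-03
```

Build a token-weighted ousiogram from a Zipf corpus over the same lexicon:

```r
corpus <- generate_zipf_corpus(lex$term, n_tokens = 2e5, seed = 2)
lensed <- lexical_lens(corpus, pds_scores)
grid <- build_ousiogram(pds_scores, c("Pw", "Dg"), weights = lensed$dist)
grid
#> <ousiogram_grid> Pw vs Dg, 60x60 bins (width 0.03333), total weight 200000
#> medians: Pw = -0.003853, Dg = 0.02945; max bin 21310

ann <- annotate_ousiogram(grid, pds_scores)
render_ousiogram(grid, ann, "ousiogram.png")  # figure + ousiogram.png.json sidecar
```

Run the ousiometer over a long token stream:

```r
set.seed(3)
text <- paste(sample(lex$term, 30000, replace = TRUE), collapse = " ")
series <- windowed_scores(tokenize_1grams(text), scores = pds_scores,
                          W = 10000, s = 100)
head(series, 3)
#>   center            Pw          Dg           St coverage
#> 1   5000  3.171643e-04 0.001197595 0.0007866015        1
#> 2   5100 -1.078278e-04 0.001190500 0.0007165973        1
#> 3   5200 -1.604276e-05 0.000848385 0.0006963031        1

traj <- build_trajectory(series, n_epochs = 10)
```

A real lexicon goes through the same pipeline: `read_vad_lexicon(path)` then
`center_scores()` in place of the synthetic generator.

## Command line

```sh
Rscript inst/cli/ousiometrics.R derive --out-dir out --seed 1
Rscript inst/cli/ousiometrics.R ousiogram --frequencies counts/ --out-dir out
Rscript inst/cli/ousiometrics.R meter --text book.txt --window 10000 --stride 100 --out-dir out
```

Exit codes: 0 ok, 10 I/O error, 11 validation error, 12 contract error,
13 other.

## License

MIT. See `LICENSE`.
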