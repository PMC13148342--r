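---
title: "Methods: deriving and using the power–danger–structure frame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving and using the power–danger–structure frame}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ousiometrics)
```

This vignette documents the model, parameter choices, and numerical
conventions behind the package. It is a methods reference, not a tutorial;
see the README for a worked example.

## The measurement model

Input lexicons assign each word a valence (Va), arousal (Ar), and dominance
(Dm) score on $[0, 1]$, produced by a best–worst scaling instrument whose
neutral point is the scale midpoint. The package therefore centers by
subtracting exactly $0.5$ from every score (`center_scores()`), never the
empirical column means: the midpoint is part of the instrument design, and
centering on sample means would make derived quantities depend on the
particular word list rather than the scale.

Centered scores live in $[-0.5, 0.5]^3$. All downstream frames are linear
images of these centered coordinates.

## Deriving the GAS basis

`derive_gas_basis()` computes the singular value decomposition of the
$N \times 3$ centered matrix $X = U \Sigma V^\top$. The rows of the returned
basis matrix are the right-singular directions $V^\top$, ordered by singular
value, so the first derived axis carries the largest share of the total sum
of squares; explained variances are $\sigma_i^2 / \sum_j \sigma_j^2$.

SVD determines each direction only up to sign. The package fixes signs by a
convention expressed in the derived frame: the goodness axis must load
positively on valence, agitation positively on arousal, and structure
*negatively* on dominance (`sign_convention = c(1, 1, -1)` on the diagonal
pivots). This makes bases comparable across lexicons and runs.

Degenerate inputs (rank-deficient score matrices) are flagged rather than
rejected: the basis carries a `degenerate` attribute when the smallest
singular value is at relative machine tolerance.

## The −45° rotation to power–danger–structure

`rotate_gas_to_pds()` applies a fixed rotation in the plane of the first two
axes:

$$
\mathrm{Pw} = \frac{\mathrm{Gd} + \mathrm{Ag}}{\sqrt 2}, \qquad
\mathrm{Dg} = \frac{-\mathrm{Gd} + \mathrm{Ag}}{\sqrt 2}, \qquad
\mathrm{St} \text{ unchanged.}
$$

Two closed-form consequences are useful as invariants. If the GAS plane
axes are uncorrelated with variances $v_1 > v_2$, then after the rotation
each plane axis carries $(v_1 + v_2)/2$ of the variance and the plane
correlation is $(v_2 - v_1)/(v_1 + v_2)$. With the reference explained
variances of 55.6% and 35.3% this gives a 45.5/45.5 split and a correlation
of $-0.223$. The test suite checks both identities to $10^{-9}$ on
exactly-orthogonal constructions.

A caveat on decorrelation: the SVD orthogonalizes *uncentered* cross-products
(columns are centered by the constant 0.5, not by their sample means), while
Pearson correlation centers on sample means. Exact zero correlations in the
GAS frame therefore hold only for exactly mean-zero inputs; for sampled
lexicons the residual correlation is $O(1/\sqrt N)$.

Because published basis matrices are typically reported to two decimals,
`framework_basis()` accepts an `orthonormal_tol` (default 0.05) and records
the actual deviation; internally derived bases are held to $10^{-9}$.

## Cone rankings

`rank_terms_in_cone()` ranks terms by their component along an arbitrary
axis, restricted to a cone about that axis. The default half-angle is
$\tfrac{1}{2} \arccos(2/\sqrt 6) \approx 17.6^\circ$ — half the angle
between a cube diagonal-adjacent pair of frame axes — chosen so cones
around distinct essential axes do not overlap.

## Corpus statistics

Frequency files are term–count TSVs; duplicates are summed; sub-corpora are
merged with *equal weight* (each is normalized to a probability distribution
first, then averaged), so a large year cannot drown out a small one. Ranks
use tie-averaging, so tied counts share the mean of the ranks they occupy.

The *lexical lens* restricts a distribution to terms present in the score
matrix and reports type and token coverage; a warning is raised when token
coverage falls below `min_token_coverage` (default 25%). Token-weighted
statistics are probability-weighted: the average of dimension $M$ is
$\sum_\tau p_\tau M_\tau$, invariant under positive rescaling of all
weights. Weighted medians use the *lower* convention — the smallest score
whose cumulative probability reaches 0.5, with no interpolation — which is
exact for point masses and deterministic for ties. Weighted skewness is
$m_3 / m_2^{3/2}$ with probability-weighted central moments.

## Ousiograms

`build_ousiogram()` bins a 2-D projection of the scores into a $60 \times 60$
histogram on $[-1, 1]^2$ (bin width $1/30$). Bins are half-open with the
floor convention, index $\lfloor (v - \mathrm{lo}) / w \rfloor$, except the
last bin, which is closed so $+1$ is representable. Out-of-extent values are
clipped into boundary bins and counted (with a warning) rather than dropped,
so histogram mass always equals total weight. Marginals are row and column
sums of the same counts; the one-sigma ellipse comes from the eigensystem of
the weighted covariance (divisor $N$, radii = square roots of eigenvalues).

Annotations are deterministic:

- **Boundary**: convex hull of occupied bin centers, oriented clockwise;
  each hull edge is divided into segments of roughly `spacing` (default
  0.15) and each segment is labeled with the not-yet-used term maximizing
  the projection onto the edge's outward normal.
- **Internal**: eight rays at multiples of $\pi/4$; on each ray,
  `n_per_ray` (default 4) evenly spaced targets between an origin-exclusion
  radius (default 0.1) and the data's extent along the ray, each labeled
  with the nearest unused term.

`render_ousiogram()` always writes a JSON sidecar (bins, marginals, medians,
ellipse, annotations, style; schema version "1.0") that is byte-deterministic
given the same inputs; figure rendering failures degrade to a warning so
headless environments still get the sidecar.

## The ousiometer

`tokenize_1grams()` lowercases the text, applies Unicode NFC when stringi is
available, and splits on the pattern
`[\p{L}\p{N}_]+(?:['’-][\p{L}\p{N}]+)*|[^\p{L}\p{N}\s]`: words keep internal
apostrophes and hyphens, every punctuation character is its own token, and
nothing is discarded. The rules are versioned (`TOKENIZER_VERSION`) and
idempotent on their own output, and manifests record the version so series
from different tokenizers are never silently compared.

`windowed_scores()` slides a window of `W` tokens (default 10,000) with
stride `s` (default 100): windows start at token 1 and there are
$\lfloor (T - W)/s \rfloor + 1$ of them; the reported center is
$W/2 + (k-1)s$. Within each window only lexicon 1-grams contribute, via the
same probability-weighted average as the corpus statistics; per-window
coverage is reported, and a window with zero matched tokens yields `NA`, not
zero — absence of evidence is not neutrality. The implementation uses
cumulative sums, so cost is linear in $T$ regardless of overlap.
`build_trajectory()` partitions the windows into `n_epochs` (default 10)
near-equal consecutive epochs with boundaries
$\lfloor n k / E \rfloor$.

Texts shorter than one window are rejected with a validation error: the
defaults are tuned for book-length texts, and for short texts one should
lower `W` explicitly rather than get a silently unstable series.

## The synthetic study generator

`generate_synthetic_lexicon()` draws centered VAD scores from a trivariate
Gaussian with the reference correlation structure
($r_{Va,Ar} = -0.27$, $r_{Ar,Dm} = 0.30$, $r_{Va,Dm} = 0.49$) and standard
deviations $(0.16, 0.13, 0.13)$, clipped to $[-0.5, 0.5]$. The defaults are
the study conditions: 20,000 terms matches the reference lexicon's scale,
the standard-deviation ratio 1 : 0.8 : 0.8 mirrors the reference singular
value proportions, and the magnitudes keep more than 99.8% of draws
in-range so clipping is negligible (the spec validator requires
$0.5/\mathrm{sd} \ge z_{0.995}$). Under these defaults the derived GAS and
PDS matrices land within about 0.02 of the reference values.

What the generator does *not* emulate: the heavy tails, multimodality, and
semantic clustering of real lexicons, and any relationship between a word's
frequency and its scores. `generate_zipf_corpus()` draws token counts from a
Zipf law (default exponent 1) independently of the scores; real corpora
couple the two.

## Reproducibility conventions

Every pipeline writes a manifest with the package version, tokenizer
version, sidecar schema version, the full configuration, and MD5 hashes of
inputs. All randomness flows from explicit seeds in `synthetic_lexicon_spec()`
and `run_config()`; repeated runs are byte-identical where the format is
text (CSV series, JSON sidecars). Errors are classed (`ousio_io_error`,
`ousio_validation_error`, `ousio_contract_error`) and map to stable CLI exit
codes via `ousio_exit_codes()`.
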