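---
title: "Methods: similarity-mapped QR storage of medical images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity-mapped QR storage of medical images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qrstore)
```

## What the package models

`qrstore` implements a storage-and-retrieval pipeline for grayscale
medical images built around three ideas:

1. **Images as probability distributions.** Each image is segmented and
   summarized by intensity, shape and texture features; the feature
   vector is mapped onto the probability simplex.  Two images are then
   compared by the Bhattacharyya coefficient
   $BC(P,Q) = \sum_x \sqrt{P(x)Q(x)}$ and its distance
   $D_B(P,Q) = -\ln BC(P,Q)$.
2. **A modified t-SNE.** The corpus is embedded in 2-D by stochastic
   neighbour embedding in which the input metric is $D_B$ (instead of
   Euclidean distance) and the objective is a Bregman divergence
   $B_\phi(P\|Q) = \phi(P) - \phi(Q) - \langle\nabla\phi(Q), P-Q\rangle$
   (with the generalized-KL generator $\phi = \sum p\log p$ as default,
   which coincides with Kullback–Leibler divergence on normalized
   affinities).  Classical Gaussian/KL t-SNE remains available as the
   baseline mode.
3. **Deduplicating QR storage.** Records are kept in a single-process,
   file-backed index.  Images are compressed by truncated SVD; each
   record is encoded into a QR symbol with Reed–Solomon error
   correction.  At ingest, if the best Bhattacharyya similarity
   $e^{-D_B}$ against the existing corpus strictly exceeds **0.70**, no
   new full entry is created: the record is stored as a *tag* referring
   to the near-duplicate's factors, and its QR payload carries only the
   key, the tag and the metadata.

## The embedding engine

Given pairwise input distances $D$, per-point conditional affinities are
$p(j|i) \propto \exp(-\beta_i D_{ij}^2)$ with $\beta_i$ found by
bisection so that the row perplexity $2^{H(p(\cdot|i))}$ (entropy in
bits) matches the target within relative tolerance $10^{-4}$.  Rows
whose off-diagonal distances are all equal are returned uniform — the
only distribution consistent with the data, achieving perplexity
$n-1$.  Infinite distances (disjoint supports) are capped at ten times
the largest finite distance before calibration so the bisection stays
well-posed.

Two interpretive decisions deserve a record:

* **The high-dimensional kernel.** The modified algorithm is sometimes
  read as skipping kernelization because Bhattacharyya inputs are
  already normalized.  But a perplexity-matched conditional affinity is
  itself part of the algorithm's contract, and raw distances are not
  row-stochastic.  The exponential family
  $p(j|i)\propto\exp(-\beta_i D_B^2)$ is the minimal construction that
  honors the perplexity step; it is used for both metrics.
* **The low-dimensional kernel.** Taking "Bhattacharyya distances
  between embedded points" literally is ill-posed — embedded points are
  not distributions.  The default low-dimensional kernel is therefore
  the Student-t kernel of standard t-SNE (chosen for its documented
  crowding-resistance).  A `simplex_bhattacharyya` mode realizes the
  literal reading by passing each embedded row through a softmax and
  using $q_{ij}\propto BC(\mathrm{softmax}(y_i), \mathrm{softmax}(y_j))$;
  it is selectable via `embed_config(low_dim_kernel=)` and covered by
  the same analytic-vs-numeric gradient checks, but it is not the
  default because the softmax collapses scale information and converges
  less reliably.

Conditionals are symmetrized to the joint
$p_{ij} = (p(j|i) + p(i|j))/2n$ as in standard practice.  Optimization
is full-batch gradient descent with momentum $0.5 \to 0.8$ (switch at
iteration 250), adaptive per-coordinate gains, early exaggeration
$\times 4$ for the first 100 iterations, learning rate 100 and at most
1000 iterations, stopping early when the relative cost change over 50
iterations falls below $10^{-7}$.  A learning rate of $10^{-3}$ appears
in the source material attached to an unrelated, unspecified neural
component; it is not used as the t-SNE step size (both are
configurable).  Note that the Bhattacharyya distance, although used
here inside a Bregman-minimizing algorithm, is itself *not* a Bregman
divergence and does not satisfy the triangle inequality; the test suite
deliberately asserts the properties it does have (symmetry,
nonnegativity, identity of indiscernibles) and no more.

## The QR codec

The codec is written from scratch and is bit-compatible with the public
QR standard, which the generation procedure defers to: ISO/IEC 18004
conventions are normative for capacity and block tables, mask formulas,
placement order and format/version words.  Error correction is
Reed–Solomon over $GF(2^8)$ with primitive polynomial 0x11D and
generator roots $\alpha^0..\alpha^{n_{ec}-1}$.  Decoding corrects up to
$\lfloor n_{ec}/2\rfloor$ byte errors per block (Berlekamp–Massey +
Chien search; error magnitudes come from solving the syndrome
Vandermonde system rather than Forney's formula — same result, fewer
root-convention pitfalls).  All eight masks are scored with the four
standard penalty rules and ties break to the lowest mask id.

Symbol *reading* is deterministic finder-pattern detection: scanlines
are run-length encoded, dark:light:dark:light:dark runs matching
1:1:3:1:1 within 50% per element are cross-validated vertically, and
each candidate must reproduce the full 7×7 finder template at module
spacing.  The four axis-aligned rotations are supported; perspective
rectification of camera photographs is out of scope (store-generated
symbols are clean renders).  A trained cascade detector was considered
and rejected: no training data or cascade description exists to
reproduce, and ratio detection is the mechanism production QR readers
use.

The EC block-structure table ships as a CSV of
`(version, level, ec_per_block, n_blocks)` only; the group-1/group-2
split and all character capacities are *derived* from the module-layout
count, and the derived totals are asserted against the standard's
per-version codeword counts in the test suite.  Interoperability of
generated symbols was verified against an independent zbar-based
decoder (50/50 payload-identical across all modes, EC levels, versions
1–12); the corresponding acceptance test requires `python` with
`pyzbar` at run time and fails — rather than skips — where no
independent decoder is installed.

## Compression and the store

Truncated SVD is the compressor; by Eckart–Young the squared Frobenius
reconstruction error equals the discarded singular-value energy, an
identity the tests check to $10^{-8}$ relative on every rank.  The rank
is chosen as the smallest $k$ capturing 95% of spectral energy by
default.  (QR *matrix decomposition* is named alongside SVD in the
source material without distinct roles; SVD subsumes it here, and no
separate orthogonalization path is exposed.)

The "more than 70% similarity" rule is evaluated on the **feature
histogram distribution of the segmented image**, not raw pixels.  The
quantity the 70% refers to is genuinely unspecified in the source
material; the feature-distribution choice ties the rule to the same
Bhattacharyya machinery the embedding uses and is tolerant to small
translations.  Tags are flattened at ingest (a tag's target always
holds factors), so chains cannot form; the suite asserts this over 500
randomized ingests.  The index is a single JSON file written via
temp-file rename; factors are flat binary files, symbols are PGM
rasters.

Images are read and written as 8-bit PGM rather than PNG: no
PNG-capable package is available in the supported dependency set, PGM
is lossless and text-representable, and every mainstream imaging stack
reads it.

## The synthetic world

`generate_phantom_image()` emulates a radiograph as a noisy uniform
background (level 0.2) carrying 1–8 disc "lesions" with
sigmoid-smoothed edges, peak intensities 0.6–0.9 and additive Gaussian
noise of σ = 0.02 — values chosen once as a plausible desk-scale
stand-in for radiographic contrast, not tuned to any test.  Discs are
placed by rejection sampling so they never overlap, making the
truth-mask component count checkable by an independent flood-fill
oracle.  What the phantoms do *not* model: anatomy, texture
nonstationarity, acquisition artifacts, 3-D structure.  A green
embedding or segmentation test therefore establishes algorithmic
correctness on separable structure, not clinical performance — which
is also why the pipeline's reported classification numbers are labelled
a *surrogate* (nearest-neighbour agreement of synthetic finding labels
in the embedding).  The headline external-dataset accuracy figures of
the source material are measured on data and a labeling task that are
not reproducible at desk scale and are deliberately not asserted
anywhere in this package.

Cluster fixtures for the embedding engine place $k$ isotropic
unit-variance Gaussians with means `separation`/√2 along distinct
coordinate axes (pairwise distance exactly `separation`); histogram
fixtures for the modified mode draw three Dirichlet families with
distinct concentration peaks.  Record fixtures carry exactly twelve
fields, mirroring a tabular radiology manifest, with an MD5 checksum of
the image bytes so tampering is detectable.

## Numerical choices and degenerate inputs

* Z-score normalization uses the population σ; constant input is an
  error, not a silent zero-division.
* `features_to_distribution` shifts by the minimum and adds a floor of
  $10^{-12}$ before normalizing, so mapped distributions share support
  and $D_B$ never takes $\ln 0$ between them.
* Affinity floors: joint $P$ at $10^{-15}$, low-dimensional $Q$ at
  $10^{-12}$ — guards against log-of-zero, far below any affinity that
  matters at the supported problem sizes.
* Undefined classification ratios (zero denominators) are `NaN`, never
  silently 0.  F1 is the harmonic mean of precision and recall; a
  variant phrasing ("recall and accuracy") in the source material is
  treated as an erratum, being inconsistent with every comparative
  table it accompanies.
* ROC AUC is the normalized Mann–Whitney statistic with ties counted ½.
* Otsu thresholding quantizes to 256 levels; its cumulative-moments
  implementation is checked against an exhaustive threshold sweep.

## Known limitations

* The embedding is exact $O(n^2)$ per iteration — no Barnes–Hut or
  interpolation acceleration; corpora beyond a few thousand points are
  out of scope.
* The QR decoder assumes one clean, axis-aligned symbol per image.
* Kanji and ECI modes, Micro-QR and structured append are not
  implemented; byte mode covers arbitrary content.
* The store is a single-process design; the distributed-database
  machinery the source material sketches (caching layers, partitioning,
  replication, stream brokers) is infrastructure, not computation, and
  is deliberately excluded.
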