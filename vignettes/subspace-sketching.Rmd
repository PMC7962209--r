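---
title: "Subspace sketching of k-mer sets: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subspace sketching of k-mer sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(KmerSketch)
```

## The model

Sketching methods compare large sequence datasets by reducing each dataset's
k-mer set to a small signature. MinHash-style signatures map k-mers through a
many-to-one hash, which costs accuracy (collisions) and forbids exact set
algebra on the signatures. KmerSketch instead samples a *structured subspace*
of the k-mer space and recodes the sampled k-mers one-to-one.

Write a k-mer `K` of length `k`. A **selection pattern** `p` (a 01-string of
length `k`) splits `K` into the selected substring `p1(K)` (bases at the 1s,
length `w`) and the unselected substring `p0(K)` (bases at the 0s). The
**substring space** is the set of all `4^w` DNA strings of length `w`; each
string is a dimension. The space is shuffled once with a seeded Fisher–Yates
permutation and cut into `N = 4^a` equal blocks ("subspaces") of `4^(w-a)`
dimensions; within a block, dimensions are ranked by their position, i.e.
recoded by lexically ordered strings of length `w - a`. One block is chosen
(by default the first; `chosen` selects another).

The sketch of a k-mer set `A` is

```
S(A) = { p0(K) · s(p1(K)) : K in A, p1(K) in chosen subspace }
```

with `s(.)` the in-subspace rank string; the concatenation is read as a
base-4 integer of `2(k-a)` bits, unselected bases in the high-order
position. Three facts carry the whole method:

1. **Uniform sampling.** The shuffle is unbiased, so the chosen subspace is
   a uniform sample without replacement of the dimensions;
   `E|S(A)| = |A|/N`, and the Jaccard/containment estimators computed from
   sketches are unbiased for the true set coefficients.
2. **Injectivity.** Distinct selected k-mers get distinct codes (the
   unselected context is carried verbatim, the rank map is a bijection on
   the block). Hence no collisions, and sketching *commutes* with union,
   intersection and subtraction — operating on sketches equals sketching
   the operated-on raw sets, exactly.
3. **Decomposability.** Running the same map with every block partitions
   `r(A)` into `N` disjoint components whose sizes sum to `|A|`; exact `J`
   and `C` are recovered by accumulating per-component intersections and
   unions, touching only `~1/N` of the data at a time.

Distances: `D_mash = -(1/k) ln(2J/(1+J))` (resemblance, similar-sized sets)
and `D_aaf = -(1/k) ln C` (containment, very different sizes) both estimate
the per-base mutation distance under a substitution model.

## Parameters and conventions

| parameter | meaning | default / constraint |
|---|---|---|
| `x` | half k-mer length, `k = 2x` | CLI constraint `12 > x` |
| `y` | half pattern weight, `w = 2y` | `x > y >= 1` |
| `z` | reduction level, `a = 2z`, fold `= 16^z` | `y > z + 2 > 1` |
| `a` | partition exponent, `N = 4^a` | library accepts any `0 <= a <= w` |
| `seed` | shuffle seed | required for reproducibility |
| `chosen` | retained subspace index | `0` (first shuffled block) |
| `minOcc` | occurrence filter | `1`; use `2` for read sets |
| `canonical` | sketch canonical k-mers | `TRUE` |

The symmetric template `0^(x-y) 1^(2y) 0^(x-y)` keeps `k` even and makes
selection commute with reverse complementation, so canonical sketches are
strand-independent. The library also accepts arbitrary patterns (the
classic illustrative example `"000010010000"` is asymmetric), but warns
that canonical sketches over asymmetric patterns are not strand-invariant.
The constraint `y > z + 2` keeps the post-reduction subspace larger than
`16^2` dimensions for robustness; the CLI enforces the full chain
`12 > x > y > z + 2 > 1` and reports the violated inequality.

`suggestK(g, u) = round_even(log4(3g/2u))` advises the k-mer length for a
genome size `g` and a random-hit probability bound `u` in [0.001, 0.01]:
k = 16 for bacterial-sized genomes, 20–22 for mammalian genomes and
metagenomes. Rounding uses R's `round()` (banker's rounding at exact .5
half-steps — a tie that cannot occur for integer `g` in practice).

## Statistics

`Ĵ` and `Ĉ` are sample proportions with denominators `n = |S(A)∪S(B)|` and
`n = min(|S(A)|,|S(B)|)`. The package reports `sd = sqrt(p̂(1-p̂)/n)`, the
95% CI `p̂ ± 1.96 sd` clipped to [0,1] (the symmetric form; one printed
source shows both bounds with a minus sign, an evident typo), the
upper-tail normal P-value of `z = p̂/sd` with the degenerate conventions
`P = 1` at `p̂ = 0` and `P = 0` at `p̂ = 1`, and the Q-value
`P × (#queries × #references)`, reported both raw and clipped at 1. The
Gaussian approximation needs `n p > 10`; smaller products are *flagged*
(`lowCount`, and `j_low_count`/`c_low_count` in the distance table) rather
than switched to an exact test, keeping the output monotone and filterable.

## Numerical choices and degenerate inputs

* **Distance saturation.** `J = 0` or `C = 0` gives an infinite distance;
  it is reported as 1.0 with a `saturated` flag (attribute on the scalar
  API, `j_saturated`/`c_saturated` in the distance table).
* **Code width.** Codes occupy `2(k-a)` bits and are stored as doubles;
  `k <= 26` is asserted at pattern construction so codes stay exact
  (`< 2^52`). The CLI's `x < 12` keeps `k <= 22` anyway.
* **Memory cap.** The materialized permutation has `4^w` entries; weights
  above `maxW` (default 14, ~268M entries) are refused loudly
  ("resource error") rather than silently subsampled.
* **Ambiguity handling.** Bases other than ACGT (any case) break the
  current window; no N-substitution. Window counts reflect only valid
  windows. Coordinates are 0-based, half-open.
* **Occurrence filter.** Counted per distinct selected k-mer, per sketching
  call (a sample spanning files should be sketched in one call); memory is
  proportional to the sketch, not the k-mer set.
* **Component code collisions.** Numeric code values may coincide across
  decomposition components (the rank strings live in different subspaces);
  all component-wise operations therefore pair components by subspace
  index, and the subspace-tagged global recoding is collision-free —
  concatenating components reconstructs the undecomposed `a = 0` recoding
  exactly.
* **Empty results.** An empty sketch is valid (with a warning); Jaccard of
  two empty sketches and containment against an empty sketch are errors.

## Reproducibility

The shuffle RNG is xoshiro256++ seeded via splitmix64, with unbiased
bounded draws by rejection; Fisher–Yates runs with descending index. All of
it is plain 64-bit integer arithmetic, so a `.shuf` file is byte-identical
across platforms and compilers given `(w, a, seed, chosen)`. On-disk
formats (`.shuf`, sketch DB, decomposition) are small versioned binaries
with magic numbers and an FNV-1a content checksum; sketches carry a full
parameter fingerprint and every pairwise operation refuses mismatched
fingerprints. The simulator derives one child seed per mutation-rate grid
point from the master seed by an integer hash, so any mutant is
independently regenerable.

## What the simulator emulates — and what it does not

`randomGenome()` draws i.i.d. uniform ACGT; `mutateGenome()` applies
independent per-site substitutions (uniform over the three alternatives),
no indels — the regime in which the Mash/Aaf conversions are derived. The
default `mutationGrid()` reproduces the standard benchmark design: 600
mutants at rates 0.001–0.60 step 0.001 (rates ≤ 0.3 conventionally the
"closely related" group). `accuracyExperiment()` sketches reference and
mutants and reports the Pearson r between true rates and estimated Mash
distances, scaled to `-log(1 - r)` (natural log) for readability, `Inf`
and a flag at machine-precision `r = 1`.

Real genomes are not i.i.d.: repeats, skewed composition and indels all
reduce distinct-k-mer counts and bias distance estimates in ways this
generator cannot produce. A green accuracy test therefore establishes that
the estimator chain (sketch → Ĵ → distance) recovers substitution rates on
homogeneous sequence at the stated sizes; it does not certify accuracy on
repeat-rich or rearranged genomes, nor on read sets with sequencing error
(for which the `minOcc = 2` filter exists). Benchmarks here run at a 1 Mb
reference by default — desk scale, chosen so the whole suite runs in
minutes; correlations at this scale are properties of the method, not
reproductions of any published curve, which depends on the (unstated)
reference genome used there.

## Open choices made here

* The single retained subspace is the *first* shuffled block by default
  (any index is selectable); nothing in the method favours one block.
* Canonicalization is ON by default and applied to the whole k-mer before
  substring selection.
* `a` is any integer in `[0, w]` in the library; the CLI exposes the
  `a = 2z` (16-fold-step) convention only, and maps "decomposition" to an
  explicit `decompose` verb instead of overloading level 0, so `z = 0`
  unambiguously means one undecomposed full-space sketch (`N = 1`).
* Set-operation results keep the minuend's occurrence metadata; mixed
  `minOcc` provenance is recorded as `NA` ("mixed").
* Byte-level compatibility with any external sketching tool's file formats
  is a non-goal.

## Known limitations

References below ~10 kb reduce to uninformatively small sketches at 16-fold
reduction and are better compared unreduced (`a = 0`). Reduction folds are
restricted to powers of 4 (CLI: powers of 16). Amino-acid alphabets are not
supported. Sketches store only presence, not abundance.
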