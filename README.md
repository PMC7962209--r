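# KmerSketch

Alignment-free comparison of nucleotide sequence datasets by sketching —
reducing each dataset's k-mer set to a small, similarity-preserving set of
integers — with a *subspace-sampling* scheme instead of MinHash. It is aimed
at people who compare genomes, read sets and metagenomes at scale: estimating
mutation distance between assemblies, screening a sequencing run against a
reference collection by containment, or clustering population resequencing
runs after subtracting the reference genome.

## The method

A *selection pattern* `p` is a 01-string of length `k`; the bases of a k-mer
at the 1-positions form its **selected substring** (length `w`, the pattern
weight), the rest its unselected substring. The space of all `4^w` selected
substrings is Fisher–Yates shuffled with a seeded, portable RNG, partitioned
into `N = 4^a` equal subspaces, and one subspace is kept. A k-mer enters the
sketch iff its selected substring lies in the kept subspace, so the expected
sketch is a `1/N` fraction of the distinct k-mer set. Each kept k-mer `K` is
recoded injectively as

    r(K) = p0(K) · s(p1(K))

— the unselected substring concatenated with the in-subspace rank of the
selected substring, read as a base-4 integer. Because `r` is one-to-one
(no hash collisions), for k-mer sets `A`, `B`:

* `Ĵ = |S(A)∩S(B)| / |S(A)∪S(B)|` and `Ĉ = |S(A)∩S(B)| / min(|S(A)|,|S(B)|)`
  are *unbiased* estimates of the true Jaccard and containment coefficients;
* `D_mash = -(1/k) ln(2Ĵ/(1+Ĵ))` and `D_aaf = -(1/k) ln Ĉ` estimate the
  per-base mutation distance;
* set algebra is exact on sketches: `S(A∩B) = S(A)∩S(B)`,
  `S(A∪B) = S(A)∪S(B)`, `S(A−B) = S(A)−S(B)` — union, intersection and
  reference subtraction can be done on sketches as if on the raw data;
* sketching with *every* subspace decomposes a k-mer set into `N` disjoint
  components from which the exact `J` and `C` are recovered component by
  component under `~1/N` memory.

`Ĵ` and `Ĉ` are sample proportions, so each estimate comes with the binomial
standard deviation `sqrt(p̂(1−p̂)/n)`, a clipped 95% CI, an upper-tail normal
P-value and a Q-value multiplied by the number of comparisons.

## Worked example

Sketch a simulated 1 Mb genome and a 2%-mutated copy at 16-fold reduction
with k = 16 (`x = 8, y = 5, z = 1` in the symmetric-template convention):

```r
library(KmerSketch)
pat <- symmetricPattern(8, 5)          # "0001111111111000": k = 16, w = 10
sp  <- shuffleSpace(pat, a = 2, seed = 42)
ref <- randomGenome(1e6, seed = 1)
mut <- mutateGenome(ref, 0.02, seed = 2)
skR <- sketchSequences(ref, pat, sp, sampleId = "ref", format = "seq")
skR
#> Sketch 'ref': 62,423 codes from 999,985 k-mer windows
#>   k = 16, w = 10, N = 4^2, subspace 0, minOcc = 1, canonical = TRUE
skM <- sketchSequences(mut, pat, sp, sampleId = "mut", format = "seq")
allVsAll(sketchDB(skM), sketchDB(skR))
#>   query reference size_a size_b shared union jaccard mash_dist j_pvalue
#> 1   mut       ref  62364  62423  45131 79656  0.5666   0.02024        0
```

The sketch holds 62,423 of ~1M k-mers (close to the expected 1/16), and the
estimated Mash distance 0.0202 recovers the simulated per-base mutation rate
0.02. `suggestK(5e6, 0.001)` returns 16 — the recommended k for
bacterial-sized genomes.

The same workflow is available from the shell via the installed script
(`system.file("scripts", "kmersketch", package = "KmerSketch")`):
`shuffle`, `sketch`, `dist`, `set -u/-i/-s`, `decompose`, `exactdist`,
`simulate`, `bench accuracy` and `suggest-k` subcommands; see `?runCLI`.

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline worked-example
quantity (the dimensionality of the substring space induced by the
illustrative 12-mer pattern with two selected positions) from scratch with
the installed package and writes it as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/subspace-sketching.Rmd`) describes the
model and its assumptions, the parameter conventions (`x`, `y`, `z` and the
constraint `12 > x > y > z + 2 > 1`), what the bundled simulator does and
does not emulate, and the numerical edge-case policies (distance saturation,
CI clipping, low-count flags).
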