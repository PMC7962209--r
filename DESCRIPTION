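Package: KmerSketch
Title: Dimensionality Reduction of K-mer Sets by Subspace Sampling for
    Alignment-Free Genome Comparison
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sketches nucleotide sequence datasets by sampling a shuffled
    k-mer substring space, a collision-free alternative to MinHash-style
    sketching. A k-mer substring selection pattern splits every k-mer into a
    selected and an unselected substring; the space of selected substrings is
    seeded-shuffled, partitioned into equal subspaces, and one subspace
    retained, so the expected sketch is a fixed fraction of the k-mer set.
    Selected k-mers are recoded by an injective integer map, which makes
    Jaccard and containment estimators unbiased and makes exact set algebra
    (union, intersection, subtraction) on sketches possible. Provides Mash
    and Aaf mutation-distance conversions with binomial standard errors,
    confidence intervals and multiplicity-adjusted significance; full
    decomposition of a k-mer set into per-subspace components for exact
    Jaccard/containment recovery under bounded memory; and a point-mutation
    simulator with a Pearson-correlation accuracy harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
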