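.withSeed <- function(seed, expr) {
  # run expr under a local RNG state so simulators do not disturb the caller
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Random reference genome
#'
#' An i.i.d. uniform ACGT string, fully determined by \code{seed}.
#'
#' @param length genome length in bp.
#' @param seed integer seed.
#' @return a single character string.
#' @export
randomGenome <- function(length, seed = 1L) {
  stopifnot(length >= 1)
  .withSeed(seed, paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                        collapse = ""))
}

#' Point-mutate a genome
#'
#' Each position is independently substituted with probability \code{rate};
#' a substituted base becomes one of the three other bases uniformly.
#' Length is preserved (no indels: the substitution-only model matches the
#' regime in which the Mash/Aaf distance conversions estimate the per-base
#' mutation rate).
#'
#' @param genome a single character string over ACGT.
#' @param rate per-base substitution probability, \code{0 <= rate < 1}.
#' @param seed integer seed; (genome, rate, seed) fully determine the mutant.
#' @return the mutated character string.
#' @export
mutateGenome <- function(genome, rate, seed = 1L) {
  stopifnot(length(genome) == 1L, rate >= 0, rate < 1)
  if (rate == 0) return(genome)
  bases <- c("A", "C", "G", "T")
  v <- strsplit(genome, "", fixed = TRUE)[[1]]
  .withSeed(seed, {
    hit <- which(runif(length(v)) < rate)
    if (length(hit)) {
      old <- match(v[hit], bases) - 1L
      v[hit] <- bases[((old + sample.int(3L, length(hit), replace = TRUE)) %% 4L) + 1L]
    }
  })
  paste(v, collapse = "")
}

# Deterministic child seed for grid point i (1-based): a Knuth-style integer
# hash of (seed, i) reduced below 2^31 so downstream consumers can treat it
# as an ordinary R integer seed.
childSeed <- function(seed, i) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 69069 + as.numeric(i) * 40503) %% 2147483647) + 1L
}

#' Design an in-silico evolution experiment
#'
#' A grid of per-base substitution rates applied to one random reference
#' genome.  The default grid, 0.001 to 0.60 in steps of 0.001, reproduces
#' the 600-mutant design used to benchmark distance estimators; rates up to
#' 0.3 are conventionally called the closely related group and the rest the
#' distantly related group.  Each grid point gets a deterministic child seed
#' derived from the master seed, so any mutant can be regenerated in
#' isolation.
#'
#' @param referenceLength reference genome length in bp.
#' @param from,to,by rate grid bounds and step (inclusive of \code{to} when
#'   on-grid).
#' @param rates explicit rate vector overriding \code{from/to/by}.
#' @param seed master seed.
#' @return A [MutationGrid-class].
#' @examples
#' length(gridRates(mutationGrid(1e5)))  # 600
#' @export
mutationGrid <- function(referenceLength = 1e6, from = 0.001, to = 0.60,
                         by = 0.001, rates = NULL, seed = 1L) {
  if (is.null(rates)) {
    n <- floor((to - from) / by + 1e-9)
    rates <- from + by * (0:n)
  }
  new("MutationGrid", referenceLength = as.numeric(referenceLength),
      rates = rates, seed = as.integer(seed))
}

#' @rdname accessors
#' @export
gridRates <- function(x) {
  stopifnot(is(x, "MutationGrid"))
  x@rates
}

#' Generate the genomes of a mutation grid
#'
#' Returns the reference (seeded from the master seed) and one mutant per
#' rate, each produced with its grid point's child seed.
#'
#' @param grid a [MutationGrid-class].
#' @return list with elements \code{reference} (string) and \code{mutants}
#'   (character vector named by rate).
#' @export
gridGenomes <- function(grid) {
  stopifnot(is(grid, "MutationGrid"))
  ref <- randomGenome(grid@referenceLength, grid@seed)
  mutants <- vapply(seq_along(grid@rates), function(i) {
    mutateGenome(ref, grid@rates[i], childSeed(grid@seed, i))
  }, "")
  names(mutants) <- format(grid@rates, trim = TRUE)
  list(reference = ref, mutants = mutants)
}

setMethod("show", "MutationGrid", function(object) {
  cat("MutationGrid: ", length(object@rates), " rates in [",
      min(object@rates), ", ", max(object@rates), "], reference ",
      format(object@referenceLength, big.mark = ","), " bp, seed ",
      object@seed, "\n", sep = "")
})

#' Accuracy harness: estimated distance versus true mutation rate
#'
#' Sketches the grid's reference and every mutant under each sketching
#' parameter set, computes the Mash distance of each mutant to the
#' reference, and reports the Pearson correlation \code{r} between the true
#' rates and the estimated distances, plus the readability scaling
#' \code{-log(1 - r)} (natural log; infinite and flagged when \code{r = 1}
#' to machine precision, as for a perfect estimator).  Degenerate (constant)
#' estimate vectors yield \code{NA} and are flagged.
#'
#' @param grid a [MutationGrid-class].
#' @param params a list of parameter sets, each a list with elements
#'   \code{x, y, z} (symmetric-pattern half length, half weight, reduction
#'   level so \code{a = 2z}) and optional \code{label}, \code{seed} (space
#'   seed; default the grid's).
#' @param genomes optional precomputed [gridGenomes()] result (to share
#'   genomes across calls).
#' @return a \code{data.frame} with one row per parameter set: \code{label,
#'   k, w, a, sketch_size_ref, pearson_r, neg_log_1mr, degenerate}.
#' @export
accuracyExperiment <- function(grid, params, genomes = NULL) {
  stopifnot(is(grid, "MutationGrid"), is.list(params), length(params) >= 1)
  if (is.null(genomes)) genomes <- gridGenomes(grid)
  rows <- lapply(params, function(ps) {
    x <- ps$x; y <- ps$y; z <- if (is.null(ps$z)) 1L else ps$z
    seed <- if (is.null(ps$seed)) grid@seed else ps$seed
    pat <- symmetricPattern(x, y)
    sp <- shuffleSpace(pat, a = 2L * z, seed = seed)
    refSk <- sketchSequences(genomes$reference, pat, sp, sampleId = "ref",
                             format = "seq")
    est <- vapply(genomes$mutants, function(m) {
      sk <- sketchSequences(m, pat, sp, sampleId = "mut", format = "seq")
      as.numeric(mashDistance(jaccardEstimate(refSk, sk), pat@k))
    }, 0)
    degenerate <- stats::sd(est) == 0
    r <- if (degenerate) NA_real_ else cor(grid@rates, est)
    data.frame(
      label = if (is.null(ps$label)) paste0("k", pat@k, "z", z) else ps$label,
      k = pat@k, w = pat@w, a = 2L * z,
      sketch_size_ref = sketchSize(refSk),
      pearson_r = r,
      neg_log_1mr = if (is.na(r) || r >= 1) Inf else -log(1 - r),
      degenerate = degenerate || (!is.na(r) && r >= 1),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write sequences as FASTA
#'
#' Small convenience for persisting simulated genomes.
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  dss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}
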