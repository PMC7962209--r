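.checkComparable <- function(a, b) {
  if (!identical(a@fingerprint, b@fingerprint))
    stop("incompatible-sketch error: sketches were built with different ",
         "parameters or shuffled spaces")
}

.sharedCount <- function(a, b) sum(!is.na(match(a, b)))

#' Jaccard and containment estimators
#'
#' For sketches \code{S(A)} and \code{S(B)} built from the same shuffled
#' space, \code{jaccardEstimate()} returns
#' \code{|S(A) n S(B)| / |S(A) u S(B)|} and \code{containmentEstimate()}
#' returns \code{|S(A) n S(B)| / min(|S(A)|, |S(B)|)}.  Because the chosen
#' subspace is a uniform sample of the substring space and the recoding is
#' injective, both are unbiased estimates of the true Jaccard/containment of
#' the underlying k-mer sets.  The Jaccard coefficient suits sets of similar
#' size; containment suits sets of very different sizes (e.g. a genome
#' against a metagenome).
#'
#' @param SA,SB [Sketch-class] objects with identical fingerprints.
#' @return numeric in \code{[0, 1]}.
#' @export
jaccardEstimate <- function(SA, SB) {
  .checkComparable(SA, SB)
  sh <- .sharedCount(SA@codes, SB@codes)
  un <- length(SA@codes) + length(SB@codes) - sh
  if (un == 0L)
    stop("parameter error: Jaccard undefined for two empty sketches")
  sh / un
}

#' @rdname jaccardEstimate
#' @export
containmentEstimate <- function(SA, SB) {
  .checkComparable(SA, SB)
  if (!length(SA@codes) || !length(SB@codes))
    stop("parameter error: containment undefined for an empty sketch")
  .sharedCount(SA@codes, SB@codes) / min(length(SA@codes), length(SB@codes))
}

#' Mutation-distance conversions
#'
#' \code{mashDistance()} converts a Jaccard estimate to the Mash distance
#' \code{-(1/k) ln(2J / (1 + J))}; \code{aafDistance()} converts a
#' containment estimate to the Aaf distance \code{-(1/k) ln(C)}.  Both
#' estimate the per-base mutation distance between the two sequence sets.  A
#' zero coefficient gives an infinite distance; it is reported as 1.0 and
#' flagged via the \code{"saturated"} attribute (a logical vector parallel to
#' the input).
#'
#' @param jhat,chat numeric in \code{[0, 1]} (vectorized).
#' @param k k-mer length used for sketching.
#' @return numeric distances with attribute \code{"saturated"}.
#' @examples
#' mashDistance(1/3, 21)  # log(2)/21
#' @export
mashDistance <- function(jhat, k) {
  stopifnot(all(jhat >= 0 & jhat <= 1), k >= 1)
  sat <- jhat == 0
  d <- ifelse(sat, 1.0, -(1 / k) * log(2 * jhat / (1 + jhat)))
  attr(d, "saturated") <- sat
  d
}

#' @rdname mashDistance
#' @export
aafDistance <- function(chat, k) {
  stopifnot(all(chat >= 0 & chat <= 1), k >= 1)
  sat <- chat == 0
  d <- ifelse(sat, 1.0, -(1 / k) * log(chat))
  attr(d, "saturated") <- sat
  d
}

#' Significance statistics for a sketch-derived proportion
#'
#' Jaccard and containment estimates are sample proportions, asymptotically
#' Gaussian with standard deviation \code{sqrt(p(1-p)/n)} where \code{n} is
#' the union size (Jaccard) or the smaller sketch size (containment).
#' Returns the population SD, the 95\% confidence interval
#' \code{p +/- 1.96 sd} clipped to \code{[0, 1]}, the upper-tail normal
#' P-value of \code{z = p/sd} (defined as 1 when \code{p = 0}), and the
#' multiplicity-adjusted Q-value \code{P * nQueries * nRefs} (raw product,
#' plus a copy clipped at 1).  \code{lowCount} flags \code{n p <= 10}, where
#' the Gaussian approximation is doubtful.
#'
#' @param pHat estimated proportion in \code{[0, 1]}.
#' @param n denominator count (>= 1).
#' @param nQueries,nRefs dimensions of the comparison batch; their product is
#'   the number of tests.
#' @return a one-row \code{data.frame} with columns \code{pHat, n, sd,
#'   ciLow, ciHigh, pValue, qValueRaw, qValue, lowCount}.
#' @export
proportionStat <- function(pHat, n, nQueries = 1L, nRefs = 1L) {
  if (any(n < 1)) stop("parameter error: n must be >= 1")
  stopifnot(all(pHat >= 0 & pHat <= 1))
  sd <- sqrt(pHat * (1 - pHat) / n)
  ciLow <- pmax(0, pHat - 1.96 * sd)
  ciHigh <- pmin(1, pHat + 1.96 * sd)
  pValue <- ifelse(pHat == 0, 1,
                   ifelse(sd == 0, 0, pnorm(pHat / sd, lower.tail = FALSE)))
  qRaw <- pValue * nQueries * nRefs
  data.frame(pHat = pHat, n = n, sd = sd, ciLow = ciLow, ciHigh = ciHigh,
             pValue = pValue, qValueRaw = qRaw, qValue = pmin(1, qRaw),
             lowCount = n * pHat <= 10)
}

.pairRecord <- function(q, r, nQueries, nRefs) {
  sh <- .sharedCount(q@codes, r@codes)
  sa <- length(q@codes); sb <- length(r@codes)
  un <- sa + sb - sh
  jhat <- if (un > 0) sh / un else NA_real_
  chat <- if (min(sa, sb) > 0) sh / min(sa, sb) else NA_real_
  k <- q@fingerprint$k
  md <- if (is.na(jhat)) NA_real_ else mashDistance(jhat, k)
  ad <- if (is.na(chat)) NA_real_ else aafDistance(chat, k)
  js <- if (un > 0) proportionStat(jhat, un, nQueries, nRefs) else NULL
  cs <- if (min(sa, sb) > 0) proportionStat(chat, min(sa, sb), nQueries, nRefs)
        else NULL
  flags <- c(
    if (!is.na(jhat) && jhat == 0) "j_saturated",
    if (!is.na(chat) && chat == 0) "c_saturated",
    if (!is.null(js) && js$lowCount) "j_low_count",
    if (!is.null(cs) && cs$lowCount) "c_low_count",
    if (un == 0) "empty_pair")
  data.frame(
    query = q@sampleId, reference = r@sampleId,
    size_a = sa, size_b = sb, shared = sh, union = un,
    jaccard = jhat, containment = chat,
    mash_dist = as.numeric(md), aaf_dist = as.numeric(ad),
    j_sd = if (is.null(js)) NA_real_ else js$sd,
    j_ci_low = if (is.null(js)) NA_real_ else js$ciLow,
    j_ci_high = if (is.null(js)) NA_real_ else js$ciHigh,
    j_pvalue = if (is.null(js)) NA_real_ else js$pValue,
    j_qvalue = if (is.null(js)) NA_real_ else js$qValue,
    c_sd = if (is.null(cs)) NA_real_ else cs$sd,
    c_ci_low = if (is.null(cs)) NA_real_ else cs$ciLow,
    c_ci_high = if (is.null(cs)) NA_real_ else cs$ciHigh,
    c_pvalue = if (is.null(cs)) NA_real_ else cs$pValue,
    c_qvalue = if (is.null(cs)) NA_real_ else cs$qValue,
    flags = paste(flags, collapse = ","),
    stringsAsFactors = FALSE)
}

#' All-queries versus all-references comparison
#'
#' Compares every query sketch against every reference sketch (query-major
#' order) and returns one row per pair with shared/union counts, Jaccard and
#' containment estimates, Mash and Aaf distances, and per-estimator SD, 95\%
#' CI, P and Q values.  Q-values use \code{x * y} tests for \code{x} queries
#' against \code{y} references.
#'
#' @param qry,ref [SketchDB-class] objects with identical fingerprints (a
#'   single [Sketch-class] is promoted to a one-sample DB).
#' @return a \code{data.frame} with \code{length(qry) * length(ref)} rows.
#' @seealso [writeDistances()]
#' @export
allVsAll <- function(qry, ref) {
  if (is(qry, "Sketch")) qry <- sketchDB(qry)
  if (is(ref, "Sketch")) ref <- sketchDB(ref)
  stopifnot(is(qry, "SketchDB"), is(ref, "SketchDB"))
  if (!length(qry@sketches) || !length(ref@sketches))
    stop("parameter error: empty sketch database")
  if (!identical(qry@fingerprint, ref@fingerprint))
    stop("incompatible-sketch error: query and reference databases were ",
         "built with different parameters or shuffled spaces")
  nq <- length(qry@sketches); nr <- length(ref@sketches)
  rows <- vector("list", nq * nr)
  i <- 0L
  for (q in qry@sketches) {
    for (r in ref@sketches) {
      i <- i + 1L
      rows[[i]] <- .pairRecord(q, r, nq, nr)
    }
  }
  do.call(rbind, rows)
}

#' Write a distance table as TSV
#'
#' @param records a \code{data.frame} from [allVsAll()].
#' @param path output file.
#' @param digits significant digits for floating-point columns.
#' @return \code{path}, invisibly.
#' @export
writeDistances <- function(records, path, digits = 6L) {
  out <- records
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], signif, digits = digits)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Suggest a k-mer length for a genome size
#'
#' Evaluates \code{log4(3 g / (2 u))}, where \code{g} is the genome size and
#' \code{u} the allowed upper bound on the probability that a random k-mer
#' hits the genome by chance, and rounds to the nearest even integer (the
#' symmetric selection pattern requires even k).  Typical \code{u} ranges
#' from 0.001 to 0.01; values outside that range are accepted with a
#' warning.  This yields k = 16 for bacterial-sized or smaller genomes and
#' k = 20-22 for mammalian genomes or metagenomes.
#'
#' @param g genome size in bp.
#' @param u random-hit probability bound.
#' @return even integer k.
#' @examples
#' suggestK(5e6, 0.001)  # 16
#' @export
suggestK <- function(g, u = 0.001) {
  stopifnot(g > 0, u > 0)
  if (u < 0.001 || u > 0.01)
    warning("u = ", u, " is outside the recommended range [0.001, 0.01]")
  kraw <- log(3 * g / (2 * u), base = 4)
  as.integer(2 * round(kraw / 2))
}
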