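# Syntrophic-potential statistics, the no-exchange null model, and the
# significance tests used on observed-vs-expected counts.

.pairIsSyntrophic <- function(pairs) nzchar(pairs$syntrophicSources)

#' Pair counts implied by a population design
#'
#' For `nSources` primary carbon sources with `perSource` metabolisms each:
#' the number of unordered metabolism pairs, of unordered source
#' combinations (including same-source), of pairings involving one fixed
#' metabolism, and the within/between-source pair counts used as the
#' denominators of the pair syntrophic potential. The canonical design (50
#' sources, 20 per source) gives 499500 / 1275 / 999 / 190 / 400.
#'
#' @param nSources number of primary carbon sources.
#' @param perSource metabolisms sampled per source.
#' @return list with `totalPairs`, `sourceCombinations`,
#'   `pairsPerMetabolism`, `withinSourcePairs`, `betweenSourcePairs`.
#' @export
populationPairCounts <- function(nSources, perSource) {
  n <- nSources * perSource
  list(totalPairs = choose(n, 2),
       sourceCombinations = choose(nSources, 2) + nSources,
       pairsPerMetabolism = n - 1,
       withinSourcePairs = choose(perSource, 2),
       betweenSourcePairs = perSource^2)
}

#' Syntrophic potential of each metabolism
#'
#' The syntrophic potential of a metabolism is the fraction of its pairings
#' with the other population members that produce at least one syntrophic
#' carbon source; with N metabolisms the denominator is N - 1 (999 for the
#' canonical population of 1,000).
#'
#' @param pairs pair table from [pairSyntrophy()] (one row per unordered
#'   pair of the whole population).
#' @return named numeric vector of potentials in `[0, 1]`, one per label.
#' @export
syntrophicPotentials <- function(pairs) {
  labels <- sort(unique(c(pairs$labelA, pairs$labelB)))
  n <- length(labels)
  if (n < 2) stop("need at least two metabolisms")
  s <- .pairIsSyntrophic(pairs)
  counts <- setNames(numeric(n), labels)
  tA <- tapply(s, pairs$labelA, sum); tB <- tapply(s, pairs$labelB, sum)
  counts[names(tA)] <- counts[names(tA)] + tA
  counts[names(tB)] <- counts[names(tB)] + tB
  counts / (n - 1)
}

#' Carbon-source pair syntrophic potential
#'
#' Fraction of metabolism pairings between two primary-carbon-source
#' classes that produce a syntrophy. With `n` metabolisms per source the
#' denominator is `n^2` for two different sources and `n (n - 1) / 2`
#' within a source (400 and 190 for the canonical 20 per source).
#'
#' @inheritParams syntrophicPotentials
#' @return symmetric numeric matrix of potentials, sources as dimnames,
#'   with the per-entry denominators in `attr(, "denominators")`.
#' @export
pairSyntrophicPotentials <- function(pairs) {
  prim <- rbind(data.frame(l = pairs$labelA, p = pairs$primaryA),
                data.frame(l = pairs$labelB, p = pairs$primaryB))
  prim <- prim[!duplicated(prim$l), ]
  sources <- sort(unique(prim$p))
  perSource <- table(factor(prim$p, levels = sources))
  s <- .pairIsSyntrophic(pairs)
  k <- length(sources)
  num <- den <- matrix(0, k, k, dimnames = list(sources, sources))
  pi <- factor(pairs$primaryA, levels = sources)
  pj <- factor(pairs$primaryB, levels = sources)
  for (r in seq_len(nrow(pairs))) {
    i <- as.integer(pi[r]); j <- as.integer(pj[r])
    num[i, j] <- num[i, j] + s[r]
    if (i != j) num[j, i] <- num[j, i] + s[r]
  }
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ni <- perSource[i]; nj <- perSource[j]
    den[i, j] <- if (i == j) ni * (ni - 1) / 2 else ni * nj
  }
  sp <- ifelse(den > 0, num / den, NA_real_)
  attr(sp, "denominators") <- den
  sp
}

#' Expected additional carbon sources for a pair under no exchange
#'
#' Null model: a pair with no metabolite exchange is viable on a carbon
#' source iff at least one member is individually viable, which happens
#' with probability `1 - (1 - pI)(1 - pJ)` per source. The expectation runs
#' over the `nSources - 2` sources beyond the two (different) primaries, or
#' `nSources - 1` when the primaries coincide.
#'
#' @param pI,pJ per-metabolism probabilities of viability on an additional
#'   carbon source (estimate: additional viable sources / (nSources - 1)).
#' @param samePrimary logical; do the two primaries coincide?
#' @param nSources number of carbon sources screened (default 50).
#' @return expected additional carbon-source count (vectorized).
#' @export
nullExpectedAdditional <- function(pI, pJ, samePrimary, nSources = 50) {
  stopifnot(all(pI >= 0 & pI <= 1), all(pJ >= 0 & pJ <= 1))
  (nSources - ifelse(samePrimary, 1, 2)) * (1 - (1 - pI) * (1 - pJ))
}

#' Observed vs null-expected additional sources for every pair
#'
#' Estimates each metabolism's off-primary viability probability from its
#' profile (`(|profile| - 1) / (nSources - 1)`), and tabulates for every
#' pair the observed number of additional carbon sources gained through
#' pooling against the no-exchange expectation of
#' [nullExpectedAdditional()].
#'
#' `observed` is the number of carbon sources the pooled pair gains beyond
#' the union of the individual profiles (the syntrophic gains);
#' `unionAdditional` the off-primary sources already covered individually;
#' `expected` the no-exchange expectation.
#'
#' @inheritParams syntrophicPotentials
#' @param profiles profile table from [viabilityProfileTable()].
#' @param nSources number of carbon sources screened.
#' @return data.frame with `labelA`, `labelB`, `observed`,
#'   `unionAdditional`, `expected`.
#' @export
nullModelTable <- function(pairs, profiles, nSources) {
  nAdd <- vapply(strsplit(profiles$viableSources, ";", fixed = TRUE),
                 function(v) sum(nzchar(v)), numeric(1)) - 1
  nAdd <- pmax(nAdd, 0)
  p <- setNames(nAdd / (nSources - 1), profiles$label)
  data.frame(labelA = pairs$labelA, labelB = pairs$labelB,
             observed = pairs$nJointAdditional,
             unionAdditional = .pairUnionAdditional(pairs, profiles),
             expected = nullExpectedAdditional(
               p[pairs$labelA], p[pairs$labelB],
               pairs$primaryA == pairs$primaryB, nSources),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Sources beyond both primaries covered by the individual profiles of a
# pair (the no-exchange part of the pair's additional sources).
.pairUnionAdditional <- function(pairs, profiles) {
  prof <- strsplit(setNames(profiles$viableSources, profiles$label),
                   ";", fixed = TRUE)
  vapply(seq_len(nrow(pairs)), function(r) {
    u <- union(prof[[pairs$labelA[r]]], prof[[pairs$labelB[r]]])
    length(setdiff(u[nzchar(u)],
                   c(pairs$primaryA[r], pairs$primaryB[r])))
  }, numeric(1))
}

#' Exact sign test of paired observed vs expected counts
#'
#' Two-sided exact binomial sign test on the paired differences; ties are
#' dropped.
#'
#' @param observed,expected equal-length numeric vectors.
#' @return the p-value (1 if every pair is tied).
#' @export
signTestObservedVsNull <- function(observed, expected) {
  stopifnot(length(observed) == length(expected))
  d <- observed - expected
  d <- d[d != 0]
  if (!length(d)) return(1)
  binom.test(sum(d > 0), length(d), 0.5)$p.value
}

#' Two-proportion test
#'
#' Chi-squared two-proportion comparison (plumbing for comparing the
#' syntrophy frequency of metabolism pairs against randomly augmented
#' single metabolisms).
#'
#' @param k1,n1 successes and trials of the first group.
#' @param k2,n2 successes and trials of the second group.
#' @return the p-value.
#' @export
twoProportionTest <- function(k1, n1, k2, n2) {
  suppressWarnings(prop.test(c(k1, k2), c(n1, n2))$p.value)
}

#' Syntrophy incidence by carbon source
#'
#' Counts, per carbon source, the pairs for which it is syntrophic, and
#' each source's share of all observed syntrophies.
#'
#' @inheritParams syntrophicPotentials
#' @param carbonSources sources to tabulate (default: those observed).
#' @return data.frame with `carbonSource`, `count`, `share` (0 when no
#'   syntrophy is observed at all).
#' @export
incidenceByCarbonSource <- function(pairs, carbonSources = NULL) {
  hits <- unlist(strsplit(pairs$syntrophicSources, ";", fixed = TRUE))
  hits <- hits[nzchar(hits)]
  if (is.null(carbonSources)) carbonSources <- sort(unique(hits))
  counts <- table(factor(hits, levels = carbonSources))
  total <- sum(counts)
  data.frame(carbonSource = carbonSources,
             count = as.integer(counts),
             share = if (total > 0) as.numeric(counts) / total else 0,
             row.names = NULL, stringsAsFactors = FALSE)
}
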