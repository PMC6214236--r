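#' @include AllClasses.R
NULL

## log2 binomial coefficient via log-gamma; well-defined for non-integer k
## (needed for the balanced normalizer at odd N)
.log2choose <- function(n, k) {
    (lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)) / log(2)
}

## n * log2(p) with the 0 * log(0) = 0 convention; -Inf when p = 0, n > 0
.nlog2p <- function(n, p) {
    out <- ifelse(n == 0, 0, n * log2(p))
    out[n > 0 & p == 0] <- -Inf
    out
}

#' Multinomial log2 score of a pair-solution observation
#'
#' Log2 probability that, of \code{N = n1 + n2 + n3} reads on a variant
#' pair, \code{n1} support one haplotype of the candidate solution,
#' \code{n2} the other, and \code{n3} are unexpected, under a multinomial
#' model with outcome likelihoods given by \code{params}:
#' \deqn{MS = \log_2\left[ \binom{N}{n_1}\binom{N-n_1}{n_2}
#'   P_1^{n_1} P_2^{n_2} P_3^{n_3} \right]}
#' Computed in log space via log-gamma. If some \eqn{P_i = 0} while
#' \eqn{n_i > 0} the score is \code{-Inf}.
#'
#' All three count arguments are vectorized.
#'
#' @param n1,n2,n3 Non-negative read counts (haplotype 1, haplotype 2,
#'   unexpected).
#' @param params A [ScoringParams-class].
#' @return The log2 multinomial probability (numeric).
#' @examples
#' multinomialScore(1, 0, 0, scoringParams(0.5, 0.5)) # -1
#' multinomialScore(2, 2, 0, scoringParams())         # log2(6 * 0.49^4)
#' @export
multinomialScore <- function(n1, n2, n3, params = scoringParams()) {
    if (any(c(n1, n2, n3) < 0)) stop("counts must be non-negative")
    N <- n1 + n2 + n3
    .log2choose(N, n1) + .log2choose(N - n1, n2) +
        .nlog2p(n1, params@p1) + .nlog2p(n2, params@p2) +
        .nlog2p(n3, params@p3)
}

#' Coverage normalizing factor
#'
#' The factor subtracted from the multinomial score to remove the
#' dependence of its magnitude on the total read count \eqn{N}:
#' \deqn{F = \log_2\left[ \binom{N}{N/2}\binom{N}{N/2}
#'   P_1^{N/2} P_2^{N/2} \right]}
#' For odd \eqn{N} the binomial coefficient is evaluated continuously via
#' log-gamma. \code{N = 0} gives 0 (empty product). Vectorized over `N`.
#'
#' @param N Total read count(s) on the pair.
#' @param params A [ScoringParams-class].
#' @return Numeric factor(s) on the log2 scale.
#' @examples
#' normalizingFactor(2, scoringParams(0.5, 0.5)) # 0
#' normalizingFactor(4)                          # log2(36 * 0.49^4)
#' @export
normalizingFactor <- function(N, params = scoringParams()) {
    if (any(N < 0)) stop("N must be non-negative")
    2 * .log2choose(N, N / 2) +
        .nlog2p(N / 2, params@p1) + .nlog2p(N / 2, params@p2)
}

#' Coverage ratio and its sigmoid weight
#'
#' The local-coverage adjustment of the confidence score: \code{c} is the
#' ratio of the pair's read count to the largest pair read count in its
#' block, and the weight is the logistic function with inflection at 0.5,
#' \eqn{s = 1 / (1 + e^{-(c - 0.5)})}. Pairs in well-covered regions
#' (c near 1) are trusted more than pairs in locally thin regions.
#'
#' @param localCoverage Read count on the pair of interest.
#' @param maxCoverage Largest pair read count in the block (> 0).
#' @return A list with components \code{c} and \code{s}.
#' @examples
#' coverageSigmoid(10, 20)$s # 0.5
#' coverageSigmoid(20, 20)$s # ~0.6225
#' @export
coverageSigmoid <- function(localCoverage, maxCoverage) {
    if (any(maxCoverage <= 0))
        stop("degenerate block: maxCoverage must be positive")
    if (any(localCoverage < 0) || any(localCoverage > maxCoverage))
        stop("localCoverage must lie in [0, maxCoverage]")
    cc <- localCoverage / maxCoverage
    list(c = cc, s = stats::plogis(cc - 0.5))
}

.solutionCounts <- function(rc, solution) {
    ## S1 pairs the alleles in cis (0-0 / 1-1); S2 in trans (0-1 / 1-0)
    if (solution == "S1")
        c(n1 = rc[[1L]], n2 = rc[[4L]], n3 = rc[[2L]] + rc[[3L]])
    else
        c(n1 = rc[[2L]], n2 = rc[[3L]], n3 = rc[[1L]] + rc[[4L]])
}

#' Confidence score of one candidate solution for a variant pair
#'
#' Scores how well the four-cell read counts of a variant pair fit one of
#' the two candidate pairings under the heterozygous assumption. Solution
#' \code{"S1"} treats the 0-0 and 1-1 cells as the two haplotypes
#' (\code{n1 = rc00, n2 = rc11}); \code{"S2"} the 0-1 and 1-0 cells. The
#' remaining reads are unexpected (\code{n3}). The score is the
#' multinomial score normalized for coverage depth and weighted by the
#' local-coverage sigmoid:
#' \deqn{CS = \log_2 s(c) + (MS - F)}
#' so that CS ranges from minus infinity to zero; values closer to zero
#' indicate higher confidence.
#'
#' @param obs A [PairObservation-class].
#' @param solution \code{"S1"} or \code{"S2"}.
#' @param maxCoverage Largest pair read count in the block.
#' @param params A [ScoringParams-class].
#' @param localCoverage Read count used for the coverage ratio; defaults
#'   to the observation's total.
#' @return A list (score breakdown) with components \code{n1}, \code{n2},
#'   \code{n3}, \code{MS}, \code{F}, \code{NS}, \code{c}, \code{CS}.
#' @examples
#' confidenceScore(pairObservation(10, 1, 0, 9), "S1", maxCoverage = 20)
#' @export
confidenceScore <- function(obs, solution = c("S1", "S2"), maxCoverage,
                            params = scoringParams(),
                            localCoverage = NULL) {
    solution <- match.arg(solution)
    N <- totalReads(obs)
    if (N == 0L)
        stop(structure(
            class = c("hierphase_unscorable", "error", "condition"),
            list(message = "pair has no informative reads and cannot be scored",
                 call = sys.call())))
    if (is.null(localCoverage)) localCoverage <- N
    n <- .solutionCounts(obs@rc, solution)
    MS <- multinomialScore(n[["n1"]], n[["n2"]], n[["n3"]], params)
    FF <- normalizingFactor(N, params)
    sig <- coverageSigmoid(localCoverage, maxCoverage)
    list(n1 = n[["n1"]], n2 = n[["n2"]], n3 = n[["n3"]],
         MS = MS, F = FF, NS = MS - FF, c = sig$c,
         CS = log2(sig$s) + MS - FF)
}

#' Confidence score of a variant pair
#'
#' Evaluates both candidate solutions of a pair and keeps the higher one.
#' An exact tie (e.g. a fully symmetric count table) is flagged; the
#' assembly stage resolves such ties by a local MEC vote.
#'
#' @inheritParams confidenceScore
#' @return A list with \code{CS1}, \code{CS2}, \code{CS = max(CS1, CS2)},
#'   \code{solution} (\code{"S1"} or \code{"S2"}) and \code{tied}.
#' @examples
#' pairCS(pairObservation(10, 1, 0, 9), maxCoverage = 20)$solution # "S1"
#' pairCS(pairObservation(5, 5, 5, 5),  maxCoverage = 20)$tied     # TRUE
#' @export
pairCS <- function(obs, maxCoverage, params = scoringParams(),
                   localCoverage = NULL) {
    b1 <- confidenceScore(obs, "S1", maxCoverage, params, localCoverage)
    b2 <- confidenceScore(obs, "S2", maxCoverage, params, localCoverage)
    tied <- identical(b1$CS, b2$CS)
    list(CS1 = b1$CS, CS2 = b2$CS, CS = max(b1$CS, b2$CS),
         solution = if (tied || b1$CS >= b2$CS) "S1" else "S2",
         tied = tied)
}

#' Classify a variant pair as normal, singleton or low-coverage
#'
#' Singleton and low-coverage pairs are the ambiguous pairs whose
#' confidence scores cannot be trusted to guide assembly. A singleton pair
#' has all its reads in a single allele-combination cell, so only one
#' haplotype is ever observed under either candidate solution; a
#' low-coverage pair has fewer reads than the block threshold (by default
#' the median pair read count in the block). Singleton takes precedence.
#'
#' @param obs A [PairObservation-class].
#' @param lowCovThreshold Block-level threshold; pairs with strictly fewer
#'   reads are low-coverage.
#' @return One of \code{"singleton"}, \code{"low_coverage"},
#'   \code{"normal"}.
#' @examples
#' classifyPair(pairObservation(7, 0, 0, 0), 6)  # singleton
#' classifyPair(pairObservation(2, 0, 0, 1), 6)  # low_coverage
#' @export
classifyPair <- function(obs, lowCovThreshold) {
    rc <- obs@rc
    if (sum(rc > 0L) == 1L) return("singleton")
    if (sum(rc) < lowCovThreshold) return("low_coverage")
    "normal"
}

## ---- vectorized block-level scoring ------------------------------------

## Count the four allele combinations for every directly observed site
## pair of a block. Returns a data.frame with one row per observed pair.
.pairCounts <- function(fragments, n) {
    fs <- fragments@sites
    fa <- fragments@alleles
    ii <- jj <- aa <- bb <- vector("list", length(fs))
    for (k in seq_along(fs)) {
        s <- fs[[k]]
        m <- length(s)
        if (m < 2L) next
        p <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
        ii[[k]] <- s[p[, 1L]]
        jj[[k]] <- s[p[, 2L]]
        aa[[k]] <- fa[[k]][p[, 1L]]
        bb[[k]] <- fa[[k]][p[, 2L]]
    }
    i <- unlist(ii, use.names = FALSE)
    if (is.null(i) || !length(i))
        return(data.frame(i = integer(), j = integer(), n00 = integer(),
                          n01 = integer(), n10 = integer(), n11 = integer(),
                          N = integer()))
    j <- unlist(jj, use.names = FALSE)
    a <- unlist(aa, use.names = FALSE)
    b <- unlist(bb, use.names = FALSE)
    key <- (as.numeric(i) - 1) * n + j
    uk <- sort(unique(key))
    kx <- match(key, uk)
    cell <- 2L * a + b
    cnt <- vapply(0:3, function(cc) {
        tabulate(kx[cell == cc], nbins = length(uk))
    }, integer(length(uk)))
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1L)
    data.frame(i = as.integer((uk - 1) %/% n + 1),
               j = as.integer((uk - 1) %% n + 1),
               n00 = cnt[, 1L], n01 = cnt[, 2L],
               n10 = cnt[, 3L], n11 = cnt[, 4L],
               N = as.integer(rowSums(cnt)))
}

## Vectorized CS over the rows of a pair-count table.
.csVec <- function(n1, n2, n3, N, maxCoverage, params) {
    MS <- .log2choose(N, n1) + .log2choose(N - n1, n2) +
        .nlog2p(n1, params@p1) + .nlog2p(n2, params@p2) +
        .nlog2p(n3, params@p3)
    FF <- 2 * .log2choose(N, N / 2) +
        .nlog2p(N / 2, params@p1) + .nlog2p(N / 2, params@p2)
    log2(stats::plogis(N / maxCoverage - 0.5)) + MS - FF
}

#' Score and classify all observed variant pairs of a block
#'
#' Builds the four-cell read-count table for every directly observed site
#' pair, computes the confidence scores of both candidate solutions, and
#' classifies each pair as normal, singleton or low-coverage. The maximum
#' coverage (largest pair read count) and the low-coverage threshold (the
#' median pair read count) are fixed once per block here and are not
#' updated during assembly.
#'
#' @param block A [VariantBlock-class].
#' @param params A [ScoringParams-class].
#' @param lowCovThreshold Optional override of the median-based threshold.
#' @param maxCoverage Optional override of the block maximum pair count.
#' @return A data.frame with columns \code{i}, \code{j} (local site
#'   indices, i < j), the four cells \code{n00..n11}, \code{N},
#'   \code{cs1}, \code{cs2}, \code{cs}, \code{solution}, \code{tied},
#'   \code{class}, \code{dist} (genomic distance) and \code{leftpos}.
#'   The threshold and maximum are attached as attributes
#'   \code{"lowCovThreshold"} and \code{"maxCoverage"}.
#' @examples
#' blk <- variantBlock(
#'     GenomicRanges::GRanges("chr", IRanges::IRanges(c(100, 200), width = 1)),
#'     fragmentSet("f1", list(1:2), list(c(0L, 1L))))
#' scorePairs(blk)
#' @export
scorePairs <- function(block, params = scoringParams(),
                       lowCovThreshold = NULL, maxCoverage = NULL) {
    n <- nSites(block)
    tbl <- .pairCounts(block@fragments, n)
    if (!nrow(tbl)) {
        attr(tbl, "lowCovThreshold") <- NA_real_
        attr(tbl, "maxCoverage") <- NA_real_
        return(tbl)
    }
    if (is.null(maxCoverage)) maxCoverage <- max(tbl$N)
    if (is.null(lowCovThreshold)) lowCovThreshold <- stats::median(tbl$N)
    tbl$cs1 <- .csVec(tbl$n00, tbl$n11, tbl$n01 + tbl$n10, tbl$N,
                      maxCoverage, params)
    tbl$cs2 <- .csVec(tbl$n01, tbl$n10, tbl$n00 + tbl$n11, tbl$N,
                      maxCoverage, params)
    tbl$cs <- pmax(tbl$cs1, tbl$cs2)
    tbl$solution <- ifelse(tbl$cs1 >= tbl$cs2, "S1", "S2")
    tbl$tied <- tbl$cs1 == tbl$cs2
    nonzero <- (tbl$n00 > 0L) + (tbl$n01 > 0L) + (tbl$n10 > 0L) +
        (tbl$n11 > 0L)
    tbl$class <- ifelse(nonzero == 1L, "singleton",
                 ifelse(tbl$N < lowCovThreshold, "low_coverage", "normal"))
    pos <- GenomicRanges::start(block@sites)
    tbl$dist <- pos[tbl$j] - pos[tbl$i]
    tbl$leftpos <- pos[tbl$i]
    attr(tbl, "lowCovThreshold") <- lowCovThreshold
    attr(tbl, "maxCoverage") <- maxCoverage
    tbl
}
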