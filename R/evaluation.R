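#' @include AllClasses.R local-mec.R
NULL

#' Switch/flip decomposition of phasing errors in one block
#'
#' Compares a predicted haplotype against the truth over the sites both
#' phase. Because the two haplotypes of a diploid block are complementary,
#' the comparison anchors at the first commonly phased site: the truth
#' haplotype matching the prediction there is taken as reference, and each
#' boundary between adjacent compared sites where agreement toggles is a
#' raw switch. Two adjacent raw switches flank a single isolated
#' mis-phased site and are collapsed into one flip error; remaining
#' toggles are switch errors. Runs of more than two adjacent toggles are
#' resolved by the minimum-cost pairing (maximal pairing of adjacent
#' boundaries, left to right). The result is invariant under global
#' complement of either input.
#'
#' @param pred,truth Haplotype 1 of prediction and truth over the same
#'   sites: 0/1 integer vectors with NA at unphased sites, or strings such
#'   as \code{"01-0"}.
#' @return A list: \code{switch}, \code{flip}, \code{compared} (indices of
#'   commonly phased sites), \code{switchBoundaries} (positions k of
#'   switch errors between compared sites k and k+1, used for QAN50
#'   splitting), and \code{uninformative} (TRUE when fewer than two sites
#'   could be compared; both counts are then zero).
#' @examples
#' countSwitchFlip("0100", "0000") # 1 flip
#' countSwitchFlip("0011", "0000") # 1 switch
#' countSwitchFlip("0110", "1001") # complement: no error
#' @export
countSwitchFlip <- function(pred, truth) {
    p <- .asHap(pred)
    t1 <- .asHap(truth)
    if (length(p) != length(t1))
        stop("pred and truth must cover the same sites")
    common <- which(!is.na(p) & !is.na(t1))
    if (length(common) < 2L)
        return(list(switch = 0L, flip = 0L, compared = common,
                    switchBoundaries = integer(0), uninformative = TRUE))
    tt <- if (t1[common[1L]] == p[common[1L]]) t1 else 1L - t1
    agree <- p[common] == tt[common]
    toggles <- which(agree[-1L] != agree[-length(agree)])
    sw <- 0L; fl <- 0L
    switchAt <- integer(0)
    if (length(toggles)) {
        runId <- cumsum(c(1L, diff(toggles) != 1L))
        for (r in split(toggles, runId)) {
            m <- length(r)
            fl <- fl + m %/% 2L
            if (m %% 2L) {
                sw <- sw + 1L
                switchAt <- c(switchAt, r[m]) # leftover of greedy pairing
            }
        }
    }
    list(switch = sw, flip = fl, compared = common,
         switchBoundaries = switchAt, uninformative = FALSE)
}

#' Pooled phasing error rate
#'
#' Total switch plus flip errors over the total number of phased variants,
#' pooled across a set of blocks ("cases").
#'
#' @param reports A data.frame with columns \code{flip}, \code{switch} and
#'   \code{nPhased} (phased variants per block, i.e. phasing decisions
#'   made).
#' @return The pooled rate in \[0, 1\], or `NA` when nothing was phased.
#' @examples
#' phasingErrorRate(data.frame(flip = 1, switch = 1, nPhased = 8)) # 0.25
#' @export
phasingErrorRate <- function(reports) {
    tot <- sum(reports$nPhased)
    if (!isTRUE(tot > 0)) return(NA_real_)
    (sum(reports$flip) + sum(reports$switch)) / tot
}

#' Perfect ratio over phasing cases
#'
#' Fraction of blocks phased without any switch or flip error (the
#' true-positive rate over cases).
#'
#' @inheritParams phasingErrorRate
#' @return The ratio in \[0, 1\], or `NA` for an empty case set.
#' @examples
#' perfectRatio(data.frame(flip = c(0, 1, 0, 0), switch = 0,
#'                         nPhased = 5)) # 0.75
#' @export
perfectRatio <- function(reports) {
    if (!nrow(reports)) return(NA_real_)
    sum(reports$flip + reports$switch == 0) / nrow(reports)
}

## Quality-adjusted sub-block spans of one block: split the block's sites
## at switch errors, take each sub-block's first-to-last phased distance,
## and weight it by the proportion of phased variants inside.
.qan50Spans <- function(pos, phased, cmp) {
    n <- length(pos)
    cut <- integer(0)
    if (length(cmp$switchBoundaries)) {
        ## boundary k separates compared sites k and k+1; split the full
        ## site list between those two sites
        cut <- cmp$compared[cmp$switchBoundaries]
    }
    bounds <- c(0L, cut, n)
    spans <- numeric(0)
    for (b in seq_len(length(bounds) - 1L)) {
        idx <- (bounds[b] + 1L):bounds[b + 1L]
        ph <- idx[phased[idx]]
        span <- if (length(ph) >= 2L) pos[max(ph)] - pos[min(ph)] else 0
        spans <- c(spans, span * sum(phased[idx]) / length(idx))
    }
    spans
}

#' Quality-adjusted N50 of error-free haplotype stretches
#'
#' Each block is broken into the longest sub-blocks containing no switch
#' error; each sub-block contributes its genomic span (first to last
#' phased variant) multiplied by the proportion of phased variants it
#' contains; QAN50 is the N50 of these adjusted spans (the largest span
#' at which the descending cumulative sum reaches half the total).
#'
#' @param spans Numeric vector of adjusted sub-block spans in bp, e.g.
#'   pooled from the \code{qan50Spans} column of [evaluatePhasing()]
#'   results.
#' @return QAN50 in bp (0 for an empty set).
#' @examples
#' qan50(c(200, 100)) # 200
#' @export
qan50 <- function(spans) {
    spans <- spans[spans > 0]
    if (!length(spans)) return(0)
    s <- sort(spans, decreasing = TRUE)
    s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Error-correction rate of a solution on a block's fragments
#'
#' The number of fragment characters that must be corrected for every
#' fragment to be consistent with one of the two complementary haplotypes,
#' divided by the total number of informative fragment characters in the
#' block.
#'
#' @param fragments The block's [FragmentSet-class] (local site indices).
#' @param hap1 0/1 integer vector (or string) over the block's sites.
#' @return The EC rate in \[0, 1\], or `NA` with no characters.
#' @examples
#' fr <- fragmentSet(letters[1:4], rep(list(1:2), 4),
#'                   list(c(0L,0L), c(0L,0L), c(0L,0L), c(0L,1L)))
#' ecRate(fr, c(0L, 0L)) # 1/8
#' @export
ecRate <- function(fragments, hap1) {
    hap1 <- .asHap(hap1)
    denom <- sum(lengths(fragments@sites))
    if (!denom) return(NA_real_)
    candidatePenalty(fragments, hap1, seq_along(hap1)) / denom
}

#' Evaluate predicted phasings against truth haplotypes
#'
#' Computes the per-block switch/flip decomposition and derives the
#' aggregate metric suite: pooled phasing error rate, perfect ratio and
#' QAN50. Sites phased by only one side are excluded from comparison and
#' count as unphased for QAN50's phased proportion. Per block,
#' \code{nDecisions} is the number of variants needing phase (all sites
#' but the leftmost) and \code{nPhased} the phasing decisions actually
#' compared.
#'
#' @param predictions List of [PhasedBlock-class] objects, or of lists
#'   with elements \code{pos} (positions) and \code{hap1} (0/1/NA).
#' @param truths Parallel list of truth haplotypes: 0/1/NA vectors or
#'   strings over the same sites as each prediction.
#' @return A list with \code{perBlock} (data.frame: nSites, nDecisions,
#'   nPhased, switch, flip, errorFree, ecRate where fragments are
#'   available) and \code{metrics} (phasingErrorRate, perfectRatio,
#'   qan50).
#' @export
evaluatePhasing <- function(predictions, truths) {
    stopifnot(length(predictions) == length(truths))
    rows <- vector("list", length(predictions))
    spans <- vector("list", length(predictions))
    for (k in seq_along(predictions)) {
        pb <- predictions[[k]]
        if (is(pb, "PhasedBlock")) {
            pos <- GenomicRanges::start(blockSites(pb))
            hp <- ifelse(phasedSites(pb), pb@hap1, NA_integer_)
            ec <- ecRate(blockFragments(pb), pb@hap1)
        } else {
            pos <- pb$pos
            hp <- .asHap(pb$hap1)
            ec <- NA_real_
        }
        ht <- .asHap(truths[[k]])
        cmp <- countSwitchFlip(hp, ht)
        phasedBoth <- !is.na(hp) & !is.na(ht)
        spans[[k]] <- .qan50Spans(pos, phasedBoth, cmp)
        rows[[k]] <- data.frame(
            block = k, nSites = length(pos),
            nDecisions = max(length(pos) - 1L, 0L),
            nPhased = max(length(cmp$compared) - 1L, 0L),
            switch = cmp$switch, flip = cmp$flip,
            errorFree = cmp$switch + cmp$flip == 0L,
            uninformative = cmp$uninformative, ecRate = ec)
    }
    perBlock <- do.call(rbind, rows)
    list(perBlock = perBlock,
         qan50Spans = spans,
         metrics = list(
             phasingErrorRate = phasingErrorRate(perBlock),
             perfectRatio = perfectRatio(perBlock),
             qan50 = qan50(unlist(spans))))
}
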