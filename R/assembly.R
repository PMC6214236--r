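#' @include AllClasses.R scoring.R local-mec.R
NULL

#' Count junctions between two clusters of variant sites
#'
#' A junction is a boundary between two position-adjacent variants that
#' belong to different clusters, counted over the position-sorted union of
#' the two clusters' sites. Two non-interleaved clusters meet at exactly
#' one junction; interleaved ("embedded") merges produce more.
#'
#' @param x,y Genomic positions (or any ordering coordinate) of the sites
#'   of the two clusters.
#' @return Integer junction count.
#' @examples
#' countJunctions(c(100, 300, 500), c(200, 400)) # 4
#' countJunctions(c(100, 200), c(300, 400))      # 1
#' @export
countJunctions <- function(x, y) {
    memb <- c(rep(0L, length(x)), rep(1L, length(y)))[order(c(x, y))]
    sum(diff(memb) != 0L)
}

#' Single-linkage score between two clusters
#'
#' The score between clusters X and Y is the maximum pair confidence score
#' over all directly observed variant pairs with one site in each cluster;
#' pairs never covered by a common fragment are not scored.
#'
#' @param pairTable Scored pair table from [scorePairs()].
#' @param X,Y Disjoint local site-index vectors.
#' @return A list: \code{score} (NA when no direct pair exists),
#'   \code{pair} (length-2 site indices of the argmax, or NULL).
#' @examples
#' blk <- variantBlock(
#'     GenomicRanges::GRanges("chr", IRanges::IRanges(c(1, 2, 3) * 100, width = 1)),
#'     fragmentSet(c("a", "b"), list(1:2, 2:3), list(c(0L, 0L), c(0L, 0L))))
#' clusterScore(scorePairs(blk), 1L, c(2L, 3L))
#' @export
clusterScore <- function(pairTable, X, Y) {
    cross <- (pairTable$i %in% X & pairTable$j %in% Y) |
             (pairTable$i %in% Y & pairTable$j %in% X)
    if (!any(cross)) return(list(score = NA_real_, pair = NULL))
    sub <- pairTable[cross, , drop = FALSE]
    best <- which.max(sub$cs)
    list(score = sub$cs[best], pair = c(sub$i[best], sub$j[best]))
}

## Pick the next merge: highest-CS cross-cluster pair among normal pairs;
## when only ambiguous pairs remain across every cluster boundary,
## singleton-led merges take precedence over low-coverage ones. Ties are
## broken by smaller genomic distance, then leftmost position, then site
## indices (determinism).
.selectNextMerge <- function(pairTable, clusterOf) {
    cross <- clusterOf[pairTable$i] != clusterOf[pairTable$j]
    stopifnot(any(cross)) # guaranteed in a connected block
    sub <- pairTable[cross, , drop = FALSE]
    for (cls in c("normal", "singleton", "low_coverage")) {
        cand <- sub[sub$class == cls, , drop = FALSE]
        if (nrow(cand)) {
            o <- order(-cand$cs, cand$dist, cand$leftpos, cand$i, cand$j)
            return(cand[o[1L], , drop = FALSE])
        }
    }
}

#' Phase a variant block by hierarchical assembly
#'
#' Starting from one cluster per site, repeatedly merges the two clusters
#' linked by the most confident directly observed variant pair
#' (single-linkage over pair confidence scores) until one cluster remains
#' -- exactly n-1 merges for an n-site block. At each merge the two
#' candidate joinings of the cluster sub-haplotypes (cis and trans) are
#' scored on the relabeled four-cell table of the leading pair and the
#' higher score wins. Three situations fall back to a local MEC vote
#' instead of the score-guided choice: (1) an embedded merge with at
#' least \code{minJunctions} junctions; (2) a merge led by an ambiguous
#' (singleton or low-coverage) pair with at least two junctions; (3) an
#' exact score tie. Ambiguous-pair-led merges only occur once no normal
#' pair remains across any cluster boundary, singletons before
#' low-coverage pairs.
#'
#' @param block A connected [VariantBlock-class] with at least 2 sites.
#' @param params A [ScoringParams-class].
#' @param minJunctions Junction count from which an embedded merge
#'   triggers the local MEC search (default 3).
#' @param lowCovThreshold Optional override of the block's median-based
#'   low-coverage threshold.
#' @return A [PhasedBlock-class]; its merge log records every decision.
#'   The returned haplotype is canonicalized so that \code{hap1} starts
#'   with allele 0.
#' @examples
#' blk <- variantBlock(
#'     GenomicRanges::GRanges("chr", IRanges::IRanges(c(1:3) * 100, width = 1)),
#'     fragmentSet(c("a", "b", "c"), list(1:2, 2:3, 1:3),
#'                 list(c(0L, 0L), c(0L, 0L), c(1L, 1L, 1L))))
#' haplotypes(assembleBlock(blk))
#' @export
assembleBlock <- function(block, params = scoringParams(),
                          minJunctions = 3L, lowCovThreshold = NULL) {
    n <- nSites(block)
    if (n < 2L)
        stop("assembleBlock needs a block with at least two sites")
    pt <- scorePairs(block, params, lowCovThreshold = lowCovThreshold)
    maxCov <- attr(pt, "maxCoverage")
    ## hot loop works on plain vectors; the data.frame is never touched
    ## again after this point
    pi <- pt$i; pj <- pt$j; pcs <- pt$cs; pN <- pt$N
    pdist <- pt$dist; pleft <- pt$leftpos
    classes <- c("normal", "singleton", "low_coverage")
    pclass <- match(pt$class, classes)
    cells <- cbind(pt$n00, pt$n01, pt$n10, pt$n11)
    pos <- GenomicRanges::start(block@sites)
    fs <- block@fragments@sites
    fa <- block@fragments@alleles
    clusterOf <- seq_len(n)
    hap <- integer(n)
    m <- n - 1L
    Lx <- Ly <- Ljun <- integer(m)
    Lclass <- Lmech <- character(m)
    Lcs <- Lcs1 <- Lcs2 <- numeric(m)
    Lp1 <- Lp2 <- rep(NA_integer_, m)
    Lflip <- Llow <- logical(m)

    for (step in seq_len(m)) {
        cross <- clusterOf[pi] != clusterOf[pj]
        sel <- 0L
        for (cl in 1:3) {
            cand <- which(cross & pclass == cl)
            if (length(cand)) {
                sel <- cand[order(-pcs[cand], pdist[cand], pleft[cand],
                                  pi[cand], pj[cand])[1L]]
                break
            }
        }
        stopifnot(sel > 0L) # guaranteed in a connected block
        x <- pi[sel]; y <- pj[sel]
        cx <- clusterOf[x]; cy <- clusterOf[y]
        Y <- which(clusterOf == cy)
        junc <- countJunctions(pos[clusterOf == cx], pos[Y])
        hx <- hap[x]; hy <- hap[y]
        cell <- function(a, b) cells[sel, 1L + 2L * a + b]
        h11 <- cell(hx, hy);          h22 <- cell(1L - hx, 1L - hy)
        h12 <- cell(hx, 1L - hy);     h21 <- cell(1L - hx, hy)
        cs1 <- .csVec(h11, h22, h12 + h21, pN[sel], maxCov, params)
        cs2 <- .csVec(h12, h21, h11 + h22, pN[sel], maxCov, params)

        mechanism <- "cs"
        vote <- NULL
        if (junc >= minJunctions) {
            mechanism <- "mec_junction"
            vote <- .voteMEC(fs, fa, clusterOf, cx, cy, hap, "junctions")
        } else if (pclass[sel] != 1L && junc >= 2L) {
            mechanism <- "mec_ambiguous"
            vote <- .voteMEC(fs, fa, clusterOf, cx, cy, hap, "block")
        } else if (cs1 == cs2) {
            mechanism <- "mec_tie"
            vote <- .voteMEC(fs, fa, clusterOf, cx, cy, hap, "junctions")
        }
        lowConf <- FALSE
        if (is.null(vote)) {
            flip <- cs2 > cs1
        } else if (vote$noVotes) {
            flip <- cs2 > cs1
            lowConf <- TRUE
        } else {
            flip <- vote$p2 < vote$p1
            Lp1[step] <- vote$p1; Lp2[step] <- vote$p2
            lowConf <- vote$p1 == vote$p2
        }
        if (flip) hap[Y] <- 1L - hap[Y]
        clusterOf[Y] <- cx
        Lx[step] <- x; Ly[step] <- y
        Lclass[step] <- classes[pclass[sel]]
        Lcs[step] <- pcs[sel]; Ljun[step] <- junc
        Lmech[step] <- mechanism
        Lcs1[step] <- cs1; Lcs2[step] <- cs2
        Lflip[step] <- flip; Llow[step] <- lowConf
    }
    if (hap[1L] == 1L) hap <- 1L - hap  # canonical orientation
    new("PhasedBlock", block = block, hap1 = hap,
        phased = rep(TRUE, n),
        mergeLog = data.frame(
            step = seq_len(m), siteX = Lx, siteY = Ly,
            pairClass = Lclass, pairCS = Lcs, junctions = Ljun,
            mechanism = Lmech, cs1 = Lcs1, cs2 = Lcs2,
            penaltyS1 = Lp1, penaltyS2 = Lp2, flipped = Lflip,
            lowConfidence = Llow))
}

## Two-candidate MEC vote on the raw fragment lists; mirrors
## localMECSelect but avoids any S4 copying inside the merge loop.
.voteMEC <- function(fs, fa, clusterOf, cx, cy, hap, scope) {
    p1 <- p2 <- 0L
    voted <- FALSE
    for (k in seq_along(fs)) {
        s <- fs[[k]]
        cOf <- clusterOf[s]
        inX <- cOf == cx
        inY <- cOf == cy
        recruit <- if (scope == "junctions") any(inX) && any(inY)
                   else any(inX) || any(inY)
        if (!recruit) next
        keep <- inX | inY
        if (!any(keep)) next
        voted <- TRUE
        a <- fa[[k]][keep]
        hh <- hap[s[keep]]
        len <- length(a)
        m1 <- sum(a != hh)
        hh2 <- ifelse(inY[keep], 1L - hh, hh)
        m2 <- sum(a != hh2)
        p1 <- p1 + min(m1, len - m1)
        p2 <- p2 + min(m2, len - m2)
    }
    if (!voted) return(list(noVotes = TRUE))
    list(noVotes = FALSE, p1 = p1, p2 = p2)
}

#' Write a merge log as a tab-separated audit file
#'
#' @param phased A [PhasedBlock-class] or a list of them.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
writeMergeLog <- function(phased, file) {
    if (is(phased, "PhasedBlock")) phased <- list(phased)
    logs <- lapply(seq_along(phased), function(k) {
        ml <- mergeLog(phased[[k]])
        if (is.null(ml) || !nrow(ml)) return(NULL)
        cbind(block = k, ml)
    })
    tab <- do.call(rbind, logs)
    utils::write.table(tab, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}
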