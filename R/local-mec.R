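#' @include AllClasses.R
NULL

#' Correction penalty of fragments against a candidate haplotype pair
#'
#' For each fragment restricted to the candidate's sites, the penalty is
#' the minimum number of allele corrections needed to make it consistent
#' with either haplotype; since the two haplotypes are complementary this
#' is \code{min(m, k - m)} where \code{m} is the number of mismatches
#' against \code{hap1} over the fragment's \code{k} informative entries on
#' those sites. Fragments with no entry on the sites contribute nothing.
#'
#' @param fragments A [FragmentSet-class] (site indices in the same space
#'   as \code{sites}).
#' @param hap1 Integer 0/1 vector, the first haplotype of the candidate;
#'   the second is its complement.
#' @param sites Site indices the candidate covers, parallel to
#'   \code{hap1}. Defaults to \code{seq_along(hap1)}.
#' @return Total penalty (integer).
#' @examples
#' fr <- fragmentSet(c("a", "b", "c"), list(1:2, 1:2, 1:2),
#'                   list(c(0L, 1L), c(0L, 1L), c(0L, 0L)))
#' candidatePenalty(fr, c(0L, 0L)) # 2
#' candidatePenalty(fr, c(0L, 1L)) # 1
#' @export
candidatePenalty <- function(fragments, hap1, sites = seq_along(hap1)) {
    stopifnot(length(hap1) == length(sites))
    hapAt <- integer(0)
    hapAt[sites] <- as.integer(hap1)
    total <- 0L
    for (k in seq_along(fragments@sites)) {
        s <- fragments@sites[[k]]
        keep <- s %in% sites
        if (!any(keep)) next
        a <- fragments@alleles[[k]][keep]
        m <- sum(a != hapAt[s[keep]])
        total <- total + min(m, length(a) - m)
    }
    total
}

#' Local MEC vote between the two candidate merges of two clusters
#'
#' When two phased clusters X and Y are merged there are exactly two
#' candidate joint solutions: keep both cluster labelings (S1), or swap
#' Y's two haplotypes (S2). Every recruited fragment votes by its
#' correction penalty against each candidate, and the candidate with the
#' lower total penalty wins. With scope \code{"junctions"} only fragments
#' informative for the merge -- those covering at least one site of each
#' cluster, hence spanning a junction of the interleaving -- are
#' recruited; scope \code{"block"} recruits every fragment touching the
#' merged region.
#'
#' @param X,Y Disjoint site-index vectors of the two clusters.
#' @param hapX,hapY 0/1 vectors: haplotype 1 of each cluster over its
#'   sites.
#' @param fragments A [FragmentSet-class] over the same site-index space.
#' @param scope Fragment recruitment rule, see Details.
#' @return A list: \code{solution} ("S1" or "S2"), \code{penalty} (named
#'   length-2 vector), \code{tied}, \code{noVotes} (TRUE when no fragment
#'   qualified, in which case S1 is returned flagged and the caller should
#'   fall back to score-guided choice), and \code{flip} (TRUE when Y must
#'   be complemented).
#' @examples
#' fr <- fragmentSet(c("a", "b", "c"), list(1:2, 1:2, 1:2),
#'                   list(c(0L, 1L), c(0L, 1L), c(0L, 0L)))
#' localMECSelect(1L, 2L, 0L, 0L, fr)$solution # "S2"
#' @export
localMECSelect <- function(X, Y, hapX, hapY, fragments,
                           scope = c("junctions", "block")) {
    scope <- match.arg(scope)
    stopifnot(length(X) == length(hapX), length(Y) == length(hapY),
              !any(X %in% Y))
    keep <- vapply(fragments@sites, function(s) {
        if (scope == "junctions") any(s %in% X) && any(s %in% Y)
        else any(s %in% X) || any(s %in% Y)
    }, logical(1L))
    sites <- c(X, Y)
    s1 <- c(as.integer(hapX), as.integer(hapY))
    s2 <- c(as.integer(hapX), 1L - as.integer(hapY))
    if (!any(keep))
        return(list(solution = "S1", penalty = c(S1 = NA_integer_,
                    S2 = NA_integer_), tied = FALSE, noVotes = TRUE,
                    flip = FALSE))
    rec <- fragments[which(keep)]
    p1 <- candidatePenalty(rec, s1, sites)
    p2 <- candidatePenalty(rec, s2, sites)
    tied <- p1 == p2
    sol <- if (p2 < p1) "S2" else "S1"
    list(solution = sol, penalty = c(S1 = p1, S2 = p2), tied = tied,
         noVotes = FALSE, flip = sol == "S2")
}

#' Exhaustive minimum-error-correction solver (test oracle)
#'
#' Enumerates every haplotype assignment of a small block (up to global
#' complement, i.e. \eqn{2^{n-1}} candidates) and returns the one
#' minimizing the total correction penalty over all fragments. This is the
#' global MEC optimum and serves as an independent oracle for the
#' assembly algorithm in tests and analyses; it is not part of the phasing
#' path and refuses blocks with more than 16 sites.
#'
#' @param x A [VariantBlock-class], or a [FragmentSet-class] (then `n`
#'   must be given).
#' @param n Number of sites when `x` is a `FragmentSet`.
#' @return A list: \code{hap1} (0/1 vector, first allele fixed to 0),
#'   \code{minCorrections}, and \code{optima} (the number of distinct
#'   optimal assignments, 1 when the optimum is unique).
#' @examples
#' fr <- fragmentSet(c("a", "b"), list(1:2, 2:3),
#'                   list(c(0L, 0L), c(0L, 0L)))
#' bruteForceMEC(fr, n = 3)$minCorrections # 0
#' @export
bruteForceMEC <- function(x, n = NULL) {
    if (is(x, "VariantBlock")) {
        n <- nSites(x)
        fragments <- x@fragments
    } else {
        fragments <- x
        if (is.null(n)) stop("n must be given with a FragmentSet")
    }
    if (n > 16L)
        stop("bruteForceMEC enumerates 2^(n-1) assignments; n must be <= 16")
    if (n < 1L) stop("empty block")
    ncand <- 2L^(n - 1L)
    ## candidate haplotypes as a ncand x n matrix; first site fixed at 0
    H <- matrix(0L, nrow = ncand, ncol = n)
    if (n > 1L)
        for (b in seq_len(n - 1L))
            H[, b + 1L] <- as.integer(bitwAnd(seq_len(ncand) - 1L,
                                              bitwShiftL(1L, b - 1L)) > 0L)
    pen <- numeric(ncand)
    for (k in seq_along(fragments@sites)) {
        s <- fragments@sites[[k]]
        a <- fragments@alleles[[k]]
        m <- rowSums(H[, s, drop = FALSE] !=
                     matrix(a, ncand, length(a), byrow = TRUE))
        pen <- pen + pmin(m, length(a) - m)
    }
    best <- which.min(pen)
    list(hap1 = H[best, ], minCorrections = as.integer(min(pen)),
         optima = sum(pen == min(pen)))
}
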