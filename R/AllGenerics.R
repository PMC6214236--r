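#' @include AllClasses.R
NULL

#' Accessors for HierPhase objects
#'
#' Small accessor generics: \code{obsCounts} returns the named four-cell
#' read-count vector of a [PairObservation-class]; \code{totalReads} its
#' sum; \code{nSites} the number of variant sites of a block;
#' \code{blockSites} / \code{blockFragments} the site `GRanges` and
#' [FragmentSet-class] of a [VariantBlock-class]; \code{haplotypes} the two
#' complementary haplotype strings of a [PhasedBlock-class];
#' \code{phasedSites} its per-site phased flags; and \code{mergeLog} the
#' assembly audit table.
#'
#' @param x An object.
#' @return See details per accessor.
#' @name accessors
#' @aliases obsCounts totalReads nSites blockSites blockFragments
#'   haplotypes phasedSites mergeLog
#' @examples
#' obsCounts(pairObservation(10, 1, 0, 9))
NULL

#' @rdname accessors
#' @export
setGeneric("obsCounts", function(x) standardGeneric("obsCounts"))

#' @rdname accessors
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname accessors
#' @export
setGeneric("blockSites", function(x) standardGeneric("blockSites"))

#' @rdname accessors
#' @export
setGeneric("blockFragments", function(x) standardGeneric("blockFragments"))

#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @rdname accessors
#' @export
setGeneric("phasedSites", function(x) standardGeneric("phasedSites"))

#' @rdname accessors
#' @export
setGeneric("mergeLog", function(x) standardGeneric("mergeLog"))

#' @rdname accessors
#' @export
setMethod("obsCounts", "PairObservation", function(x) x@rc)

#' @rdname accessors
#' @export
setMethod("totalReads", "PairObservation", function(x) sum(x@rc))

#' @rdname accessors
#' @export
setMethod("nSites", "VariantBlock", function(x) length(x@sites))

#' @rdname accessors
#' @export
setMethod("nSites", "PhasedBlock", function(x) length(x@block@sites))

#' @rdname accessors
#' @export
setMethod("blockSites", "VariantBlock", function(x) x@sites)

#' @rdname accessors
#' @export
setMethod("blockSites", "PhasedBlock", function(x) x@block@sites)

#' @rdname accessors
#' @export
setMethod("blockFragments", "VariantBlock", function(x) x@fragments)

#' @rdname accessors
#' @export
setMethod("blockFragments", "PhasedBlock", function(x) x@block@fragments)

#' @rdname accessors
#' @export
setMethod("haplotypes", "PhasedBlock", function(x) {
    h1 <- ifelse(x@phased, as.character(x@hap1), "-")
    h2 <- ifelse(x@phased, as.character(1L - x@hap1), "-")
    c(hap1 = paste(h1, collapse = ""), hap2 = paste(h2, collapse = ""))
})

#' @rdname accessors
#' @export
setMethod("phasedSites", "PhasedBlock", function(x) x@phased)

#' @rdname accessors
#' @export
setMethod("mergeLog", "PhasedBlock", function(x) x@mergeLog)

#' @describeIn FragmentSet-class Number of fragments.
#' @param x A `FragmentSet`.
#' @export
setMethod("length", "FragmentSet", function(x) length(x@name))

#' @describeIn FragmentSet-class Subset fragments.
#' @param i Index vector.
#' @param j,drop Ignored.
#' @param ... Ignored.
#' @export
setMethod("[", "FragmentSet", function(x, i, j, ..., drop = TRUE) {
    new("FragmentSet", name = x@name[i], chrom = x@chrom[i],
        sites = x@sites[i], alleles = x@alleles[i])
})

#' @describeIn FragmentSet-class Fragment names.
#' @export
setMethod("names", "FragmentSet", function(x) x@name)

setMethod("show", "ScoringParams", function(object) {
    cat(sprintf("ScoringParams: P1=%.4g P2=%.4g P3=%.4g\n",
                object@p1, object@p2, object@p3))
})

setMethod("show", "PairObservation", function(object) {
    rc <- object@rc
    cat(sprintf(
        "PairObservation: 00=%d 01=%d 10=%d 11=%d (N=%d)\n",
        rc[1L], rc[2L], rc[3L], rc[4L], sum(rc)))
})

setMethod("show", "FragmentSet", function(object) {
    n <- length(object@name)
    cat(sprintf("FragmentSet with %d fragment%s over %d chromosome%s\n",
                n, if (n == 1L) "" else "s",
                length(unique(object@chrom)),
                if (length(unique(object@chrom)) == 1L) "" else "s"))
    if (n) {
        k <- min(n, 3L)
        for (f in seq_len(k))
            cat(sprintf("  %s [%s] sites %d..%d (%d informative)\n",
                        object@name[f], object@chrom[f],
                        min(object@sites[[f]]), max(object@sites[[f]]),
                        length(object@sites[[f]])))
        if (n > k) cat(sprintf("  ... and %d more\n", n - k))
    }
})

setMethod("show", "VariantBlock", function(object) {
    cat(sprintf(
        "VariantBlock: %d sites on %s (%d..%d), %d informative fragments\n",
        length(object@sites),
        as.character(GenomicRanges::seqnames(object@sites)[1L]),
        min(GenomicRanges::start(object@sites)),
        max(GenomicRanges::start(object@sites)),
        length(object@fragments)))
})

setMethod("show", "PhasedBlock", function(object) {
    h <- haplotypes(object)
    trunc <- function(s) if (nchar(s) > 40L) paste0(substr(s, 1L, 40L), "...") else s
    cat(sprintf("PhasedBlock: %d sites, %d phased\n",
                length(object@hap1), sum(object@phased)))
    cat("  hap1: ", trunc(h[["hap1"]]), "\n  hap2: ", trunc(h[["hap2"]]),
        "\n", sep = "")
    mech <- table(object@mergeLog$mechanism)
    if (length(mech))
        cat("  merges: ",
            paste(sprintf("%s=%d", names(mech), as.integer(mech)),
                  collapse = ", "), "\n", sep = "")
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(
        paste0("SimConfig: blocks %s x%d, coverage %g, seqError %g, ",
               "skew %g/%g, reads 2x%g insert %g+/-%g (%s errors)\n"),
        paste(object@blockSizes, collapse = "/"), object@blocksPerSize,
        object@coverage, object@seqError, 100 * object@skew,
        100 * (1 - object@skew), object@readLen, object@insertMean,
        object@insertSd, object@errorMode))
})
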