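#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
NULL

#' Multinomial scoring parameters
#'
#' Container for the three outcome likelihoods of the confidence-score
#' model: \code{p1} and \code{p2} are the likelihoods of observing a read
#' from either haplotype of a diploid individual, and \code{p3} absorbs
#' unexpected observations (sequencing or alignment error). The three must
#' sum to one.
#'
#' @slot p1 Likelihood of a read drawn from the first haplotype.
#' @slot p2 Likelihood of a read drawn from the second haplotype.
#' @slot p3 Likelihood of an unexpected observation.
#'
#' @seealso [scoringParams()], [multinomialScore()], [pairCS()]
#' @export
setClass("ScoringParams",
    representation(p1 = "numeric", p2 = "numeric", p3 = "numeric"))

setValidity("ScoringParams", function(object) {
    p <- c(object@p1, object@p2, object@p3)
    if (length(p) != 3L || anyNA(p))
        return("p1, p2, p3 must be single non-missing numbers")
    if (any(p < 0) || any(p > 1))
        return("likelihoods must lie in [0, 1]")
    if (abs(sum(p) - 1) > 1e-8)
        return("p1 + p2 + p3 must equal 1")
    TRUE
})

#' Create scoring parameters
#'
#' @param p1,p2 Haplotype observation likelihoods (default 0.49 each, the
#'   recommended setting for diploid short-read data).
#' @param p3 Error likelihood; defaults to \code{1 - p1 - p2}.
#' @return A [ScoringParams-class] object.
#' @examples
#' scoringParams()
#' scoringParams(0.45, 0.45)
#' @export
scoringParams <- function(p1 = 0.49, p2 = 0.49, p3 = NULL) {
    if (is.null(p3)) p3 <- 1 - p1 - p2
    new("ScoringParams", p1 = p1, p2 = p2, p3 = p3)
}

#' Read counts over the four allele combinations of a variant pair
#'
#' For two bi-allelic heterozygous variants, every informative read falls
#' into one of four cells according to the alleles it carries: 0-0, 0-1,
#' 1-0 or 1-1 (0 = reference allele, 1 = alternative allele).
#'
#' @slot rc Integer vector of length four, named
#'   \code{c("rc00","rc01","rc10","rc11")}.
#' @seealso [pairObservation()], [pairCS()], [classifyPair()]
#' @export
setClass("PairObservation", representation(rc = "integer"))

setValidity("PairObservation", function(object) {
    if (length(object@rc) != 4L || anyNA(object@rc))
        return("rc must hold four non-missing counts")
    if (any(object@rc < 0L))
        return("read counts must be non-negative")
    TRUE
})

#' Create a pair observation
#'
#' @param rc00,rc01,rc10,rc11 Read counts of the four allele combinations.
#' @return A [PairObservation-class].
#' @examples
#' pairObservation(10, 1, 0, 9)
#' @export
pairObservation <- function(rc00, rc01, rc10, rc11) {
    new("PairObservation", rc = as.integer(
        c(rc00 = rc00, rc01 = rc01, rc10 = rc10, rc11 = rc11)))
}

#' Set of sequencing fragments encoded over variant sites
#'
#' A fragment is one sequencing unit (both mates of a read pair merged)
#' reduced to the alleles it carries at heterozygous variant sites. The
#' representation is sparse: only sites where the fragment shows the
#' reference (0) or alternative (1) allele are stored; any other base,
#' deletion or uncovered site is the implicit gap symbol \code{"-"}.
#'
#' @slot name Fragment (read pair) identifiers.
#' @slot chrom Chromosome each fragment belongs to.
#' @slot sites List of strictly increasing integer site indices (1-based
#'   ordinals within the chromosome's sorted site list).
#' @slot alleles List of 0/1 integer vectors parallel to \code{sites}.
#'
#' @seealso [fragmentSet()], [extractFragments()], [readFragmentFile()]
#' @export
setClass("FragmentSet",
    representation(name = "character", chrom = "character",
                   sites = "list", alleles = "list"))

setValidity("FragmentSet", function(object) {
    n <- length(object@name)
    if (length(object@chrom) != n || length(object@sites) != n ||
        length(object@alleles) != n)
        return("name, chrom, sites and alleles must have equal length")
    for (k in seq_len(n)) {
        s <- object@sites[[k]]; a <- object@alleles[[k]]
        if (length(s) != length(a))
            return(sprintf("fragment %d: sites/alleles length mismatch", k))
        if (length(s) < 1L)
            return(sprintf("fragment %d: no covered site", k))
        if (is.unsorted(s, strictly = TRUE))
            return(sprintf("fragment %d: site indices not strictly increasing", k))
        if (!all(a %in% c(0L, 1L)))
            return(sprintf("fragment %d: alleles outside {0,1}", k))
    }
    TRUE
})

#' Create a fragment set
#'
#' @param name Character vector of fragment names.
#' @param sites List of integer site-index vectors (1-based, strictly
#'   increasing within a fragment).
#' @param alleles List of 0/1 integer vectors parallel to \code{sites}.
#' @param chrom Chromosome name(s), recycled to the number of fragments.
#' @return A [FragmentSet-class].
#' @examples
#' fragmentSet(c("f1", "f2"), list(1:2, 2:3), list(c(0L, 0L), c(1L, 1L)))
#' @export
fragmentSet <- function(name, sites, alleles, chrom = "chr") {
    n <- length(name)
    sites <- lapply(sites, as.integer)
    alleles <- lapply(alleles, as.integer)
    new("FragmentSet", name = as.character(name),
        chrom = rep_len(as.character(chrom), n),
        sites = sites, alleles = alleles)
}

#' A connected block of heterozygous variants with its fragments
#'
#' The unit of phasing: a maximal set of variants in which every variant is
#' linked to the others (possibly transitively) by informative fragments,
#' i.e. fragments covering at least two of the block's sites. Fragment site
#' indices are local, 1 .. number of sites.
#'
#' @slot sites A [GenomicRanges::GRanges] of the block's variant sites,
#'   sorted by position, with optional \code{ref}/\code{alt} metadata.
#' @slot siteIndex Integer ordinals of these sites within the chromosome's
#'   full sorted site list.
#' @slot fragments A [FragmentSet-class] with local site indices; every
#'   fragment covers at least two block sites.
#'
#' @seealso [variantBlock()], [buildBlocks()], [assembleBlock()]
#' @export
setClass("VariantBlock",
    representation(sites = "GRanges", siteIndex = "integer",
                   fragments = "FragmentSet"))

setValidity("VariantBlock", function(object) {
    n <- length(object@sites)
    if (length(object@siteIndex) != n)
        return("siteIndex length must match number of sites")
    if (n > 1L && is.unsorted(GenomicRanges::start(object@sites)))
        return("sites must be sorted by position")
    fs <- object@fragments@sites
    if (length(fs)) {
        idx <- unlist(fs, use.names = FALSE)
        if (any(idx < 1L) || any(idx > n))
            return("fragment site indices outside block")
        if (any(lengths(fs) < 2L))
            return("every block fragment must cover at least two sites")
        # pair graph over sites must be connected
        comp <- .fragmentComponents(fs, n)
        if (length(unique(comp)) != 1L)
            return("block sites are not connected by its fragments")
    } else if (n > 1L) {
        return("multi-site block without fragments cannot be connected")
    }
    TRUE
})

#' Create a variant block
#'
#' @param sites `GRanges` of variant sites (sorted by position).
#' @param fragments [FragmentSet-class] with local (1-based) site indices
#'   into \code{sites}.
#' @param siteIndex Chromosome-level ordinals of the sites; defaults to
#'   \code{seq_along(sites)}.
#' @return A [VariantBlock-class].
#' @export
variantBlock <- function(sites, fragments, siteIndex = seq_along(sites)) {
    new("VariantBlock", sites = sites, siteIndex = as.integer(siteIndex),
        fragments = fragments)
}

#' Phased haplotypes over a variant block
#'
#' Result of assembling one block: two complementary haplotypes, given as
#' the allele vector of the first haplotype (the second is its bitwise
#' complement, by the heterozygous assumption), per-site phased flags, and
#' an audit log of every merge decision taken during assembly.
#'
#' @slot block The [VariantBlock-class] that was phased.
#' @slot hap1 Integer 0/1 vector over the block's sites.
#' @slot phased Logical per-site flags (sites left undecided are FALSE).
#' @slot mergeLog A data.frame with one row per merge: the leading pair,
#'   its class and confidence scores, junction count, the mechanism used
#'   (confidence-guided or local MEC) and penalties where applicable.
#'
#' @seealso [assembleBlock()], [haplotypes()], [mergeLog()]
#' @export
setClass("PhasedBlock",
    representation(block = "VariantBlock", hap1 = "integer",
                   phased = "logical", mergeLog = "data.frame"))

setValidity("PhasedBlock", function(object) {
    n <- length(object@block@sites)
    if (length(object@hap1) != n || length(object@phased) != n)
        return("hap1 and phased must match the number of block sites")
    if (!all(object@hap1[object@phased] %in% c(0L, 1L)))
        return("phased alleles must be 0 or 1")
    TRUE
})

#' Simulation configuration for diploid fragment generation
#'
#' Describes one simulated sequencing experiment: variant blocks of given
#' sizes, paired-end fragments sampled from two complementary haplotypes
#' with configurable mean per-site coverage, per-base sequencing error and
#' haplotype sampling skew.
#'
#' @slot blockSizes Variant counts per block (default 30/50/100/200/500).
#' @slot blocksPerSize Blocks simulated per size (default 10).
#' @slot regionSpan Span in bp per block; \code{NA} means 82 bp per
#'   variant, the density used throughout the package's benchmarks.
#' @slot coverage Mean sequencing coverage per site (default 30).
#' @slot seqError Per-base error probability at variant sites (default 0.01).
#' @slot skew Probability that a fragment originates from haplotype 1
#'   (0.5 = balanced, 0.1 = extreme 10/90 skew).
#' @slot readLen Read length in bp (default 250).
#' @slot insertMean,insertSd Insert size distribution (default 850 +/- 50).
#' @slot errorMode \code{"flip"} corrupts a site to the opposite allele;
#'   \code{"missing"} turns it into the gap symbol.
#'
#' @seealso [simConfig()], [simulateDataset()], [scenarioGrid()]
#' @export
setClass("SimConfig",
    representation(blockSizes = "numeric", blocksPerSize = "numeric",
                   regionSpan = "numeric", coverage = "numeric",
                   seqError = "numeric", skew = "numeric",
                   readLen = "numeric", insertMean = "numeric",
                   insertSd = "numeric", errorMode = "character"))

setValidity("SimConfig", function(object) {
    if (any(object@blockSizes < 2))
        return("block sizes must be at least 2")
    if (object@coverage <= 0) return("coverage must be positive")
    if (object@seqError < 0 || object@seqError > 1)
        return("seqError must be a probability")
    if (object@skew <= 0 || object@skew > 0.5)
        return("skew is the haplotype-1 sampling probability, in (0, 0.5]")
    if (!object@errorMode %in% c("flip", "missing"))
        return("errorMode must be 'flip' or 'missing'")
    if (object@readLen < 1 || object@insertMean < object@readLen)
        return("insertMean must be at least readLen")
    TRUE
})

#' Create a simulation configuration
#'
#' Defaults reproduce the benchmark design used throughout the package:
#' block sizes 30/50/100/200/500 with 10 blocks each, 2 x 250 bp read
#' pairs with insert 850 +/- 50 bp, coverage 30, sequencing error 0.01,
#' balanced haplotype sampling.
#'
#' @param blockSizes,blocksPerSize,regionSpan,coverage,seqError,skew,readLen,insertMean,insertSd,errorMode
#'   See [SimConfig-class].
#' @return A [SimConfig-class].
#' @examples
#' simConfig(blockSizes = 30, blocksPerSize = 2, coverage = 20)
#' @export
simConfig <- function(blockSizes = c(30, 50, 100, 200, 500),
                      blocksPerSize = 10, regionSpan = NA_real_,
                      coverage = 30, seqError = 0.01, skew = 0.5,
                      readLen = 250, insertMean = 850, insertSd = 50,
                      errorMode = c("flip", "missing")) {
    errorMode <- match.arg(errorMode)
    new("SimConfig", blockSizes = blockSizes, blocksPerSize = blocksPerSize,
        regionSpan = regionSpan, coverage = coverage, seqError = seqError,
        skew = skew, readLen = readLen, insertMean = insertMean,
        insertSd = insertSd, errorMode = errorMode)
}
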