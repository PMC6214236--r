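#' @include AllClasses.R
NULL

#' Simulate truth haplotypes over one variant block
#'
#' Samples \code{n} distinct variant positions uniformly over a genomic
#' span and a uniform random 0/1 allele per site for haplotype 1;
#' haplotype 2 is the complement. Uses the current RNG stream, so results
#' are reproducible after \code{set.seed()}.
#'
#' @param n Number of variant sites.
#' @param span Region span in bp (must be >= n).
#' @param chrom Contig name for the block.
#' @return A list: \code{chrom}, \code{pos} (sorted), \code{hap1}.
#' @examples
#' set.seed(1)
#' simulateTruth(30, 1e4)
#' @export
simulateTruth <- function(n, span, chrom = "sim1") {
    if (n > span)
        stop("cannot place ", n, " variants in a span of ", span, " bp")
    list(chrom = chrom, pos = sort(sample.int(span, n)),
         hap1 = sample(0:1, n, replace = TRUE))
}

#' Simulate paired-end diploid fragments over a block
#'
#' Emulates short-read sequencing of a diploid region directly at the
#' variant sites, without a reference genome or aligner. Each fragment is
#' a read pair: the insert length is Normal(insertMean, insertSd), the
#' start uniform over the (insert-extended) region, and the two reads
#' cover \code{readLen} bp at either end of the insert. The originating
#' haplotype is drawn with probability \code{skew} for haplotype 1. Each
#' variant site covered by a read copies the origin haplotype's allele
#' and is then corrupted with probability \code{seqError}: flipped to the
#' opposite allele (\code{errorMode = "flip"}, the worst case for
#' phasing) or dropped as the gap symbol (\code{"missing"}). Fragments
#' covering fewer than two sites are discarded, so the returned set is
#' haplotype-informative. Mapping error is deliberately not modelled.
#'
#' @param truth A list as returned by [simulateTruth()].
#' @param config A [SimConfig-class]; its coverage, seqError, skew, read
#'   geometry and errorMode fields are used.
#' @return A [FragmentSet-class] with local site indices 1..n.
#' @examples
#' set.seed(1)
#' tr <- simulateTruth(30, 2500)
#' simulateFragments(tr, simConfig(coverage = 30, seqError = 0))
#' @export
simulateFragments <- function(truth, config = simConfig()) {
    pos <- truth$pos
    n <- length(pos)
    span <- max(pos)
    readLen <- config@readLen
    insertMean <- config@insertMean
    nFrag <- max(1L, round(config@coverage * (span + insertMean) /
                           (2 * readLen)))
    starts <- sample.int(span + insertMean, nFrag, replace = TRUE) -
        insertMean
    inserts <- pmax(2 * readLen,
                    round(stats::rnorm(nFrag, insertMean, config@insertSd)))
    fromHap1 <- stats::runif(nFrag) < config@skew
    name <- sites <- alleles <- vector("list", nFrag)
    for (k in seq_len(nFrag)) {
        s <- starts[k]
        covered <- which((pos >= s & pos <= s + readLen - 1) |
                         (pos >= s + inserts[k] - readLen &
                          pos <= s + inserts[k] - 1))
        if (length(covered) < 2L) next
        a <- if (fromHap1[k]) truth$hap1[covered]
             else 1L - truth$hap1[covered]
        err <- stats::runif(length(covered)) < config@seqError
        if (config@errorMode == "flip") {
            a[err] <- 1L - a[err]
        } else if (any(err)) {
            covered <- covered[!err]
            a <- a[!err]
            if (length(covered) < 2L) next
        }
        name[[k]] <- sprintf("frag%06d", k)
        sites[[k]] <- covered
        alleles[[k]] <- a
    }
    keep <- !vapply(name, is.null, logical(1L))
    fragmentSet(unlist(name[keep]), sites[keep], alleles[keep],
                chrom = truth$chrom)
}

#' Simulate a full multi-block dataset
#'
#' Generates truth haplotypes and fragments for every block of the
#' configuration: \code{blocksPerSize} blocks for each entry of
#' \code{blockSizes}, each on its own contig so block discovery keeps
#' them apart. The per-block span is \code{regionSpan} when set, else
#' 82 bp per variant.
#'
#' @param config A [SimConfig-class].
#' @param seed Optional integer seed set before generation.
#' @return A list of blocks, each a list with \code{chrom}, \code{pos},
#'   \code{hap1} and \code{fragments} (a [FragmentSet-class]).
#' @examples
#' ds <- simulateDataset(simConfig(blockSizes = 30, blocksPerSize = 2),
#'                       seed = 1)
#' length(ds)
#' @export
simulateDataset <- function(config = simConfig(), seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    out <- list()
    b <- 0L
    for (sz in config@blockSizes) {
        span <- if (is.na(config@regionSpan)) 82 * sz else config@regionSpan
        for (r in seq_len(config@blocksPerSize)) {
            b <- b + 1L
            truth <- simulateTruth(sz, span, chrom = sprintf("block%03d", b))
            truth$fragments <- simulateFragments(truth, config)
            out[[b]] <- truth
        }
    }
    out
}

#' Reproducible grid of simulation scenarios
#'
#' Expands the benchmark grid -- by default 3 coverages x 3 sequencing
#' error rates x 5 skew levels = 45 conditions -- crossed with replicate
#' indices, and assigns each run a derived seed so every dataset is
#' reproducible from the single master seed. Materialize a row with
#' \code{simulateDataset(simConfig(coverage = row$coverage, ...),
#' seed = row$seed)}.
#'
#' @param coverages,seqErrors,skews Grid levels.
#' @param replicates Replicates per condition.
#' @param seed Master seed.
#' @return A data.frame with columns \code{coverage}, \code{seqError},
#'   \code{skew}, \code{replicate}, \code{seed}.
#' @examples
#' nrow(scenarioGrid(replicates = 1)) / 1 # 45 conditions
#' @export
scenarioGrid <- function(coverages = c(20, 30, 40),
                         seqErrors = c(0.002, 0.01, 0.03),
                         skews = c(0.5, 0.4, 0.3, 0.2, 0.1),
                         replicates = 1, seed = 1) {
    grid <- expand.grid(coverage = coverages, seqError = seqErrors,
                        skew = skews, replicate = seq_len(replicates),
                        KEEP.OUT.ATTRS = FALSE)
    grid$seed <- .deriveSeeds(seed, nrow(grid))
    grid
}
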