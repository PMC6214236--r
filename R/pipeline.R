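#' @include fragments-io.R assembly.R evaluation.R simulate.R
NULL

## Build a site GRanges for fragment-file input: positions from an
## optional sites TSV (chrom, pos[, ref, alt]) or unit-spaced indices.
.sitesForFragments <- function(fragments, sitesFile = NULL) {
    if (!is.null(sitesFile)) {
        tab <- utils::read.table(sitesFile, sep = "\t", header = TRUE)
        gr <- GenomicRanges::GRanges(tab$chrom,
            IRanges::IRanges(tab$pos, width = 1L))
        if (!is.null(tab$ref)) S4Vectors::mcols(gr)$ref <- tab$ref
        if (!is.null(tab$alt)) S4Vectors::mcols(gr)$alt <- tab$alt
    } else {
        chroms <- unique(fragments@chrom)
        grl <- lapply(chroms, function(ch) {
            n <- max(unlist(fragments@sites[fragments@chrom == ch]))
            GenomicRanges::GRanges(ch, IRanges::IRanges(seq_len(n),
                                                        width = 1L))
        })
        gr <- do.call(c, grl)
    }
    chroms <- as.character(GenomicRanges::seqnames(gr))
    gr <- gr[order(chroms, GenomicRanges::start(gr))]
    chroms <- as.character(GenomicRanges::seqnames(gr))
    S4Vectors::mcols(gr)$siteIndex <- if (length(gr))
        as.integer(stats::ave(seq_along(gr), chroms, FUN = seq_along))
    else integer(0)
    gr
}

#' Phase a sample end to end
#'
#' Full phasing pipeline: read heterozygous bi-allelic SNPs and
#' informative fragments (from a VCF + indexed BAM, or from a plain-text
#' fragment file), partition the variants into connected blocks, phase
#' every block by hierarchical assembly, and write the results.
#'
#' With VCF input a phased VCF (\code{<out>.phased.vcf}) is written; in
#' all cases a haplotype table (\code{<out>.haps.tsv}), a merge-log audit
#' file (\code{<out>.mergelog.tsv}) and a JSON summary with the
#' block-size histogram (\code{<out>.summary.json}) are produced.
#'
#' @param vcf,bam Paths for alignment-based input (both required
#'   together).
#' @param fragmentFile Path to a plain-text fragment file (alternative
#'   input).
#' @param sitesFile Optional TSV (chrom, pos) giving genomic positions of
#'   the fragment file's site indices.
#' @param out Output path prefix; `NULL` suppresses file output.
#' @param sample VCF sample to phase.
#' @param params [ScoringParams-class] for pair scoring.
#' @param minJunctions Local-MEC trigger threshold (default 3).
#' @param lowCovThreshold Optional override of the per-block median
#'   low-coverage threshold.
#' @param minMapq,minBaseq Extraction filters for BAM input.
#' @return Invisibly, a list with \code{sites}, \code{blocks},
#'   \code{phased} (list of [PhasedBlock-class]) and \code{summary}.
#' @export
runPhase <- function(vcf = NULL, bam = NULL, fragmentFile = NULL,
                     sitesFile = NULL, out = NULL, sample = 1L,
                     params = scoringParams(), minJunctions = 3L,
                     lowCovThreshold = NULL, minMapq = 0L, minBaseq = 0L) {
    if (!is.null(fragmentFile)) {
        fragments <- readFragmentFile(fragmentFile)
        sites <- .sitesForFragments(fragments, sitesFile)
    } else {
        if (is.null(vcf) || is.null(bam))
            stop("provide either fragmentFile or both vcf and bam")
        sites <- readVariantSites(vcf, sample)
        fragments <- extractFragments(bam, sites, minMapq, minBaseq)
    }
    blocks <- buildBlocks(fragments, sites)
    phased <- lapply(blocks, assembleBlock, params = params,
                     minJunctions = minJunctions,
                     lowCovThreshold = lowCovThreshold)
    sizes <- vapply(blocks, nSites, integer(1L))
    summary <- list(
        nSites = length(sites),
        nFragments = length(fragments),
        nBlocks = length(blocks),
        nUnphaseable = length(attr(blocks, "unphaseable")),
        blockSizeHistogram = if (length(sizes))
            as.list(table(sizes)) else list())
    if (!is.null(out)) {
        if (!is.null(vcf))
            writePhasedVcf(phased, vcf, paste0(out, ".phased.vcf"), sample)
        hapTab <- do.call(rbind, lapply(seq_along(phased), function(k) {
            pb <- phased[[k]]
            sts <- blockSites(pb)
            data.frame(
                chrom = as.character(GenomicRanges::seqnames(sts)),
                pos = GenomicRanges::start(sts),
                siteIndex = pb@block@siteIndex,
                hap1 = ifelse(phasedSites(pb), pb@hap1, NA_integer_),
                phaseSet = GenomicRanges::start(sts)[1L])
        }))
        if (is.null(hapTab))
            hapTab <- data.frame(chrom = character(), pos = integer(),
                                 siteIndex = integer(), hap1 = integer(),
                                 phaseSet = integer())
        utils::write.table(hapTab, paste0(out, ".haps.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        if (length(phased))
            writeMergeLog(phased, paste0(out, ".mergelog.tsv"))
        jsonlite::write_json(summary, paste0(out, ".summary.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    invisible(list(sites = sites, blocks = blocks, phased = phased,
                   summary = summary))
}

#' Simulate a benchmark dataset to files
#'
#' Generates a dataset under one simulation configuration and writes the
#' plain-text fragment file (\code{<out>.fragments.tsv}) and the truth
#' haplotypes (\code{<out>.truth.tsv}); optionally a VCF of the simulated
#' het sites (\code{<out>.sites.vcf}).
#'
#' @param config A [SimConfig-class].
#' @param out Output path prefix.
#' @param seed Integer seed; the run is fully reproducible from it.
#' @param writeSitesVcf Also emit a minimal VCF of the simulated sites.
#' @return Invisibly, the simulated dataset (see [simulateDataset()]).
#' @export
runSimulate <- function(config = simConfig(), out, seed = 1L,
                        writeSitesVcf = FALSE) {
    dataset <- simulateDataset(config, seed = seed)
    fs <- fragmentSet(
        name = unlist(lapply(dataset, function(b) b$fragments@name)),
        sites = do.call(c, lapply(dataset, function(b) b$fragments@sites)),
        alleles = do.call(c, lapply(dataset,
                                    function(b) b$fragments@alleles)),
        chrom = unlist(lapply(dataset, function(b) b$fragments@chrom)))
    writeFragmentFile(fs, paste0(out, ".fragments.tsv"))
    truth <- lapply(dataset, function(b)
        list(chrom = b$chrom, pos = b$pos, hap1 = b$hap1))
    writeTruthFile(truth, paste0(out, ".truth.tsv"))
    sitesTab <- do.call(rbind, lapply(dataset, function(b)
        data.frame(chrom = b$chrom, pos = b$pos)))
    utils::write.table(sitesTab, paste0(out, ".sites.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (writeSitesVcf) .writeSimpleVcf(dataset, paste0(out, ".sites.vcf"))
    invisible(dataset)
}

## Minimal unphased VCF for simulated sites (alleles are placeholders:
## simulated data carries 0/1 encodings, not nucleotides).
.writeSimpleVcf <- function(dataset, file) {
    con <- file(file, "w")
    writeLines(c("##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
               "SIM")), con)
    for (b in dataset)
        writeLines(sprintf("%s\t%d\t.\tA\tC\t.\tPASS\t.\tGT\t0/1",
                           b$chrom, b$pos), con)
    close(con)
    invisible(file)
}

#' Evaluate a prediction against a truth phasing
#'
#' Loads a predicted phasing (phased VCF with PS tags, or a
#' \code{.haps.tsv} table from [runPhase()]) and a truth phasing (phased
#' VCF or truth TSV), matches blocks by chromosome and position, and
#' computes the full metric suite. Per-block rows are written to
#' \code{<out>.blocks.tsv} and the aggregate metrics to
#' \code{<out>.metrics.json}.
#'
#' @param pred,truth Input paths; format detected from content
#'   (\code{.vcf} vs TSV).
#' @param out Optional output prefix.
#' @param sample VCF sample for either input.
#' @return Invisibly, the [evaluatePhasing()] result.
#' @export
runEvaluate <- function(pred, truth, out = NULL, sample = 1L) {
    predBlocks <- .readPhasingFile(pred, sample)
    truthBlocks <- .readPhasingFile(truth, sample)
    ## index truth alleles by chrom:pos
    tpos <- unlist(lapply(truthBlocks, function(b)
        paste(b$chrom, b$pos)))
    thap <- unlist(lapply(truthBlocks, function(b) b$hap1))
    preds <- truths <- list()
    for (b in predBlocks) {
        m <- match(paste(b$chrom, b$pos), tpos)
        if (all(is.na(m))) next  # disjoint site sets: skip, flagged below
        preds[[length(preds) + 1L]] <- b
        truths[[length(truths) + 1L]] <- ifelse(is.na(m), NA_integer_,
                                                thap[m])
    }
    if (!length(preds)) {
        warning("no overlapping sites between prediction and truth")
        return(invisible(NULL))
    }
    res <- evaluatePhasing(preds, truths)
    if (!is.null(out)) {
        utils::write.table(res$perBlock, paste0(out, ".blocks.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(res$metrics, paste0(out, ".metrics.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    invisible(res)
}

.readPhasingFile <- function(path, sample = 1L) {
    firstLine <- readLines(path, n = 1L)
    if (startsWith(firstLine, "##fileformat=VCF"))
        return(readPhasedHaplotypes(path, sample))
    tab <- utils::read.table(path, sep = "\t", header = TRUE)
    if (all(c("chrom", "pos", "hap1", "phaseSet") %in% names(tab))) {
        return(lapply(split(tab, paste(tab$chrom, tab$phaseSet)),
                      function(d) {
            d <- d[order(d$pos), ]
            list(chrom = as.character(d$chrom[1L]), pos = d$pos,
                 hap1 = as.integer(d$hap1))
        }))
    }
    if (all(c("chrom", "pos", "hap1") %in% names(tab)))
        return(readTruthFile(path))
    stop("unrecognized phasing file format: ", path)
}
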