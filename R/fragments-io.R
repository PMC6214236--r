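#' @include AllClasses.R utils.R
#' @importFrom VariantAnnotation readVcf writeVcf geno geno<- header
#'   ref alt
#' @importFrom SummarizedExperiment rowRanges
#' @importFrom Rsamtools ScanBamParam scanBamHeader
#' @importFrom GenomicAlignments readGAlignments cigar
#'   cigarRangesAlongReferenceSpace cigarRangesAlongQuerySpace
NULL

#' Read heterozygous bi-allelic SNP sites from a VCF
#'
#' Keeps only bi-allelic SNP records whose genotype in the chosen sample
#' is heterozygous; multi-allelic, indel and homozygous records are
#' dropped (counts are reported via \code{message}). Sites are sorted by
#' chromosome and position and numbered per chromosome
#' (\code{siteIndex}, 1-based).
#'
#' @param file Path to a VCF (optionally bgzipped).
#' @param sample Sample name or column index (default: first sample).
#' @return A `GRanges` with metadata columns \code{ref}, \code{alt},
#'   \code{siteIndex}. Drop counts are attached as attribute
#'   \code{"dropped"}.
#' @export
readVariantSites <- function(file, sample = 1L) {
    vcf <- VariantAnnotation::readVcf(file)
    gtm <- VariantAnnotation::geno(vcf)$GT
    if (is.null(gtm))
        stop("VCF has no GT field")
    if (is.character(sample) && !sample %in% colnames(gtm))
        stop("sample '", sample, "' not found in VCF (samples: ",
             paste(colnames(gtm), collapse = ", "), ")")
    gt <- gtm[, sample]
    rr <- SummarizedExperiment::rowRanges(vcf)
    refA <- as.character(VariantAnnotation::ref(vcf))
    altL <- VariantAnnotation::alt(vcf)
    nAlt <- lengths(altL)
    altA <- rep(NA_character_, length(rr))
    altA[nAlt == 1L] <- as.character(unlist(altL[nAlt == 1L]))
    isBiSnp <- nAlt == 1L & nchar(refA) == 1L &
        !is.na(altA) & nchar(altA) == 1L &
        refA %in% c("A", "C", "G", "T") & altA %in% c("A", "C", "G", "T")
    isHet <- gt %in% c("0/1", "1/0", "0|1", "1|0")
    keep <- isBiSnp & isHet
    dropped <- c(nonSnpOrMultiallelic = sum(!isBiSnp),
                 homozygousOrMissing = sum(isBiSnp & !isHet))
    if (any(dropped > 0))
        message("dropped ", dropped[1L], " non-SNP/multi-allelic and ",
                dropped[2L], " non-heterozygous records")
    gr <- GenomicRanges::granges(rr)[keep]
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        ref = refA[keep], alt = altA[keep])
    chroms <- as.character(GenomicRanges::seqnames(gr))
    gr <- gr[order(chroms, GenomicRanges::start(gr))]
    chroms <- as.character(GenomicRanges::seqnames(gr))
    S4Vectors::mcols(gr)$siteIndex <- if (length(gr))
        as.integer(stats::ave(seq_along(gr), chroms, FUN = seq_along))
    else integer(0)
    names(gr) <- NULL
    attr(gr, "dropped") <- dropped
    gr
}

## Map one reference position to the query (read) coordinate of an
## alignment, given parallel reference/query IRanges of its aligned
## (M/=/X) cigar segments. NA when the position falls in a deletion,
## intron or outside the alignment.
.refToQuery <- function(p, refStarts, refEnds, qryStarts) {
    k <- which(p >= refStarts & p <= refEnds)
    if (!length(k)) return(NA_integer_)
    qryStarts[k[1L]] + (p - refStarts[k[1L]])
}

#' Extract haplotype-informative fragments from a BAM file
#'
#' Visits every alignment overlapping the variant sites, reads the base at
#' each covered site through the alignment's CIGAR (so deletions, introns
#' and soft clips become gaps), and encodes it as 0 (reference allele),
#' 1 (alternative allele) or a gap for any other base or a base below
#' \code{minBaseq}. Both mates of a read pair are merged into a single
#' fragment; when the mates disagree at a shared site the site is treated
#' as unreliable and gapped. Fragments informative at fewer than two
#' sites are discarded.
#'
#' The default \code{minMapq = 0} and \code{minBaseq = 0} keep all reads,
#' so block discovery sees the full connectivity of the data; both are
#' configurable.
#'
#' @param file Path to an indexed BAM file.
#' @param sites Variant sites from [readVariantSites()].
#' @param minMapq Minimum mapping quality; lower alignments are skipped.
#' @param minBaseq Minimum base quality; lower bases become gaps.
#' @return A [FragmentSet-class] with per-chromosome 1-based site
#'   indices.
#' @export
extractFragments <- function(file, sites, minMapq = 0L, minBaseq = 0L) {
    bamChroms <- names(Rsamtools::scanBamHeader(file)[[1L]]$targets)
    siteChroms <- unique(as.character(GenomicRanges::seqnames(sites)))
    missing <- setdiff(siteChroms, bamChroms)
    if (length(missing))
        stop("chromosomes in VCF but not in BAM: ",
             paste(missing, collapse = ", "),
             " (BAM has: ", paste(bamChroms, collapse = ", "), ")")
    allName <- allChrom <- allSites <- allAlleles <- list()
    for (chrom in siteChroms) {
        cs <- sites[as.character(GenomicRanges::seqnames(sites)) == chrom]
        pos <- GenomicRanges::start(cs)
        refA <- S4Vectors::mcols(cs)$ref
        altA <- S4Vectors::mcols(cs)$alt
        which <- GenomicRanges::GRanges(chrom,
            IRanges::IRanges(min(pos), max(pos)))
        param <- Rsamtools::ScanBamParam(
            what = c("qname", "mapq", "seq", "qual"), which = which)
        aln <- GenomicAlignments::readGAlignments(file, param = param)
        if (!length(aln)) next
        md <- S4Vectors::mcols(aln)
        keepAln <- is.na(md$mapq) | md$mapq >= minMapq
        aln <- aln[keepAln]; md <- md[keepAln, ]
        if (!length(aln)) next
        cig <- GenomicAlignments::cigar(aln)
        refR <- GenomicAlignments::cigarRangesAlongReferenceSpace(
            cig, pos = GenomicRanges::start(aln), ops = c("M", "=", "X"))
        qryR <- GenomicAlignments::cigarRangesAlongQuerySpace(
            cig, ops = c("M", "=", "X"))
        seqs <- as.character(md$seq)
        quals <- as.character(md$qual)
        perRead <- new.env(parent = emptyenv())
        for (r in seq_along(aln)) {
            lo <- GenomicRanges::start(aln)[r]
            hi <- GenomicRanges::end(aln)[r]
            sIdx <- which(pos >= lo & pos <= hi)
            if (!length(sIdx)) next
            rs <- IRanges::start(refR[[r]]); re <- IRanges::end(refR[[r]])
            qs <- IRanges::start(qryR[[r]])
            for (si in sIdx) {
                qpos <- .refToQuery(pos[si], rs, re, qs)
                sym <- NA_integer_  # gap
                if (!is.na(qpos)) {
                    base <- substr(seqs[r], qpos, qpos)
                    bq <- utf8ToInt(substr(quals[r], qpos, qpos)) - 33L
                    if (length(bq) && !is.na(bq) && bq >= minBaseq) {
                        if (base == refA[si]) sym <- 0L
                        else if (base == altA[si]) sym <- 1L
                    }
                }
                qn <- md$qname[r]
                cur <- get0(qn, envir = perRead)
                if (is.null(cur)) cur <- list()
                prev <- cur[[as.character(si)]]
                if (is.null(prev)) cur[[as.character(si)]] <- sym
                else if (!identical(prev, sym))
                    cur[[as.character(si)]] <- NA_integer_ # mate conflict
                assign(qn, cur, envir = perRead)
            }
        }
        for (qn in ls(perRead)) {
            ent <- get(qn, envir = perRead)
            si <- as.integer(names(ent))
            al <- unlist(ent, use.names = FALSE)
            ok <- !is.na(al)
            if (sum(ok) < 2L) next
            o <- order(si[ok])
            allName <- c(allName, qn)
            allChrom <- c(allChrom, chrom)
            allSites <- c(allSites, list(si[ok][o]))
            allAlleles <- c(allAlleles, list(al[ok][o]))
        }
    }
    if (!length(allName))
        return(fragmentSet(character(0), list(), list(), character(0)))
    fragmentSet(unlist(allName), allSites, allAlleles, unlist(allChrom))
}

#' Partition variants into connected blocks
#'
#' Two variants are connected when at least one fragment covers both; the
#' relation is transitive, and each connected component of the resulting
#' variant graph becomes one phaseable block. Sites with no informative
#' coverage are unphaseable singletons and are returned separately.
#'
#' @param fragments A [FragmentSet-class] with per-chromosome site
#'   indices.
#' @param sites `GRanges` of sites with \code{siteIndex} metadata, as from
#'   [readVariantSites()].
#' @return A list of [VariantBlock-class] objects ordered by chromosome
#'   and first position, with the unphaseable singleton sites attached as
#'   attribute \code{"unphaseable"} (a `GRanges`).
#' @examples
#' sites <- GenomicRanges::GRanges("c", IRanges::IRanges(c(10, 20, 30), width = 1))
#' S4Vectors::mcols(sites)$siteIndex <- 1:3
#' fr <- fragmentSet(c("a", "b"), list(1:2, 2:3),
#'                   list(c(0L, 0L), c(0L, 0L)), "c")
#' length(buildBlocks(fr, sites)) # one block of 3
#' @export
buildBlocks <- function(fragments, sites) {
    blocks <- list()
    lonely <- GenomicRanges::GRanges()
    for (chrom in unique(as.character(GenomicRanges::seqnames(sites)))) {
        cs <- sites[as.character(GenomicRanges::seqnames(sites)) == chrom]
        cs <- cs[order(GenomicRanges::start(cs))]
        n <- length(cs)
        frIdx <- which(fragments@chrom == chrom &
                       lengths(fragments@sites) >= 2L)
        comp <- .fragmentComponents(fragments@sites[frIdx], n)
        covered <- unique(unlist(fragments@sites[frIdx], use.names = FALSE))
        for (cid in unique(comp[covered])) {
            member <- which(comp == cid & seq_len(n) %in% covered)
            if (length(member) < 2L) {
                lonely <- c(lonely, GenomicRanges::granges(cs[member]))
                next
            }
            inBlock <- frIdx[vapply(fragments@sites[frIdx],
                function(s) s[1L] %in% member, logical(1L))]
            local <- match(seq_len(n), member)
            fr <- fragments[inBlock]
            fr@sites <- lapply(fr@sites, function(s) local[s])
            blocks[[length(blocks) + 1L]] <- variantBlock(
                cs[member], fr, siteIndex = member)
        }
        uncovered <- setdiff(seq_len(n), covered)
        if (length(uncovered))
            lonely <- c(lonely, GenomicRanges::granges(cs[uncovered]))
    }
    if (length(blocks)) {
        ord <- order(
            vapply(blocks, function(b)
                as.character(GenomicRanges::seqnames(b@sites)[1L]),
                character(1L)),
            vapply(blocks, function(b)
                min(GenomicRanges::start(b@sites)), numeric(1L)))
        blocks <- blocks[ord]
    }
    attr(blocks, "unphaseable") <- lonely
    blocks
}

## ---- plain-text fragment format ---------------------------------------

#' Read or write the plain-text SNP-fragment format
#'
#' A line-per-fragment TSV that lets the phasing core run without any
#' alignment files. Columns: \code{chrom}, \code{name}, \code{start}
#' (1-based site index of the first covered site on that chromosome), and
#' \code{alleles} (a string over \code{0}, \code{1}, \code{-} where
#' \code{-} marks gaps between the first and last covered site). Reading
#' drops fragments informative at fewer than two sites.
#'
#' @param file Path to the fragment file.
#' @param fragments A [FragmentSet-class] (for writing).
#' @return `readFragmentFile` returns a [FragmentSet-class];
#'   `writeFragmentFile` the path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' fr <- fragmentSet(c("a", "b"), list(c(1L, 3L), 2:3),
#'                   list(c(0L, 1L), c(1L, 1L)), "chr1")
#' writeFragmentFile(fr, f)
#' readFragmentFile(f)
#' @export
readFragmentFile <- function(file) {
    tab <- utils::read.table(file, sep = "\t", header = TRUE,
                             colClasses = c("character", "character",
                                            "integer", "character"))
    if (!all(c("chrom", "name", "start", "alleles") %in% names(tab)))
        stop("fragment file must have columns chrom, name, start, alleles")
    sites <- alleles <- vector("list", nrow(tab))
    keep <- logical(nrow(tab))
    for (k in seq_len(nrow(tab))) {
        ch <- strsplit(tab$alleles[k], "")[[1L]]
        if (!all(ch %in% c("0", "1", "-")))
            stop("line ", k, ": alleles must be over {0,1,-}")
        inf <- ch != "-"
        if (sum(inf) < 2L) next
        keep[k] <- TRUE
        sites[[k]] <- tab$start[k] + which(inf) - 1L
        alleles[[k]] <- as.integer(ch[inf])
    }
    if (sum(!keep))
        message("dropped ", sum(!keep), " uninformative fragment(s)")
    fragmentSet(tab$name[keep], sites[keep], alleles[keep], tab$chrom[keep])
}

#' @rdname readFragmentFile
#' @export
writeFragmentFile <- function(fragments, file) {
    n <- length(fragments)
    start <- vapply(fragments@sites, function(s) s[1L], integer(1L))
    alleles <- vapply(seq_len(n), function(k) {
        s <- fragments@sites[[k]]
        rel <- s - s[1L] + 1L
        out <- rep("-", max(rel))
        out[rel] <- as.character(fragments@alleles[[k]])
        paste(out, collapse = "")
    }, character(1L))
    utils::write.table(
        data.frame(chrom = fragments@chrom, name = fragments@name,
                   start = start, alleles = alleles),
        file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

## ---- phased VCF output -------------------------------------------------

#' Write phased blocks to a VCF
#'
#' Rewrites the input VCF with phased genotypes: each phased site becomes
#' \code{0|1} or \code{1|0} with a \code{PS} (phase set) FORMAT tag equal
#' to the position of its block's first variant; undecided sites and
#' records that were never phaseable keep their original genotype.
#'
#' @param phasedBlocks List of [PhasedBlock-class] objects.
#' @param vcfIn Path of the VCF the sites came from.
#' @param out Output VCF path.
#' @param sample Sample name or column index to phase.
#' @return The output path, invisibly.
#' @export
writePhasedVcf <- function(phasedBlocks, vcfIn, out, sample = 1L) {
    vcf <- VariantAnnotation::readVcf(vcfIn)
    gt <- VariantAnnotation::geno(vcf)$GT
    ps <- matrix(NA_integer_, nrow(gt), ncol(gt),
                 dimnames = dimnames(gt))
    vchrom <- as.character(GenomicRanges::seqnames(
        SummarizedExperiment::rowRanges(vcf)))
    vpos <- GenomicRanges::start(SummarizedExperiment::rowRanges(vcf))
    for (pb in phasedBlocks) {
        sts <- blockSites(pb)
        chrom <- as.character(GenomicRanges::seqnames(sts))[1L]
        pos <- GenomicRanges::start(sts)
        phaseSet <- pos[1L]
        rows <- match(paste(chrom, pos), paste(vchrom, vpos))
        if (anyNA(rows))
            stop("phased block sites missing from VCF: internal mismatch")
        ph <- phasedSites(pb)
        gt[rows[ph], sample] <- ifelse(pb@hap1[ph] == 0L, "0|1", "1|0")
        ps[rows[ph], sample] <- phaseSet
    }
    hdr <- VariantAnnotation::header(vcf)
    if (!"PS" %in% rownames(VariantAnnotation::geno(hdr))) {
        VariantAnnotation::geno(hdr) <- rbind(
            VariantAnnotation::geno(hdr),
            S4Vectors::DataFrame(Number = "1", Type = "Integer",
                Description = "Phase set (position of first variant in block)",
                row.names = "PS"))
        VariantAnnotation::header(vcf) <- hdr
    }
    VariantAnnotation::geno(vcf)$GT <- gt
    VariantAnnotation::geno(vcf)$PS <- ps
    VariantAnnotation::writeVcf(vcf, out)
    invisible(out)
}

#' Read phased haplotypes from a VCF
#'
#' Decodes phased genotypes (\code{0|1} / \code{1|0}) back into per-block
#' haplotype vectors, grouping sites by the \code{PS} tag when present and
#' otherwise treating all phased sites of a chromosome as one block.
#'
#' @param file Phased VCF path.
#' @param sample Sample name or column index.
#' @return A list of blocks, each a list with \code{chrom}, \code{pos}
#'   and \code{hap1} (0/1 with NA at unphased sites).
#' @export
readPhasedHaplotypes <- function(file, sample = 1L) {
    vcf <- VariantAnnotation::readVcf(file)
    gt <- VariantAnnotation::geno(vcf)$GT[, sample]
    ps <- if ("PS" %in% names(VariantAnnotation::geno(vcf)))
        VariantAnnotation::geno(vcf)$PS[, sample] else rep(NA_integer_,
                                                           length(gt))
    rr <- SummarizedExperiment::rowRanges(vcf)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    hap <- rep(NA_integer_, length(gt))
    hap[gt == "0|1"] <- 0L
    hap[gt == "1|0"] <- 1L
    grp <- ifelse(is.na(hap), NA,
                  paste(chrom, ifelse(is.na(ps), "all", ps)))
    out <- list()
    for (g in unique(grp[!is.na(grp)])) {
        sel <- which(!is.na(grp) & grp == g)
        sel <- sel[order(pos[sel])]
        out[[length(out) + 1L]] <- list(chrom = chrom[sel[1L]],
                                        pos = pos[sel], hap1 = hap[sel])
    }
    out
}

#' Read or write two-row truth haplotypes
#'
#' Simple TSV truth format with columns \code{chrom}, \code{pos},
#' \code{hap1}; haplotype 2 is the complement. One block per chromosome.
#'
#' @param file Path.
#' @param blocks For writing: list of lists with \code{chrom}, \code{pos},
#'   \code{hap1}.
#' @return `readTruthFile` returns a list of blocks as in
#'   [readPhasedHaplotypes()].
#' @export
readTruthFile <- function(file) {
    tab <- utils::read.table(file, sep = "\t", header = TRUE)
    lapply(split(tab, tab$chrom), function(d) {
        d <- d[order(d$pos), ]
        list(chrom = as.character(d$chrom[1L]), pos = d$pos,
             hap1 = as.integer(d$hap1))
    })
}

#' @rdname readTruthFile
#' @export
writeTruthFile <- function(blocks, file) {
    tab <- do.call(rbind, lapply(blocks, function(b)
        data.frame(chrom = b$chrom, pos = b$pos, hap1 = b$hap1)))
    utils::write.table(tab, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}
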