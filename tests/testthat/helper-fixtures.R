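# Fixture builders and independent oracles shared across tests.

# FragmentSet from allele strings like "01-0": '-' are gaps, `start` is
# the site index of the first character.
mkFrags <- function(strings, start = 1L, chrom = "chr",
                    names = sprintf("f%03d", seq_along(strings))) {
    start <- rep_len(start, length(strings))
    sites <- alleles <- vector("list", length(strings))
    for (k in seq_along(strings)) {
        ch <- strsplit(strings[[k]], "")[[1L]]
        inf <- which(ch != "-")
        sites[[k]] <- start[k] + inf - 1L
        alleles[[k]] <- as.integer(ch[inf])
    }
    fragmentSet(names, sites, alleles, chrom)
}

# VariantBlock over n sites (positions default to 100, 200, ...) from
# fragment strings; counts repeats each string.
mkBlock <- function(strings, counts = 1L, pos = NULL, chrom = "chr") {
    counts <- rep_len(counts, length(strings))
    strings <- rep(strings, counts)
    fr <- mkFrags(strings, chrom = chrom)
    n <- max(unlist(fr@sites))
    if (is.null(pos)) pos <- 100L * seq_len(n)
    sites <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(pos, width = 1L))
    variantBlock(sites, fr)
}

# Three-variant, 50-read instance on which the confidence-guided
# assembly and global MEC provably disagree: three concentrated read
# types feed the 0-0 cell of each pair while two read types support a
# balanced 1:1 split of the cross cells. Every pair sees 26 reads, the
# MEC optimum (000/111, 14 corrections) is unique, and the assembly
# follows the balanced solution 011/100 instead.
divergenceBlock <- function() {
    mkBlock(c("00-", "0-0", "-00", "011", "100"),
            counts = c(12L, 12L, 12L, 7L, 7L))
}

# Random connected block with known truth, built through the simulator;
# returns the largest discovered block and the matching truth alleles.
randomTruthBlock <- function(n, coverage = 30, seqError = 0, skew = 0.5,
                             minSites = 2L) {
    repeat {
        truth <- simulateTruth(n, span = 82L * n)
        fr <- simulateFragments(truth, simConfig(
            coverage = coverage, seqError = seqError, skew = skew))
        sites <- GenomicRanges::GRanges(truth$chrom,
            IRanges::IRanges(truth$pos, width = 1L))
        S4Vectors::mcols(sites)$siteIndex <- seq_along(truth$pos)
        blocks <- buildBlocks(fr, sites)
        if (!length(blocks)) next
        sizes <- vapply(blocks, nSites, integer(1L))
        blk <- blocks[[which.max(sizes)]]
        if (nSites(blk) < minSites) next
        return(list(block = blk,
                    truthHap = truth$hap1[blk@siteIndex],
                    fullTruth = truth))
    }
}

# Exhaustive minimum-cost switch/flip decomposition oracle: every toggle
# boundary costs one switch, two adjacent toggle boundaries can merge
# into one flip; recursion explores all pairings.
switchFlipOracle <- function(pred, truth) {
    p <- strsplit(pred, "")[[1L]]
    t1 <- strsplit(truth, "")[[1L]]
    tt <- if (t1[1L] == p[1L]) t1 else as.character(1L - as.integer(t1))
    agree <- p == tt
    toggles <- which(agree[-1L] != agree[-length(agree)])
    rec <- function(tg) {
        if (!length(tg)) return(c(switch = 0L, flip = 0L))
        asSwitch <- rec(tg[-1L]) + c(1L, 0L)
        best <- asSwitch
        if (length(tg) >= 2L && tg[2L] == tg[1L] + 1L) {
            asFlip <- rec(tg[-(1:2)]) + c(0L, 1L)
            if (sum(asFlip) < sum(best) ||
                (sum(asFlip) == sum(best) && asFlip[2L] > best[2L]))
                best <- asFlip
        }
        best
    }
    out <- rec(toggles)
    list(switch = unname(out[1L]), flip = unname(out[2L]),
         total = sum(out))
}

# Minimal single-sample VCF written as text; gts is a character vector of
# genotypes parallel to pos.
writeTestVcf <- function(file, chrom, pos, ref, alt, gts,
                         sample = "S1") {
    lines <- c(
        "##fileformat=VCFv4.2",
        paste0("##contig=<ID=", unique(chrom), ",length=100000>"),
        "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
               sample),
        sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                chrom, pos, ref, alt, gts))
    writeLines(lines, file)
    file
}

# Sorted, indexed BAM from SAM record lines (QNAME FLAG RNAME POS MAPQ
# CIGAR RNEXT PNEXT TLEN SEQ QUAL).
writeTestBam <- function(records, prefix = tempfile(),
                         chrom = "chr1", len = 100000L) {
    sam <- paste0(prefix, ".sam")
    writeLines(c(sprintf("@HD\tVN:1.6\tSO:coordinate"),
                 sprintf("@SQ\tSN:%s\tLN:%d", chrom, len),
                 records), sam)
    bam <- Rsamtools::asBam(sam, prefix, overwrite = TRUE)
    bam
}

samRecord <- function(qname, pos, cigar, seq, flag = 0L, chrom = "chr1",
                      mapq = 60L, qual = NULL) {
    if (is.null(qual)) qual <- strrep("I", nchar(seq))
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
            qname, flag, chrom, pos, mapq, cigar, seq, qual)
}
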