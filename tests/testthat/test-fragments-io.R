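test_that("VCF reading keeps only heterozygous bi-allelic SNPs", {
    f <- tempfile(fileext = ".vcf")
    writeTestVcf(f, "chr1", c(100L, 200L, 300L, 400L),
                 ref = c("A", "C", "G", "AT"),
                 alt = c("G", "T", "A", "A"),
                 gts = c("0/1", "1/1", "0|1", "0/1"))
    sites <- suppressMessages(readVariantSites(f))
    expect_length(sites, 2L)
    expect_identical(GenomicRanges::start(sites), c(100L, 300L))
    expect_identical(S4Vectors::mcols(sites)$ref, c("A", "G"))
    expect_identical(S4Vectors::mcols(sites)$siteIndex, c(1L, 2L))
    expect_identical(unname(attr(sites, "dropped")),
                     c(1L, 1L))  # one indel, one homozygote
})

test_that("sites are numbered per chromosome after sorting", {
    f <- tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##contig=<ID=chr1,length=100000>",
        "##contig=<ID=chr2,length=100000>",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
        "chr1\t500\t.\tA\tC\t.\tPASS\t.\tGT\t0/1",
        "chr1\t100\t.\tA\tC\t.\tPASS\t.\tGT\t0/1",
        "chr2\t250\t.\tG\tT\t.\tPASS\t.\tGT\t1|0"), f)
    sites <- readVariantSites(f)
    expect_length(sites, 3L)
    byChrom <- split(sites, as.character(GenomicRanges::seqnames(sites)))
    expect_identical(S4Vectors::mcols(byChrom$chr1)$siteIndex, 1:2)
    expect_identical(GenomicRanges::start(byChrom$chr1), c(100L, 500L))
    expect_identical(S4Vectors::mcols(byChrom$chr2)$siteIndex, 1L)
    expect_error(readVariantSites(f, sample = "nope"), "not found")
})

test_that("fragment extraction encodes alleles through the CIGAR", {
    vcf <- tempfile(fileext = ".vcf")
    writeTestVcf(vcf, "chr1", c(100L, 120L, 140L),
                 ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                 gts = rep("0/1", 3))
    sites <- readVariantSites(vcf)
    mkSeq <- function(bases) {
        # 50bp read starting at 95: sites 100/120/140 sit at qpos 6/26/46
        s <- strrep("A", 50)
        for (k in seq_along(bases))
            substr(s, c(6L, 26L, 46L)[k], c(6L, 26L, 46L)[k]) <- bases[k]
        s
    }
    bam <- writeTestBam(c(
        samRecord("r1", 95L, "50M", mkSeq(c("A", "T", "G"))),  # 0,1,0
        samRecord("r2", 95L, "50M", mkSeq(c("G", "C", "C")))), # 1,0,-
        prefix = tempfile())
    fr <- extractFragments(bam, sites)
    expect_length(fr, 2L)
    o <- match(c("r1", "r2"), names(fr))
    expect_identical(fr@sites[[o[1]]], 1:3)
    expect_identical(fr@alleles[[o[1]]], c(0L, 1L, 0L))
    expect_identical(fr@sites[[o[2]]], 1:2)  # site 3 is neither allele
    expect_identical(fr@alleles[[o[2]]], c(1L, 0L))
})

test_that("mates merge into one fragment; conflicts become gaps", {
    vcf <- tempfile(fileext = ".vcf")
    writeTestVcf(vcf, "chr1", c(100L, 120L, 300L),
                 ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                 gts = rep("0/1", 3))
    sites <- readVariantSites(vcf)
    seq1 <- strrep("A", 30)                      # covers 95..124: sites 1,2
    substr(seq1, 6, 6) <- "A"; substr(seq1, 26, 26) <- "C"
    seq2 <- strrep("T", 30)                      # covers 290..319: site 3
    substr(seq2, 11, 11) <- "A"                  # alt at 300
    bam <- writeTestBam(c(
        samRecord("rp", 95L, "30M", seq1, flag = 99L),
        samRecord("rp", 290L, "30M", seq2, flag = 147L),
        # conflicting pair: both mates cover site 1 with opposite alleles
        samRecord("rc", 95L, "30M", seq1, flag = 99L),
        samRecord("rc", 98L, "30M", paste0("GGG", strrep("C", 27)),
                  flag = 147L)),
        prefix = tempfile())
    fr <- extractFragments(bam, sites)
    rp <- which(names(fr) == "rp")
    expect_identical(fr@sites[[rp]], c(1L, 2L, 3L))
    expect_identical(fr@alleles[[rp]], c(0L, 0L, 1L))
    # rc: site1 conflict -> gap; site2 from mate1 (0) + site2 in mate2?
    # mate2 (98..127) covers sites 100 and 120 with G..C: site1=alt(1)
    # conflicting with mate1 ref(0) -> gap; site2 agrees (C=ref).
    rc <- which(names(fr) == "rc")
    expect_length(rc, 0L)  # only site2 left informative -> dropped
})

test_that("deletions and chromosome mismatches are handled", {
    vcf <- tempfile(fileext = ".vcf")
    writeTestVcf(vcf, "chr1", c(100L, 107L, 120L),
                 ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                 gts = rep("0/1", 3))
    sites <- readVariantSites(vcf)
    # 10M5D40M from 95: ref 95..104 (query 1..10), del 105..109,
    # ref 110..149 (query 11..50); site 107 deleted, 100->q6, 120->q21
    s <- strrep("A", 50)
    substr(s, 21, 21) <- "A"
    bam <- writeTestBam(samRecord("rd", 95L, "10M5D40M", s),
                        prefix = tempfile())
    fr <- extractFragments(bam, sites)
    expect_identical(fr@sites[[1L]], c(1L, 3L))  # site 2 gapped
    badSites <- GenomicRanges::GRanges("chrX",
        IRanges::IRanges(c(1L, 2L), width = 1L))
    S4Vectors::mcols(badSites) <- S4Vectors::DataFrame(
        ref = "A", alt = "C", siteIndex = 1:2)
    expect_error(extractFragments(bam, badSites), "chrX")
})

test_that("base and mapping quality filters apply", {
    vcf <- tempfile(fileext = ".vcf")
    writeTestVcf(vcf, "chr1", c(100L, 120L),
                 ref = c("A", "C"), alt = c("G", "T"), gts = rep("0/1", 2))
    sites <- readVariantSites(vcf)
    qual <- paste0(strrep("I", 5), "#", strrep("I", 24))  # qpos 6 has Q2
    sq <- strrep("A", 30)                 # ref at site 1 (qpos 6)
    substr(sq, 26, 26) <- "C"             # ref at site 2 (qpos 26)
    bam <- writeTestBam(c(
        samRecord("hq", 95L, "30M", sq),
        samRecord("lq", 95L, "30M", sq, qual = qual),
        samRecord("lm", 95L, "30M", sq, mapq = 5L)),
        prefix = tempfile())
    expect_length(extractFragments(bam, sites), 3L)
    frq <- extractFragments(bam, sites, minBaseq = 20L)
    expect_false("lq" %in% names(frq))  # site 1 below baseq -> 1 site left
    frm <- extractFragments(bam, sites, minMapq = 30L)
    expect_false("lm" %in% names(frm))
})

test_that("blocks are the connected components of the pair graph", {
    gr <- function(n, chrom = "c") {
        g <- GenomicRanges::GRanges(chrom,
            IRanges::IRanges(10L * seq_len(n), width = 1L))
        S4Vectors::mcols(g)$siteIndex <- seq_len(n)
        g
    }
    # transitive joining: A-B and B-C form one block
    fr <- mkFrags(c("00", "00"), start = c(1L, 2L), chrom = "c")
    blocks <- buildBlocks(fr, gr(3L))
    expect_length(blocks, 1L)
    expect_identical(blocks[[1L]]@siteIndex, 1:3)
    # disconnected pairs form two blocks
    fr2 <- mkFrags(c("00", "00"), start = c(1L, 3L), chrom = "c")
    blocks2 <- buildBlocks(fr2, gr(4L))
    expect_length(blocks2, 2L)
    # uncovered variant reported unphaseable
    blocks3 <- buildBlocks(fr2, gr(5L))
    expect_length(attr(blocks3, "unphaseable"), 1L)
    expect_identical(
        GenomicRanges::start(attr(blocks3, "unphaseable")), 50L)
})

test_that("block partition matches the igraph components oracle", {
    skip_if_not_installed("igraph")
    set.seed(7)
    for (rep in 1:20) {
        n <- sample(4:12, 1L)
        m <- sample(2:10, 1L)
        starts <- sample(seq_len(n - 1L), m, replace = TRUE)
        fr <- mkFrags(rep("00", m), start = starts, chrom = "c")
        g <- GenomicRanges::GRanges("c",
            IRanges::IRanges(10L * seq_len(n), width = 1L))
        S4Vectors::mcols(g)$siteIndex <- seq_len(n)
        blocks <- buildBlocks(fr, g)
        edges <- cbind(starts, starts + 1L)
        ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
        ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
        comp <- igraph::components(ig)
        expect_identical(length(blocks),
                         sum(comp$csize >= 2L))
        sizes <- sort(vapply(blocks, nSites, integer(1L)))
        expect_identical(sizes, sort(as.integer(
            comp$csize[comp$csize >= 2L])))
    }
})

test_that("every block fragment covers >=2 block sites, none shared", {
    set.seed(11)
    rb <- randomTruthBlock(30)
    fr <- blockFragments(rb$block)
    expect_true(all(lengths(fr@sites) >= 2L))
    # and validity enforces connectivity
    expect_true(validObject(rb$block))
})

test_that("fragment file round-trips and drops uninformative lines", {
    fr <- mkFrags(c("01-1", "10"), start = c(2L, 5L), chrom = "chrZ")
    f <- tempfile(fileext = ".tsv")
    writeFragmentFile(fr, f)
    back <- readFragmentFile(f)
    expect_identical(back@sites, fr@sites)
    expect_identical(back@alleles, fr@alleles)
    expect_identical(back@chrom, fr@chrom)
    writeLines(c("chrom\tname\tstart\talleles", "c\tf1\t1\t0",
                 "c\tf2\t1\t0-1"), f)
    expect_message(back2 <- readFragmentFile(f), "dropped 1")
    expect_length(back2, 1L)
})

test_that("phased VCF output encodes the phase partition and PS tag", {
    vcf <- tempfile(fileext = ".vcf")
    writeTestVcf(vcf, "chr1", c(100L, 200L, 300L, 400L),
                 ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C"),
                 gts = rep("0/1", 4))
    sites <- readVariantSites(vcf)
    blk <- variantBlock(GenomicRanges::granges(sites[1:3]),
                        mkFrags(c("010", "010"), chrom = "chr1"),
                        siteIndex = 1:3)
    pb <- new("PhasedBlock", block = blk, hap1 = c(0L, 1L, 0L),
              phased = rep(TRUE, 3L), mergeLog = data.frame())
    out <- tempfile(fileext = ".vcf")
    writePhasedVcf(list(pb), vcf, out)
    dec <- readPhasedHaplotypes(out)
    expect_length(dec, 1L)
    expect_identical(dec[[1L]]$pos, c(100L, 200L, 300L))
    expect_identical(dec[[1L]]$hap1, c(0L, 1L, 0L))
    # site 4 was not phased
    lines <- grep("^chr1\t400", readLines(out), value = TRUE)
    expect_match(lines, "0/1")
    # complemented solution encodes the same phase partition
    pbC <- new("PhasedBlock", block = blk, hap1 = c(1L, 0L, 1L),
               phased = rep(TRUE, 3L), mergeLog = data.frame())
    outC <- tempfile(fileext = ".vcf")
    writePhasedVcf(list(pbC), vcf, outC)
    decC <- readPhasedHaplotypes(outC)
    cmp <- countSwitchFlip(dec[[1L]]$hap1, decC[[1L]]$hap1)
    expect_identical(cmp$switch + cmp$flip, 0L)
})
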