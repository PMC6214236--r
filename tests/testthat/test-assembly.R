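test_that("junction counting enumerates cluster boundaries", {
    expect_identical(countJunctions(c(100, 300, 500), c(200, 400)), 4L)
    expect_identical(countJunctions(c(100, 200), c(300, 400)), 1L)
    expect_identical(countJunctions(100, 200), 1L)
    # brute-force check on random interleavings
    set.seed(3)
    for (r in 1:25) {
        pos <- sample(1000L, sample(4:10, 1L))
        grp <- sample(c(TRUE, FALSE), length(pos), replace = TRUE)
        if (!any(grp) || all(grp)) next
        memb <- grp[order(pos)]
        expect_identical(countJunctions(pos[grp], pos[!grp]),
                         sum(memb[-1L] != memb[-length(memb)]))
    }
})

test_that("cluster score is the single-linkage max over direct pairs", {
    blk <- mkBlock(c("000", "000", "011", "0-1"), pos = c(10, 20, 30))
    tbl <- scorePairs(blk)
    res <- clusterScore(tbl, c(1L, 2L), 3L)
    direct <- tbl[(tbl$i %in% 1:2 & tbl$j == 3L), ]
    expect_equal(res$score, max(direct$cs))
    expect_true(res$pair[2L] == 3L)
    expect_true(is.na(clusterScore(tbl, 1L, integer(0))$score))
    # random instances vs exhaustive cross-pair scan
    set.seed(5)
    for (r in 1:10) {
        rb <- randomTruthBlock(6, coverage = 25)
        t2 <- scorePairs(rb$block)
        n <- nSites(rb$block)
        X <- sort(sample(n, 2L))
        Y <- setdiff(seq_len(n), X)
        sc <- clusterScore(t2, X, Y)
        cross <- t2[(t2$i %in% X) != (t2$j %in% X), ]
        if (nrow(cross)) expect_equal(sc$score, max(cross$cs))
        else expect_true(is.na(sc$score))
    }
})

test_that("merge selection prefers high scores, then proximity", {
    # two independent site pairs with different support, linked weakly
    blk <- mkBlock(c("00--", "00--", "00--", "--00", "--00", "-00-"),
                   pos = c(100, 200, 300, 400))
    tbl <- scorePairs(blk)
    lead <- HierPhase:::.selectNextMerge(tbl, 1:4)
    best <- tbl[which.max(tbl$cs), ]
    expect_identical(c(lead$i, lead$j), c(best$i, best$j))
    # equal scores, different distances: the closer pair leads
    blk2 <- mkBlock(c("00-", "0-0", "00-", "0-0"), pos = c(0, 150, 900))
    t2 <- scorePairs(blk2)
    expect_equal(t2$cs[1L], t2$cs[2L], tolerance = 1e-12)
    lead2 <- HierPhase:::.selectNextMerge(t2, 1:3)
    expect_identical(c(lead2$i, lead2$j), c(1L, 2L))  # 150bp beats 900bp
})

test_that("singleton-led merges precede low-coverage ones when only ambiguous pairs remain", {
    # pair (1,2): singleton (all reads one cell); pair (2,3): low coverage
    blk <- mkBlock(c("00-", "00-", "00-", "00-", "-00", "-11"),
                   pos = c(100, 200, 300))
    tbl <- scorePairs(blk)
    expect_setequal(tbl$class, c("singleton", "low_coverage"))
    lead <- HierPhase:::.selectNextMerge(tbl, 1:3)
    expect_identical(tbl$class[tbl$i == lead$i & tbl$j == lead$j],
                     "singleton")
    pb <- assembleBlock(blk)
    expect_identical(mergeLog(pb)$pairClass[1L], "singleton")
})

test_that("merging joins sub-haplotypes by the higher-scoring pairing", {
    # clean cis signal across the leading pair
    blk <- mkBlock(c("00", "00", "00", "11", "11"), pos = c(10, 20))
    pb <- assembleBlock(blk)
    expect_identical(unname(haplotypes(pb)["hap1"]), "00")
    # counts (10,1,0,9) favour the cis pairing
    blk2 <- mkBlock(c("00", "01", "11"), counts = c(10L, 1L, 9L),
                    pos = c(10, 20))
    pb2 <- assembleBlock(blk2)
    expect_identical(unname(haplotypes(pb2)["hap1"]), "00")
    # trans-dominant counts flip the joined cluster
    blk3 <- mkBlock(c("01", "10"), counts = c(9L, 10L), pos = c(10, 20))
    expect_identical(unname(haplotypes(assembleBlock(blk3))["hap1"]),
                     "01")
})

test_that("three-variant noise-free block recovers truth via highest-CS-first merges", {
    blk <- mkBlock(c("01-", "01-", "011", "-11", "0-1", "100", "1-0"),
                   pos = c(100, 200, 300))
    pb <- assembleBlock(blk)
    expect_identical(unname(haplotypes(pb)["hap1"]), "011")
    ml <- mergeLog(pb)
    expect_identical(nrow(ml), 2L)
    # first merge uses the best-scoring non-ambiguous observed pair
    tbl <- scorePairs(blk)
    norm <- tbl[tbl$class == "normal", ]
    best <- norm[which.max(norm$cs), ]
    expect_identical(c(ml$siteX[1L], ml$siteY[1L]), c(best$i, best$j))
})

test_that("assembly performs exactly n-1 merges and is deterministic", {
    set.seed(21)
    rb <- randomTruthBlock(40, coverage = 25, seqError = 0.02)
    pb1 <- assembleBlock(rb$block)
    expect_identical(nrow(mergeLog(pb1)), nSites(rb$block) - 1L)
    pb2 <- assembleBlock(rb$block)
    expect_identical(mergeLog(pb1), mergeLog(pb2))
    expect_identical(pb1@hap1, pb2@hap1)
})

test_that("assembly output is invariant to fragment order and relabeling", {
    set.seed(31)
    rb <- randomTruthBlock(25, coverage = 25, seqError = 0.02)
    blk <- rb$block
    pb <- assembleBlock(blk)
    perm <- sample(length(blk@fragments))
    blkP <- variantBlock(blk@sites, blk@fragments[perm], blk@siteIndex)
    pbP <- assembleBlock(blkP)
    expect_identical(pb@hap1, pbP@hap1)  # canonical orientation
})

test_that("embedded merges trigger the local MEC search", {
    # strong balanced pairs knit {1,3,5} and {2,4} first; the final
    # merge fully interleaves them (4 junctions)
    blk <- mkBlock(c("0-0-0", "1-1-1", "-0-0-", "-1-1-", "00000"),
                   counts = c(6L, 6L, 6L, 6L, 2L),
                   pos = c(10, 20, 30, 40, 50))
    pb <- assembleBlock(blk, minJunctions = 3L)
    ml <- mergeLog(pb)
    expect_true(any(ml$mechanism == "mec_junction" & ml$junctions >= 3L))
    expect_identical(unname(haplotypes(pb)["hap1"]), "00000")
    # with a high threshold the same block assembles score-guided
    pb2 <- assembleBlock(blk, minJunctions = 10L)
    expect_false(any(mergeLog(pb2)$mechanism == "mec_junction"))
})

test_that("ambiguous-pair merges with two junctions invoke local MEC", {
    # the balanced pair (1,3) assembles first; the remaining merge of
    # {1,3} with the embedded site 2 is led by a singleton pair with
    # 2 junctions, firing the block-scope MEC vote
    blk <- mkBlock(c("0-0", "1-1", "00-"), counts = c(5L, 5L, 1L),
                   pos = c(10, 20, 30))
    pb <- assembleBlock(blk)
    ml <- mergeLog(pb)
    expect_identical(ml$mechanism[2L], "mec_ambiguous")
    expect_identical(ml$junctions[2L], 2L)
    expect_identical(unname(haplotypes(pb)["hap1"]), "000")
})

test_that("exact score ties fall back to the MEC vote", {
    # fully symmetric table on the only pair: CS1 = CS2 and the two MEC
    # penalties tie as well -> S1 kept, flagged low confidence
    blk <- mkBlock(c("00", "11", "01", "10"), counts = 5L)
    pb <- assembleBlock(blk)
    ml <- mergeLog(pb)
    expect_identical(ml$mechanism, "mec_tie")
    expect_true(ml$lowConfidence)
    expect_identical(ml$penaltyS1, ml$penaltyS2)
})

test_that("noise-free random blocks up to 200 sites recover the truth", {
    set.seed(97)
    for (n in c(10L, 60L, 200L)) {
        rb <- randomTruthBlock(n, coverage = 25, seqError = 0)
        pb <- assembleBlock(rb$block)
        cmp <- countSwitchFlip(pb@hap1, rb$truthHap)
        expect_identical(cmp$switch + cmp$flip, 0L)
    }
})

test_that("merge log export writes one row per merge", {
    set.seed(13)
    rb <- randomTruthBlock(10)
    pb <- assembleBlock(rb$block)
    f <- tempfile(fileext = ".tsv")
    writeMergeLog(pb, f)
    tab <- read.delim(f)
    expect_identical(nrow(tab), nSites(rb$block) - 1L)
    expect_true(all(c("mechanism", "cs1", "cs2", "junctions") %in%
                    names(tab)))
})
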