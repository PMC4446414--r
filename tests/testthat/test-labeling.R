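# Two genes [11,110] and [211,310] (+) with a 100 bp intergenic region;
# coverage is laid out per test to hit the gap/fold-change thresholds.
twoGeneAnn <- makeAnn(c(11, 211), c(110, 310), c("+", "+"), L = 400L)

twoGeneTrack <- function(leftCov, rightCov, irCovered) {
    v <- integer(400)
    v[11:110] <- leftCov
    v[211:310] <- rightCov
    # irCovered = fraction of the 100 bp IR with nonzero signal
    k <- round(100 * irCovered)
    if (k > 0) v[111:(110 + k)] <- 1L
    makeTrack(v)
}

test_that("negative selection requires both gap and fold-change", {
    pairs <- deriveGenePairs(twoGeneAnn)
    # gap 0.6, ratio (120+1)/(10+1) = 11 > 10 -> negative
    neg <- selectNegativePairs(pairs, twoGeneTrack(120L, 10L, 0.4))
    expect_identical(nrow(neg), 1L)
    expect_identical(neg$label, "negative")
    expect_identical(neg$source, "gap_filter")
    # gap 0.6 but ratio ~5 -> rejected (conjunction)
    expect_identical(
        nrow(selectNegativePairs(pairs, twoGeneTrack(50L, 10L, 0.4))), 0L)
    # gap exactly 0.5 -> rejected (strict >)
    expect_identical(
        nrow(selectNegativePairs(pairs, twoGeneTrack(120L, 10L, 0.5))), 0L)
    # ratio exactly 10 -> rejected (strict >): (109+1)/(10+1) = 10
    expect_identical(
        nrow(selectNegativePairs(pairs, twoGeneTrack(109L, 10L, 0.4))), 0L)
})

test_that("spanning positives need full IR containment and ratio <= 2", {
    pairs <- deriveGenePairs(twoGeneAnn)
    tr <- twoGeneTrack(30L, 20L, 1)     # ratio (31)/(21) = 1.476
    spanning <- GRanges("chrT", IRanges(100, 320), strand = "*")
    pos <- selectPositivePairs(pairs, spanning, tr)
    expect_identical(nrow(pos), 1L)
    expect_identical(pos$source, "long_read")
    # ratio exactly 2 is still accepted: (41+1)/(20+1) = 2
    tr2 <- twoGeneTrack(41L, 20L, 1)
    expect_identical(nrow(selectPositivePairs(pairs, spanning, tr2)), 1L)
    # partial IR coverage by the evidence read is not enough
    partial <- GRanges("chrT", IRanges(150, 320), strand = "*")
    expect_identical(nrow(selectPositivePairs(pairs, partial, tr)), 0L)
    # evidence on the wrong strand does not count
    wrong <- GRanges("chrT", IRanges(100, 320), strand = "-")
    expect_identical(nrow(selectPositivePairs(pairs, wrong, tr)), 0L)
    # ratio just above 2 is rejected
    tr3 <- twoGeneTrack(43L, 20L, 1)
    expect_identical(nrow(selectPositivePairs(pairs, spanning, tr3)), 0L)
})

test_that("negative and positive labeled sets are disjoint", {
    set.seed(404)
    for (rep in 1:5) {
        ann <- randomAnn(20L)
        tr <- randomTrack(genomeLength(ann))
        pairs <- deriveGenePairs(ann)
        ev <- GRanges(genomeId(ann),
                      IRanges(sample.int(genomeLength(ann) - 100L, 30L),
                              width = 100L), strand = "*")
        neg <- selectNegativePairs(pairs, tr)
        pos <- selectPositivePairs(pairs, ev, tr)
        key <- function(d) paste(d$strand, d$leftId, d$rightId)
        expect_length(intersect(key(neg), key(pos)), 0L)
    }
})

test_that("length-ratio densities compute the documented ratios", {
    # plus pairs (|ir|,|gl|,|gr|) = (100,400,500) and (100,500,300); the
    # first gives ir ratio 0.1 and gd ratio 0.1; minus genes kept clear
    # of the plus intergenic regions so all pairs stay eligible
    ann <- makeAnn(c(1, 501, 1101, 2001, 2401, 2801),
                   c(400, 1000, 1400, 2300, 2700, 3100),
                   c("+", "+", "+", "-", "-", "-"), L = 3500L)
    d <- fitLengthDensities(ann)
    expect_equal(d[["+"]]$ir[1], 100 / (100 + 400 + 500))
    expect_equal(d[["+"]]$gd[1], 100 / (100 + 400 + 500))
    expect_true(all(d[["+"]]$ir >= 0 & d[["+"]]$ir <= 1))
    expect_true(all(d[["-"]]$gd >= 0 & d[["-"]]$gd <= 1))
})

test_that("density fitting needs two eligible pairs per strand", {
    ann <- makeAnn(c(1, 201, 401, 601, 801, 1001),
                   c(100, 300, 500, 700, 900, 1100),
                   c("+", "+", "+", "-", "-", "-"), L = 1200L)
    expect_silent(fitLengthDensities(ann))
    # a single consecutive pair on the plus strand is not enough
    ann1 <- makeAnn(c(1, 201, 601, 801, 1001),
                    c(100, 300, 700, 900, 1100),
                    c("+", "+", "-", "-", "-"), L = 1200L)
    expect_error(fitLengthDensities(ann1), "insufficient pairs")
})

test_that("density sampling is seeded and mean-consistent", {
    obs <- c(0.05, 0.1, 0.2, 0.4)
    a <- withr::with_seed(7, sampleDensity(obs, 100))
    b <- withr::with_seed(7, sampleDensity(obs, 100))
    expect_identical(a, b)
    draws <- withr::with_seed(8, sampleDensity(obs, 1e4))
    se <- stats::sd(obs) / sqrt(1e4)
    expect_lt(abs(mean(draws) - mean(obs)), 3 * se)
})

test_that("cIR is placed on the exact minimum-GC window", {
    # gene of 1000 bp: GGGG-rich except a 300 bp A-run at offsets 350-649
    geneSeq <- paste0(strrep("G", 350), strrep("A", 300), strrep("G", 350))
    ann <- gcPlacementFixture(geneSeq)
    tr <- makeTrack(rep(5L, genomeLength(ann)),
                    rep(5L, genomeLength(ann)))
    dens <- list(
        "+" = list(ir = c(0.3, 0.3), gd = c(0.6, 0.6)),
        "-" = list(ir = c(0.3, 0.3), gd = c(0.6, 0.6)))
    ctu <- constructCTUs(ann, dens, tr, seed = 1)
    big <- ctu[ctu$sourceGeneId == "g03", , drop = FALSE]
    expect_identical(nrow(big), 1L)
    L <- big$cirEnd - big$cirStart + 1L
    expect_identical(L, 300L)            # round(0.3 * 1000)
    # the 300 bp zero-GC window is offsets 350..649 -> start 501+350
    expect_identical(big$cirStart, 501L + 350L)
    expect_equal(big$cirGC, 0)
})

test_that("cIR placement equals exhaustive window scan on random genes", {
    set.seed(405)
    for (rep in 1:50) {
        glen <- sample(800:1200, 1L)
        geneSeq <- paste(sample(c("A", "C", "G", "T"), glen,
                                replace = TRUE), collapse = "")
        ann <- gcPlacementFixture(geneSeq, glen)
        tr <- makeTrack(rep(5L, genomeLength(ann)),
                        rep(5L, genomeLength(ann)))
        p <- runif(1, 0.24, 0.4); q <- runif(1, 0.2, 0.6)
        dens <- list("+" = list(ir = c(p, p), gd = c(q, q)),
                     "-" = list(ir = c(p, p), gd = c(q, q)))
        ctu <- constructCTUs(ann, dens, tr, seed = rep)
        big <- ctu[ctu$sourceGeneId == "g03", , drop = FALSE]
        if (nrow(big) == 0L) next
        L <- big$cirEnd - big$cirStart + 1L
        m <- glen / 2
        jMin <- max(1L, ceiling(m - p * glen / 2 - q * glen / 2))
        jMax <- min(glen - L - 1L, floor(m - p * glen / 2 + q * glen / 2))
        bf <- bruteMinGCStart(paste0(strrep("AT", 250), geneSeq),
                              501L, glen, L, jMin, jMax)
        expect_identical(big$cirStart - 501L, as.integer(bf["start"]))
        expect_equal(big$cirGC, unname(bf["gc"]), tolerance = 1e-12)
    }
})

test_that("emitted constructed pairs satisfy all exclusion filters", {
    set.seed(406)
    cfg <- simConfig(nGenes = 120L, depth = 40)
    truth <- simulateGenome(cfg, seed = 11)
    cov <- simulateCoverage(truth, seed = 12)
    ann <- truth@annotation
    dens <- fitLengthDensities(ann)
    ctu <- constructCTUs(ann, dens, cov$track, seed = 13)
    if (nrow(ctu) > 0L) {
        expect_true(all(ctu$gapFraction <= 0.5))
        expect_true(all(ctu$exprRatio <= 10))
        expect_true(all(ctu$cirEnd - ctu$cirStart + 1L >= 225L))
        # partition: flanks and cIR tile the source gene exactly
        g <- genes(ann)
        idx <- match(ctu$sourceGeneId, mcols(g)$gene_id)
        expect_identical(ctu$leftStart, start(g)[idx])
        expect_identical(ctu$rightEnd, end(g)[idx])
        expect_identical(ctu$cirStart, ctu$leftEnd + 1L)
        expect_identical(ctu$rightStart, ctu$cirEnd + 1L)
        expect_true(all(ctu$leftEnd >= ctu$leftStart))
        expect_true(all(ctu$rightEnd >= ctu$rightStart))
    }
    # seeded runs reproduce bit-identically
    ctu2 <- constructCTUs(ann, dens, cov$track, seed = 13)
    expect_identical(as.data.frame(ctu), as.data.frame(ctu2))
})

test_that("a cIR shorter than the long-read span is discarded", {
    geneSeq <- paste0(strrep("G", 450), strrep("A", 100), strrep("G", 450))
    ann <- gcPlacementFixture(geneSeq)
    tr <- makeTrack(rep(5L, genomeLength(ann)),
                    rep(5L, genomeLength(ann)))
    dens <- list("+" = list(ir = c(0.1, 0.1), gd = c(0.4, 0.4)),
                 "-" = list(ir = c(0.1, 0.1), gd = c(0.4, 0.4)))
    ctu <- constructCTUs(ann, dens, tr, seed = 2)  # L = 100 < 225
    expect_identical(nrow(ctu[ctu$sourceGeneId == "g03", , drop = FALSE]),
                     0L)
})
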