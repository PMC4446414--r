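# Feature frames for classifier tests are built directly: two clusters in
# feature space, with the six named junction features.
featFrame <- function(n, center) {
    as.data.frame(setNames(lapply(seq_along(center), function(j)
        center[j] + rnorm(n, 0, 0.05)),
        c("gapCount", "gapFraction", "log2FcLeftIr", "log2FcRightIr",
          "log2FcLeftRight", "normVariance")))
}

test_that("a separable training set cross-validates perfectly", {
    set.seed(606)
    pos <- featFrame(60, c(0, 0, 0, 0, 0, 0))
    neg <- featFrame(60, c(40, 1, 4, 4, 4, 3))
    m <- trainTUModel(rbind(pos, neg),
                      rep(c("positive", "negative"), each = 60),
                      seed = 1)
    expect_equal(cvAccuracy(m), 1.0)
    # training points re-predicted correctly after perfect separation
    pr <- predictPairs(m, rbind(pos, neg))
    expect_identical(pr$label, rep(c("positive", "negative"), each = 60))
    expect_true(all(pr$score[1:60] > 0))
    expect_true(all(pr$score[61:120] < 0))
})

test_that("permuted labels give chance-level cross-validation", {
    set.seed(607)
    x <- featFrame(400, c(0, 0, 0, 0, 0, 0))
    y <- sample(rep(c("positive", "negative"), each = 200))
    m <- trainTUModel(x, y, seed = 2)
    expect_lt(abs(cvAccuracy(m) - 0.5), 0.08)
})

test_that("training is seeded and order-invariant", {
    set.seed(608)
    x <- rbind(featFrame(40, rep(0, 6)), featFrame(40, rep(2, 6)))
    y <- rep(c("positive", "negative"), each = 40)
    m1 <- trainTUModel(x, y, seed = 9)
    m2 <- trainTUModel(x, y, seed = 9)
    expect_identical(cvAccuracy(m1), cvAccuracy(m2))
    expect_identical(m1@foldPredictions, m2@foldPredictions)
    # permuting example order does not change CV accuracy (same seed,
    # stratified folds)
    perm <- sample(80)
    m3 <- trainTUModel(x[perm, ], y[perm], seed = 9)
    expect_equal(cvAccuracy(m3), cvAccuracy(m1))
})

test_that("degenerate training sets are rejected", {
    x <- featFrame(20, rep(0, 6))
    expect_error(trainTUModel(x, rep("positive", 20)),
                 "degenerate training set")
    expect_error(predictPairs(
        trainTUModel(rbind(x, featFrame(20, rep(2, 6))),
                     rep(c("positive", "negative"), each = 20), seed = 1),
        data.frame(bogus = 1)), "feature dimension mismatch")
})

test_that("decision scores fall with widening coverage gaps", {
    # train on junctions whose only informative feature is the gap, then
    # sweep gapFraction: scores must decrease monotonically overall
    set.seed(609)
    pos <- featFrame(80, c(5, 0.05, 0, 0, 0, 0.2))
    neg <- featFrame(80, c(80, 0.9, 0, 0, 0, 0.2))
    m <- trainTUModel(rbind(pos, neg),
                      rep(c("positive", "negative"), each = 80), seed = 3)
    sweep <- featFrame(9, c(0, 0, 0, 0, 0, 0.2))
    sweep$gapFraction <- seq(0.05, 0.9, length.out = 9)
    sweep$gapCount <- round(100 * sweep$gapFraction)
    sc <- predictPairs(m, sweep)$score
    expect_lt(stats::cor(sweep$gapFraction, sc, method = "spearman"),
              -0.9)
})

test_that("TU assembly chains positive junctions into maximal runs", {
    ann <- makeAnn(c(1, 201, 401), c(100, 300, 500), rep("+", 3))
    pairs <- deriveGenePairs(ann)
    pairs$label <- c("positive", "negative")
    ts <- assembleTUs(ann, pairs)
    tt <- tuTable(ts)
    expect_identical(nrow(tt), 2L)
    expect_identical(as.list(tt$geneIds),
                     list(c("g01", "g02"), "g03"))
    expect_identical(tt$start, c(1L, 401L))
    expect_identical(tt$end, c(300L, 500L))

    # 5-gene chain all positive -> one TU
    ann5 <- makeAnn(seq(1, 1601, by = 400), seq(300, 1900, by = 400),
                    rep("+", 5))
    p5 <- deriveGenePairs(ann5)
    p5$label <- rep("positive", 4)
    tt5 <- tuTable(assembleTUs(ann5, p5))
    expect_identical(nrow(tt5), 1L)
    expect_identical(tt5$nGenes, 5L)

    # all negative -> all singletons
    p5$label <- rep("negative", 4)
    dist <- tuSizeDistribution(assembleTUs(ann5, p5))
    expect_equal(unname(dist["1"]), 100)
})

test_that("assembled TUs always partition the gene set", {
    set.seed(610)
    for (rep in 1:20) {
        ann <- randomAnn(15L)
        ts <- randomTUSet(ann)
        ids <- unlist(tuTable(ts)$geneIds)
        expect_setequal(ids, mcols(genes(ann))$gene_id)
        expect_identical(anyDuplicated(ids), 0L)
        expect_identical(sum(tuTable(ts)$nGenes), length(genes(ann)))
        d <- tuSizeDistribution(ts)
        expect_equal(sum(d), 100)
    }
})

test_that("TU size histogram matches a direct tally", {
    ann <- makeAnn(seq(1, 2001, by = 400), seq(300, 2300, by = 400),
                   rep("+", 6))
    p <- deriveGenePairs(ann)
    p$label <- c("positive", "negative", "negative", "negative",
                 "positive")
    d <- tuSizeDistribution(assembleTUs(ann, p))
    # sizes 2,1,1,2 -> 50% size-1, 50% size-2
    expect_equal(unname(d["1"]), 50)
    expect_equal(unname(d["2"]), 50)
    expect_equal(sum(d), 100)
    expect_error(tuSizeDistribution(
        TUSet("chrT", DataFrame(tuId = character(), strand = character(),
                                start = integer(), end = integer(),
                                nGenes = integer(),
                                geneIds = CharacterList()))),
        "empty")
})

test_that("splitting on interleaved opposite-strand genes is optional", {
    ann <- makeAnn(c(1, 201, 401), c(100, 300, 500), c("+", "-", "+"))
    pairs <- deriveGenePairs(ann)
    pairs$label <- "positive"
    joinedDefault <- tuTable(assembleTUs(ann, pairs))
    expect_identical(max(joinedDefault$nGenes), 2L)
    forcedSplit <- tuTable(assembleTUs(ann, pairs,
                                       splitOnOpposite = TRUE))
    expect_identical(max(forcedSplit$nGenes), 1L)
})

test_that("ROC endpoints and chance level behave as required", {
    truth <- rep(c("positive", "negative"), each = 50)
    perfect <- c(runif(50, 1, 2), runif(50, -2, -1))
    expect_equal(rocCurve(truth, perfect)$auc, 1.0)
    expect_equal(rocCurve(truth, -perfect)$auc, 0.0)
    set.seed(611)
    truthBig <- rep(c("positive", "negative"), each = 500)
    rnd <- rocCurve(truthBig, rnorm(1000))
    expect_lt(abs(rnd$auc - 0.5), 0.05)
    expect_error(rocCurve(rep("positive", 10), rnorm(10)),
                 "single-class")
    # agreement with a rank-statistic computation
    sc <- rnorm(1000)
    expect_equal(rocCurve(truthBig, sc)$auc, bruteAUC(truthBig, sc),
                 tolerance = 1e-12)
})
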