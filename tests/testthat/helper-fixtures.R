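# Fixture builders and independent brute-force oracles. The oracles
# deliberately use naive per-position loops so they share no code with
# the implementation they check.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
    library(IRanges)
    library(Biostrings)
})

makeAnn <- function(starts, ends, strands, L = max(ends) + 50L,
                    ids = sprintf("g%02d", seq_along(starts)),
                    genomeId = "chrT", sequence = NULL) {
    gr <- GRanges(genomeId, IRanges(starts, ends), strand = strands)
    mcols(gr)$gene_id <- ids
    GenomeAnnotation(genomeId, L, gr, sequence = sequence)
}

makeTrack <- function(plus, minus = rep(0L, length(plus)),
                      genomeId = "chrT") {
    CoverageTrack(genomeId, plus, minus)
}

# Random annotation of n same-strand-mixed genes on a genome of length L.
randomAnn <- function(n, L = 2000L, minLen = 20L, maxLen = 80L,
                      gapMax = 60L) {
    pos <- 1L + sample.int(gapMax, 1L)
    starts <- integer(n); ends <- integer(n)
    for (i in seq_len(n)) {
        len <- sample(minLen:maxLen, 1L)
        starts[i] <- pos
        ends[i] <- pos + len - 1L
        pos <- ends[i] + 1L + sample.int(gapMax, 1L)
    }
    L <- max(L, pos + 50L)
    makeAnn(starts, ends, sample(c("+", "-"), n, replace = TRUE), L = L)
}

randomTrack <- function(L, maxCov = 5L, zeroProb = 0.3,
                        genomeId = "chrT") {
    draw <- function() {
        v <- sample(0:maxCov, L, replace = TRUE)
        v[runif(L) < zeroProb] <- 0L
        as.integer(v)
    }
    CoverageTrack(genomeId, draw(), draw())
}

# Annotation whose third (large, +) gene has a designed GC landscape,
# surrounded by smaller genes; used for pseudo-IR placement checks.
gcPlacementFixture <- function(geneSeq, glen = nchar(geneSeq)) {
    pre <- strrep("AT", 250)  # 500 bp before the gene
    post <- strrep("AT", 500)
    seqChar <- paste0(pre, geneSeq, post)
    L <- nchar(seqChar)
    makeAnn(c(1, 201, 501, 501 + glen + 99, 1, 301),
            c(150, 400, 500 + glen, 500 + glen + 300, 200, 450),
            c("+", "+", "+", "+", "-", "-"),
            L = L, sequence = Biostrings::DNAString(seqChar))
}

# --- brute-force oracles -------------------------------------------------

bruteCoverage <- function(starts, ends, strands, L) {
    plus <- integer(L); minus <- integer(L)
    for (i in seq_along(starts)) {
        for (p in starts[i]:ends[i]) {
            if (strands[i] == "+") plus[p] <- plus[p] + 1L
            else minus[p] <- minus[p] + 1L
        }
    }
    list(plus = plus, minus = minus)
}

bruteDepth <- function(plus, minus, geneStarts, geneEnds) {
    L <- length(plus)
    coding <- logical(L)
    for (i in seq_along(geneStarts))
        coding[geneStarts[i]:geneEnds[i]] <- TRUE
    (sum(plus) + sum(minus)) / sum(coding)
}

bruteCoveredFraction <- function(v, starts, ends) {
    inreg <- logical(length(v))
    for (i in seq_along(starts)) inreg[starts[i]:ends[i]] <- TRUE
    mean(v[inreg] >= 1)
}

bruteAntisense <- function(plus, minus, starts, ends, strands) {
    sense <- 0; anti <- 0
    for (i in seq_along(starts)) {
        idx <- starts[i]:ends[i]
        if (strands[i] == "+") {
            sense <- sense + sum(plus[idx]); anti <- anti + sum(minus[idx])
        } else {
            sense <- sense + sum(minus[idx]); anti <- anti + sum(plus[idx])
        }
    }
    anti / sense
}

bruteGap <- function(v, s, e) {
    if (e < s) return(c(0L, 0))
    idx <- s:e
    c(sum(v[idx] == 0), mean(v[idx] == 0))
}

bruteVarianceFeatures <- function(v, ls, le, is, ie, rs, re) {
    m <- function(s, e) if (e < s) 0 else mean(v[s:e])
    span <- v[min(ls, rs):max(le, re)]
    c(log2((m(ls, le) + 1) / (m(is, ie) + 1)),
      log2((m(rs, re) + 1) / (m(is, ie) + 1)),
      log2((m(ls, le) + 1) / (m(rs, re) + 1)),
      stats::var(span / (mean(span) + 1)))
}

# Exhaustive minimum-GC window search over all feasible cIR starts.
bruteMinGCStart <- function(seqChar, geneStart, geneLen, L, jMin, jMax) {
    best <- NULL; bestGC <- Inf
    for (j in jMin:jMax) {
        w <- substr(seqChar, geneStart + j, geneStart + j + L - 1L)
        gc <- sum(strsplit(w, "")[[1]] %in% c("G", "C")) / L
        if (gc < bestGC - 1e-12) { bestGC <- gc; best <- j }
    }
    c(start = best, gc = bestGC)
}

# Confirmed TUs by naive scan: for each read, each maximal run of
# consecutive same-strand genes fully inside it.
bruteConfirmed <- function(evStarts, evEnds, evStrands, ann) {
    g <- genes(ann)
    out <- character(0)
    for (st in c("+", "-")) {
        gs <- g[as.character(strand(g)) == st]
        if (length(gs) == 0L) next
        ids <- mcols(gs)$gene_id
        for (k in seq_along(evStarts)) {
            if (!(evStrands[k] %in% c("*", st))) next
            inside <- start(gs) >= evStarts[k] & end(gs) <= evEnds[k]
            run <- character(0)
            for (i in seq_along(gs)) {
                if (inside[i]) run <- c(run, ids[i])
                else if (length(run)) {
                    out <- c(out, paste(c(st, run), collapse = "|"))
                    run <- character(0)
                }
            }
            if (length(run))
                out <- c(out, paste(c(st, run), collapse = "|"))
        }
    }
    sort(unique(out))
}

# Rank-statistic AUC (Mann-Whitney), independent of pROC.
bruteAUC <- function(truth, scores) {
    pos <- scores[truth == "positive"]; neg <- scores[truth == "negative"]
    cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
    mean(cmp)
}

# Random TUSet over an annotation: random junction cuts per strand.
randomTUSet <- function(ann, pCut = 0.5, id = "rnd") {
    pairs <- deriveGenePairs(ann)
    lab <- ifelse(runif(nrow(pairs)) < pCut, "negative", "positive")
    pairs$label <- lab
    assembleTUs(ann, pairs, datasetId = id)
}
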