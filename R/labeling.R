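# Training-data construction: negatives by gap/fold-change filters,
# positives by spanning long-read evidence, and additional positives by
# carving a pseudo intergenic region (cIR) out of single genes at the
# GC-minimal position.

# Per-pair coverage summaries used by the label filters.
pairExpression <- function(pairs, track) {
    pre <- trackPrefix(track)
    st <- pairs$strand
    meanL <- intervalMean(pre, st, pairs$leftStart, pairs$leftEnd)
    meanR <- intervalMean(pre, st, pairs$rightStart, pairs$rightEnd)
    ir <- intervalStats(pre, st, pairs$irStart, pairs$irEnd)
    gapFraction <- ifelse(ir$n > 0L, ir$zero / ir$n, 0)
    list(meanLeft = meanL, meanRight = meanR,
         ratio = exprRatio(meanL, meanR), gapFraction = gapFraction)
}

#' Select negative training pairs (separate-TU junctions)
#'
#' A consecutive same-strand gene pair is labeled a confident
#' non-co-transcribed (negative) example when both hold: more than half
#' of its intergenic positions have zero abundance, and the two genes'
#' mean expression levels differ by more than `ratioThreshold`-fold
#' (ratio of means with pseudocount 1). Both thresholds are strict.
#'
#' @param pairs candidate junctions from [deriveGenePairs()].
#' @param track a [CoverageTrack-class].
#' @param gapThreshold minimum (exclusive) zero-coverage fraction of the
#'   intergenic region; default 0.5.
#' @param ratioThreshold minimum (exclusive) expression fold change;
#'   default 10.
#' @return The selected rows of `pairs` with added columns `label`
#'   (`"negative"`), `source` (`"gap_filter"`), `gapFraction`, `exprRatio`.
#' @export
selectNegativePairs <- function(pairs, track, gapThreshold = 0.5,
                                ratioThreshold = 10) {
    ex <- pairExpression(pairs, track)
    keep <- ex$gapFraction > gapThreshold & ex$ratio > ratioThreshold
    out <- pairs[keep, , drop = FALSE]
    out$label <- rep("negative", sum(keep))
    out$source <- rep("gap_filter", sum(keep))
    out$gapFraction <- ex$gapFraction[keep]
    out$exprRatio <- ex$ratio[keep]
    out
}

#' Select positive training pairs from spanning evidence
#'
#' A pair is labeled co-transcribed (positive) when a single long read or
#' paired-end fragment span fully contains its intergenic region and the
#' two genes' expression levels are within `ratioThreshold`-fold
#' (inclusive). For abutting or overlapping genes the junction point must
#' be spanned.
#'
#' @param pairs candidate junctions from [deriveGenePairs()].
#' @param evidence `GRanges` of long-read or fragment spans (strand `"*"`
#'   matches both strands, as for non-strand-specific long reads).
#' @param track a [CoverageTrack-class].
#' @param ratioThreshold maximum (inclusive) expression fold change;
#'   default 2.
#' @return The selected rows of `pairs` with `label` (`"positive"`),
#'   `source` (`"long_read"`), `gapFraction`, `exprRatio` columns.
#' @export
selectPositivePairs <- function(pairs, evidence, track,
                                ratioThreshold = 2) {
    ex <- pairExpression(pairs, track)
    est <- as.character(strand(evidence))
    es <- start(evidence); ee <- end(evidence)
    covered <- vapply(seq_len(nrow(pairs)), function(i) {
        ok <- est == "*" | est == pairs$strand[i]
        if (!any(ok)) return(FALSE)
        if (pairs$irLength[i] > 0L) {
            qs <- pairs$irStart[i]; qe <- pairs$irEnd[i]
        } else {
            # no intergenic bases: require the junction itself be spanned
            qs <- min(pairs$leftEnd[i], pairs$rightStart[i])
            qe <- max(pairs$leftEnd[i], pairs$rightStart[i])
        }
        any(es[ok] <= qs & ee[ok] >= qe)
    }, logical(1))
    keep <- covered & ex$ratio <= ratioThreshold
    out <- pairs[keep, , drop = FALSE]
    out$label <- rep("positive", sum(keep))
    out$source <- rep("long_read", sum(keep))
    out$gapFraction <- ex$gapFraction[keep]
    out$exprRatio <- ex$ratio[keep]
    out
}

#' Empirical length-ratio distributions of intergenic regions
#'
#' For every strand, over consecutive same-strand gene pairs with no
#' opposite-strand gene in between, collects two families of ratios with
#' common denominator `|ir| + |g_left| + |g_right|`:
#' the intergenic-length ratio `|ir| / denom` ("ir") and the
#' gene-length-difference ratio `||g_left| - |g_right|| / denom` ("gd").
#' These empirical distributions drive the probabilistic sizing of pseudo
#' intergenic regions; sampling resamples the observations with
#' replacement (assumption-free, no smoothing).
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param pairs optionally precomputed [deriveGenePairs()] output.
#' @return A list with elements `"+"` and `"-"`, each a list of numeric
#'   vectors `ir` and `gd` (observations in `[0, 1]`).
#' @export
fitLengthDensities <- function(annotation, pairs = NULL) {
    if (is.null(pairs)) pairs <- deriveGenePairs(annotation)
    out <- list()
    for (st in c("+", "-")) {
        p <- pairs[pairs$strand == st & !pairs$oppositeBetween, ,
                   drop = FALSE]
        if (nrow(p) < 2L)
            stop("insufficient pairs for density on strand ", st,
                 call. = FALSE)
        lenL <- p$leftEnd - p$leftStart + 1L
        lenR <- p$rightEnd - p$rightStart + 1L
        denom <- p$irLength + lenL + lenR
        out[[st]] <- list(ir = p$irLength / denom,
                          gd = abs(lenL - lenR) / denom)
    }
    out
}

#' Draw from an empirical length-ratio distribution
#'
#' @param observations numeric vector of observed ratios.
#' @param n number of draws.
#' @return `n` values resampled with replacement (uses the current RNG
#'   state; seed externally for reproducibility).
#' @export
sampleDensity <- function(observations, n = 1L) {
    stopIfNot(length(observations) >= 2L,
              "insufficient pairs for density")
    observations[sample.int(length(observations), n, replace = TRUE)]
}

#' Construct pseudo gene pairs (cTUs) inside single genes
#'
#' For every gene, draws an intergenic-length ratio `p` and a
#' gene-length-difference ratio `q` from the strand's empirical
#' distributions ([fitLengthDensities()]), and carves a pseudo intergenic
#' region (cIR) of length `round(p * |g|)` out of the gene at the
#' GC-minimal position: candidate cIR start offsets range over
#' `[m - p|g|/2 - q|g|/2, m - p|g|/2 + q|g|/2]` around the gene midpoint
#' `m` (clamped so both flanks keep at least 1 bp), and the start
#' minimizing the GC fraction of the cIR window is chosen (leftmost on
#' ties). The remaining 5' and 3' parts of the gene act as pseudo flanking
#' genes. Since an expressed gene is transcribed as one molecule, the
#' resulting triplet mimics a genuinely co-transcribed gene pair and is
#' used as positive training data.
#'
#' A constructed pair is kept only if its cIR zero-coverage fraction is
#' <= `gapThreshold`, its flank expression ratio is <= `ratioThreshold`,
#' and the cIR is at least `minCIRLength` bp long (so constructed
#' positives extend beyond what spanning reads can certify). Genes too
#' short to partition are skipped.
#'
#' @param annotation a [GenomeAnnotation-class] carrying the genome
#'   sequence (needed for GC).
#' @param densities output of [fitLengthDensities()].
#' @param track a [CoverageTrack-class].
#' @param seed optional integer seed for the p/q draws.
#' @param minCIRLength minimum cIR length in bp (default 225, the typical
#'   long-read length these constructed examples must exceed).
#' @param gapThreshold maximum cIR zero-coverage fraction (default 0.5).
#' @param ratioThreshold maximum flank expression ratio (default 10).
#' @return `DataFrame` with one row per kept constructed pair:
#'   `sourceGeneId`, `strand`, `p`, `q`, `leftStart`, `leftEnd`,
#'   `cirStart`, `cirEnd`, `rightStart`, `rightEnd`, `cirGC`.
#' @importFrom Biostrings DNAString
#' @export
constructCTUs <- function(annotation, densities, track, seed = NULL,
                          minCIRLength = 225L, gapThreshold = 0.5,
                          ratioThreshold = 10) {
    stopIfNot(!is.null(genomeSequence(annotation)),
              "genome sequence required for GC-based cIR placement")
    g <- genes(annotation)
    seqChar <- as.character(genomeSequence(annotation))
    isGC <- c(0, cumsum(strsplit(seqChar, "")[[1]] %in%
                        c("G", "C", "g", "c")))
    pre <- trackPrefix(track)
    withSeed(seed, {
        rows <- vector("list", length(g))
        for (i in seq_along(g)) {
            st <- as.character(strand(g))[i]
            gs <- start(g)[i]; glen <- width(g)[i]
            p <- sampleDensity(densities[[st]]$ir, 1L)
            q <- sampleDensity(densities[[st]]$gd, 1L)
            L <- as.integer(round(p * glen))
            # offsets are 0-based within the gene: cIR start offset j keeps
            # flanks [0, j-1] and [j+L, glen-1], each >= 1 bp
            if (L < 1L || L > glen - 2L) next
            m <- glen / 2
            X <- m - (p * glen) / 2 - (q * glen) / 2
            Y <- m - (p * glen) / 2 + (q * glen) / 2
            jMin <- max(1L, as.integer(ceiling(X)))
            jMax <- min(glen - L - 1L, as.integer(floor(Y)))
            if (jMax < jMin) {          # clamp window into the feasible range
                j0 <- max(1L, min(glen - L - 1L, as.integer(round(X))))
                jMin <- jMax <- j0
                if (jMin < 1L || jMin > glen - L - 1L) next
            }
            js <- jMin:jMax
            gc <- (isGC[gs + js + L] - isGC[gs + js]) / L
            j <- js[which.min(gc)]       # which.min takes the leftmost tie
            cirStart <- gs + j
            cirEnd <- cirStart + L - 1L
            flankL <- c(gs, cirStart - 1L)
            flankR <- c(cirEnd + 1L, gs + glen - 1L)
            rows[[i]] <- data.frame(
                sourceGeneId = mcols(g)$gene_id[i], strand = st,
                p = p, q = q,
                leftStart = flankL[1], leftEnd = flankL[2],
                cirStart = cirStart, cirEnd = cirEnd,
                rightStart = flankR[1], rightEnd = flankR[2],
                cirGC = min(gc), stringsAsFactors = FALSE)
        }
        rows <- rows[!vapply(rows, is.null, logical(1))]
        if (length(rows) == 0L) {
            emptyCTUFrame()
        } else {
            ctu <- DataFrame(do.call(rbind, rows))
            # exclusion filters: keep constructed pairs that look like real
            # co-transcribed pairs and exceed the long-read span
            stc <- ctu$strand
            meanL <- intervalMean(pre, stc, ctu$leftStart, ctu$leftEnd)
            meanR <- intervalMean(pre, stc, ctu$rightStart, ctu$rightEnd)
            ir <- intervalStats(pre, stc, ctu$cirStart, ctu$cirEnd)
            gapFrac <- ifelse(ir$n > 0L, ir$zero / ir$n, 0)
            ratio <- exprRatio(meanL, meanR)
            Lvec <- ctu$cirEnd - ctu$cirStart + 1L
            keep <- gapFrac <= gapThreshold & ratio <= ratioThreshold &
                Lvec >= minCIRLength
            out <- ctu[keep, , drop = FALSE]
            out$gapFraction <- gapFrac[keep]
            out$exprRatio <- ratio[keep]
            out
        }
    })
}

emptyCTUFrame <- function() {
    DataFrame(sourceGeneId = character(), strand = character(),
              p = numeric(), q = numeric(), leftStart = integer(),
              leftEnd = integer(), cirStart = integer(),
              cirEnd = integer(), rightStart = integer(),
              rightEnd = integer(), cirGC = numeric(),
              gapFraction = numeric(), exprRatio = numeric())
}
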