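# Junction features: expression continuity over the intergenic region and
# expression variance across the whole candidate region. All ratios and
# logs use a pseudocount of 1 because zero coverage is common at junction
# boundaries.

FEATURE_NAMES <- c("gapCount", "gapFraction", "log2FcLeftIr",
                   "log2FcRightIr", "log2FcLeftRight", "normVariance")

#' Continuity features of a region
#'
#' Counts positions with zero read abundance in a region on one strand,
#' and the fraction they make of the region length. A zero-length region
#' yields `(0, 0)`.
#'
#' @param track a [CoverageTrack-class].
#' @param start,end region bounds (1-based closed; `end < start` means an
#'   empty region). Vectorized.
#' @param strand `"+"` or `"-"` (recycled).
#' @return `data.frame` with columns `gapCount`, `gapFraction`.
#' @export
continuityFeatures <- function(track, start, end, strand) {
    pre <- trackPrefix(track)
    strand <- rep_len(strand, length(start))
    st <- intervalStats(pre, strand, as.integer(start), as.integer(end))
    data.frame(gapCount = as.integer(st$zero),
               gapFraction = ifelse(st$n > 0L, st$zero / st$n, 0))
}

#' Variance features of a candidate junction region
#'
#' Given the left flank, intergenic region and right flank of a candidate
#' junction (real gene pair or constructed pair), computes log2 fold
#' changes between the mean abundances of the three parts (pseudocount 1)
#' and the normalized variance of per-base abundance across the entire
#' candidate span: the sample variance of the abundance after dividing by
#' `mean + 1`, so that constant coverage gives exactly 0 and the statistic
#' is scale-free.
#'
#' @param track a [CoverageTrack-class].
#' @param leftStart,leftEnd,irStart,irEnd,rightStart,rightEnd interval
#'   bounds (vectorized; `irEnd < irStart` means an empty intergenic
#'   region).
#' @param strand `"+"` or `"-"` (recycled).
#' @return `data.frame` with `log2FcLeftIr`, `log2FcRightIr`,
#'   `log2FcLeftRight`, `normVariance`.
#' @export
varianceFeatures <- function(track, leftStart, leftEnd, irStart, irEnd,
                             rightStart, rightEnd, strand) {
    pre <- trackPrefix(track)
    n <- length(leftStart)
    strand <- rep_len(strand, n)
    mL <- intervalMean(pre, strand, as.integer(leftStart),
                       as.integer(leftEnd))
    mI <- intervalMean(pre, strand, as.integer(irStart),
                       as.integer(irEnd))
    mR <- intervalMean(pre, strand, as.integer(rightStart),
                       as.integer(rightEnd))
    spanS <- pmin(as.integer(leftStart), as.integer(rightStart))
    spanE <- pmax(as.integer(leftEnd), as.integer(rightEnd))
    stats <- intervalStats(pre, strand, spanS, spanE)
    mean <- ifelse(stats$n > 0L, stats$sum / stats$n, 0)
    varRaw <- ifelse(stats$n > 1L,
        (stats$sq - stats$sum^2 / pmax(stats$n, 1L)) /
            pmax(stats$n - 1L, 1L), 0)
    data.frame(
        log2FcLeftIr = log2((mL + 1) / (mI + 1)),
        log2FcRightIr = log2((mR + 1) / (mI + 1)),
        log2FcLeftRight = log2((mL + 1) / (mR + 1)),
        normVariance = varRaw / (mean + 1)^2)
}

#' Extract the junction feature vector
#'
#' Assembles the six junction features for a set of candidates: real gene
#' pairs ([deriveGenePairs()] rows) or constructed pairs
#' ([constructCTUs()] rows, whose `cirStart`/`cirEnd` play the role of
#' the intergenic region). Features are `gapCount` and `gapFraction`
#' (continuity of the intergenic region), `log2FcLeftIr`,
#' `log2FcRightIr`, `log2FcLeftRight` (fold changes between parts) and
#' `normVariance` (variance across the entire candidate span).
#' Extraction is deterministic and purely a function of the intervals and
#' the track.
#'
#' @param candidates a `DataFrame`/`data.frame` of gene pairs or
#'   constructed pairs.
#' @param track a [CoverageTrack-class].
#' @return `data.frame` with the six feature columns, one row per
#'   candidate.
#' @export
extractFeatures <- function(candidates, track) {
    cd <- as.data.frame(candidates)
    if ("cirStart" %in% colnames(cd)) {
        irS <- cd$cirStart; irE <- cd$cirEnd
    } else {
        irS <- cd$irStart; irE <- cd$irEnd
    }
    if (nrow(cd) == 0L) {
        out <- as.data.frame(setNames(
            rep(list(numeric(0)), length(FEATURE_NAMES)), FEATURE_NAMES))
        return(out)
    }
    cf <- continuityFeatures(track, irS, irE, cd$strand)
    vf <- varianceFeatures(track, cd$leftStart, cd$leftEnd, irS, irE,
                           cd$rightStart, cd$rightEnd, cd$strand)
    cbind(cf, vf)
}
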