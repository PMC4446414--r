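# Evaluation of predicted TU sets: long-read confirmed TUs and junction
# sensitivity, TU-set similarity, sequencing-depth resampling, and the
# inside/outside-TU intergenic expression contrast.

# Junction keys "strand\rleftId\rrightId" joined within the TUs of a set.
tuJunctionKeys <- function(tuset) {
    tt <- tuTable(tuset)
    multi <- tt[tt$nGenes > 1L, , drop = FALSE]
    if (nrow(multi) == 0L) return(character(0))
    unlist(lapply(seq_len(nrow(multi)), function(i) {
        ids <- multi$geneIds[[i]]
        paste(multi$strand[i], ids[-length(ids)], ids[-1], sep = "\r")
    }), use.names = FALSE)
}

#' Long-read confirmed TUs
#'
#' A run of same-strand genes is a confirmed TU when the entire span from
#' the first gene's start to the last gene's end lies within at least one
#' single evidence read (or fragment span). For each evidence interval,
#' every maximal run of consecutive same-strand genes fully contained in
#' it is recorded; identical runs from different reads are merged with
#' their support counts summed.
#'
#' @param evidence `GRanges` of long-read/fragment spans (strand `"*"`
#'   matches both strands).
#' @param annotation a [GenomeAnnotation-class].
#' @return `DataFrame` with `strand`, `geneIds` (`CharacterList`),
#'   `nGenes`, `supportingReadCount`, sorted for reproducibility
#'   (independent of read input order).
#' @export
confirmedTUs <- function(evidence, annotation) {
    g <- genes(annotation)
    runs <- character(0)
    est <- as.character(strand(evidence))
    for (st in c("+", "-")) {
        gs <- g[as.character(strand(g)) == st]
        if (length(gs) == 0L) next
        ids <- mcols(gs)$gene_id
        ev <- evidence[est == st | est == "*"]
        if (length(ev) == 0L) next
        for (k in seq_along(ev)) {
            contained <- which(start(gs) >= start(ev)[k] &
                               end(gs) <= end(ev)[k])
            if (length(contained) == 0L) next
            breaks <- c(0L, which(diff(contained) != 1L),
                        length(contained))
            for (b in seq_len(length(breaks) - 1L)) {
                run <- contained[(breaks[b] + 1L):breaks[b + 1L]]
                runs <- c(runs,
                          paste(c(st, ids[run]), collapse = "\r"))
            }
        }
    }
    if (length(runs) == 0L)
        return(DataFrame(strand = character(),
                         geneIds = CharacterList(),
                         nGenes = integer(),
                         supportingReadCount = integer()))
    tab <- table(runs)
    keys <- sort(names(tab))
    parts <- strsplit(keys, "\r", fixed = TRUE)
    DataFrame(
        strand = vapply(parts, `[`, character(1), 1L),
        geneIds = CharacterList(lapply(parts, `[`, -1L)),
        nGenes = lengths(parts) - 1L,
        supportingReadCount = as.integer(tab[keys]))
}

#' Junction sensitivity against confirmed TUs
#'
#' Fraction of confirmed TUs recovered by a prediction. A confirmed TU is
#' recovered when all of its genes lie consecutively within one predicted
#' TU, i.e. every internal junction of the confirmed run is predicted
#' co-transcribed (a confirmed TU may be a sub-run of a longer predicted
#' TU). Single-gene confirmed TUs are always recovered.
#'
#' @param predicted a [TUSet-class].
#' @param confirmed output of [confirmedTUs()] (or a ground-truth
#'   [TUSet-class], whose TUs then act as the confirmed runs).
#' @return Sensitivity in `[0, 1]`.
#' @export
tuSensitivity <- function(predicted, confirmed) {
    if (is(confirmed, "TUSet")) confirmed <- tuTable(confirmed)
    stopIfNot(nrow(confirmed) > 0L, "nothing to evaluate: no confirmed TUs")
    joined <- tuJunctionKeys(predicted)
    recovered <- vapply(seq_len(nrow(confirmed)), function(i) {
        ids <- confirmed$geneIds[[i]]
        if (length(ids) < 2L) return(TRUE)
        need <- paste(confirmed$strand[i], ids[-length(ids)], ids[-1],
                      sep = "\r")
        all(need %in% joined)
    }, logical(1))
    mean(recovered)
}

#' Similarity between two TU sets
#'
#' Agreement between two TU sets over the junctions they join: the
#' Jaccard index of the two sets of consecutive same-strand gene pairs
#' placed in one TU. Equals 1 for identical sets (and when neither set
#' joins any pair), 0 when no joined junction is shared; symmetric.
#'
#' @param a,b [TUSet-class] objects over the same annotation.
#' @return Similarity in `[0, 1]`.
#' @export
similarityScore <- function(a, b) {
    if (genomeId(a) != genomeId(b))
        stop("different annotations: TU sets are not comparable",
             call. = FALSE)
    ja <- unique(tuJunctionKeys(a))
    jb <- unique(tuJunctionKeys(b))
    un <- union(ja, jb)
    if (length(un) == 0L) return(1)
    length(intersect(ja, jb)) / length(un)
}

#' Sequencing-depth resampling experiment
#'
#' Subsamples the read set without replacement to a grid of target depths
#' (in X), rebuilds coverage, re-runs a fixed prediction pipeline and
#' scores junction sensitivity against a confirmed TU set — replicated
#' `replicates` times per depth to average out resampling noise. At full
#' depth the subsample is the whole read set, so the full-data result is
#' reproduced exactly.
#'
#' @param reads `GRanges` or `data.frame` of the full read set.
#' @param annotation a [GenomeAnnotation-class].
#' @param targetDepths numeric vector of depths (X), each at most the
#'   full-data estimated depth.
#' @param pipeline `function(track)` returning a [TUSet-class] (typically
#'   a closure over a trained model, see [predictTUs()]).
#' @param confirmed confirmed TU set (see [tuSensitivity()]).
#' @param replicates subsamples per depth (default 25).
#' @param seed optional integer seed.
#' @param strandMode passed to [buildCoverage()].
#' @return List with `depths`, `replicates`, `sensitivities` (matrix
#'   depth x replicate) and `meanSensitivity`.
#' @export
depthResample <- function(reads, annotation, targetDepths, pipeline,
                          confirmed, replicates = 25L, seed = NULL,
                          strandMode = "stranded-forward") {
    rd <- normalizeReads(reads, annotation)
    fullTrack <- buildCoverage(rd, annotation, strandMode)
    fullDepth <- estimatedDepth(fullTrack, annotation)
    if (any(targetDepths > fullDepth + 1e-9))
        stop("target depth exceeds full-data depth (",
             format(fullDepth), "X)", call. = FALSE)
    N <- nrow(rd)
    sens <- matrix(NA_real_, nrow = length(targetDepths),
                   ncol = replicates,
                   dimnames = list(format(targetDepths), NULL))
    withSeed(seed, {
        for (d in seq_along(targetDepths)) {
            nDraw <- as.integer(round(N * targetDepths[d] / fullDepth))
            for (r in seq_len(replicates)) {
                idx <- sample.int(N, nDraw)
                tr <- buildCoverage(rd[idx, , drop = FALSE], annotation,
                                    strandMode)
                sens[d, r] <- tuSensitivity(pipeline(tr), confirmed)
            }
        }
    })
    list(depths = targetDepths, replicates = replicates,
         sensitivities = sens, meanSensitivity = rowMeans(sens))
}

#' Inside- vs outside-TU intergenic expression contrast
#'
#' Intergenic regions between genes of one TU ("inside") should be
#' expressed, while intergenic regions between distinct TUs on the same
#' strand ("outside") should not. Reports the mean per-region abundance
#' of both groups and a one-sided rank-sum (Wilcoxon) p-value for
#' inside > outside. Zero-length regions are excluded.
#'
#' @param tuset a [TUSet-class].
#' @param track a [CoverageTrack-class].
#' @param annotation the matching [GenomeAnnotation-class].
#' @return List with `insideMean`, `outsideMean`, `pValue`, `nInside`,
#'   `nOutside` and the per-region means `inside`, `outside`.
#' @importFrom stats wilcox.test
#' @export
intergenicContrast <- function(tuset, track, annotation) {
    g <- genes(annotation)
    pre <- trackPrefix(track)
    ids <- mcols(g)$gene_id
    geneStart <- setNames(start(g), ids)
    geneEnd <- setNames(end(g), ids)
    tt <- tuTable(tuset)
    regionMeanOf <- function(leftIds, rightIds, st) {
        s <- geneEnd[leftIds] + 1L
        e <- geneStart[rightIds] - 1L
        keep <- e >= s
        if (!any(keep)) return(numeric(0))
        intervalMean(pre, st[keep], unname(s[keep]), unname(e[keep]))
    }
    inL <- character(0); inR <- character(0); inS <- character(0)
    for (i in which(tt$nGenes > 1L)) {
        m <- tt$geneIds[[i]]
        inL <- c(inL, m[-length(m)]); inR <- c(inR, m[-1])
        inS <- c(inS, rep(tt$strand[i], length(m) - 1L))
    }
    outL <- character(0); outR <- character(0); outS <- character(0)
    for (st in c("+", "-")) {
        sel <- tt[tt$strand == st, , drop = FALSE]
        if (nrow(sel) < 2L) next
        sel <- sel[order(sel$start), , drop = FALSE]
        lastGene <- vapply(sel$geneIds, function(x) x[length(x)],
                           character(1))
        firstGene <- vapply(sel$geneIds, `[`, character(1), 1L)
        outL <- c(outL, lastGene[-nrow(sel)])
        outR <- c(outR, firstGene[-1])
        outS <- c(outS, rep(st, nrow(sel) - 1L))
    }
    inside <- regionMeanOf(inL, inR, inS)
    outside <- regionMeanOf(outL, outR, outS)
    if (length(inside) == 0L || length(outside) == 0L)
        stop("empty group: need inside- and outside-TU intergenic regions",
             call. = FALSE)
    p <- suppressWarnings(
        wilcox.test(inside, outside, alternative = "greater")$p.value)
    list(insideMean = mean(inside), outsideMean = mean(outside),
         pValue = p, nInside = length(inside), nOutside = length(outside),
         inside = inside, outside = outside)
}
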