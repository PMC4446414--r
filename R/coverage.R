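#' Build a strand-specific per-base coverage track
#'
#' Increments, for every mapped read, the abundance of each genome
#' position it covers on its assigned strand. Input can be a `GRanges` of
#' aligned read spans, a `data.frame` with `start`, `end`, `strand`
#' columns (1-based closed), or a path to a BED or SAM/BAM file. Gapped
#' alignments contribute only their aligned bases.
#'
#' @param reads read spans (`GRanges`, `data.frame`, or file path).
#' @param annotation the [GenomeAnnotation-class] of the target genome.
#' @param strandMode `"stranded-forward"` keeps the aligned strand,
#'   `"stranded-reverse"` flips it (dUTP-style libraries), `"unstranded"`
#'   puts all reads on the plus track (strand-specific statistics are then
#'   meaningless).
#' @return A [CoverageTrack-class].
#' @examples
#' gr <- GenomicRanges::GRanges("g", IRanges::IRanges(1, 300), strand = "+")
#' S4Vectors::mcols(gr)$gene_id <- "A"
#' ann <- GenomeAnnotation("g", 1000, gr)
#' rd <- data.frame(start = 11, end = 20, strand = "+")
#' tr <- buildCoverage(rd, ann)
#' sum(plusCoverage(tr))  # 10
#' @importFrom IRanges coverage
#' @export
buildCoverage <- function(reads, annotation,
                          strandMode = c("stranded-forward",
                                         "stranded-reverse",
                                         "unstranded")) {
    strandMode <- match.arg(strandMode)
    L <- genomeLength(annotation)
    rd <- normalizeReads(reads, annotation)
    if (nrow(rd) > 0L) {
        if (any(rd$start < 1L) || any(rd$end > L))
            stop("read out of bounds: alignment extends past genome ends",
                 call. = FALSE)
    }
    st <- rd$strand
    if (strandMode == "stranded-reverse")
        st <- ifelse(st == "+", "-", "+")
    if (strandMode == "unstranded")
        st <- rep("+", length(st))
    covOn <- function(sel) {
        if (!any(sel)) return(integer(L))
        as.integer(coverage(IRanges(rd$start[sel], rd$end[sel]), width = L))
    }
    CoverageTrack(genomeId(annotation), covOn(st == "+"), covOn(st == "-"))
}

# Coerce read input to a data.frame(start, end, strand); checks reference
# names when the input carries them.
normalizeReads <- function(reads, annotation) {
    if (is.character(reads) && length(reads) == 1L) {
        if (grepl("\\.(sam|bam)$", reads, ignore.case = TRUE))
            return(readSAMReads(reads, annotation))
        reads <- rtracklayer::import(reads, format = "bed")
    }
    if (inherits(reads, "GRanges")) {
        sq <- unique(as.character(seqnames(reads)))
        if (length(sq) > 0L && !all(sq %in% genomeId(annotation)))
            stop("unknown reference: reads mapped to ",
                 paste(setdiff(sq, genomeId(annotation)), collapse = ","),
                 call. = FALSE)
        st <- as.character(strand(reads))
        st[st == "*"] <- "+"
        return(data.frame(start = start(reads), end = end(reads),
                          strand = st, stringsAsFactors = FALSE))
    }
    if (is.data.frame(reads)) {
        stopIfNot(all(c("start", "end", "strand") %in% colnames(reads)),
                  "read data.frame needs start, end, strand columns")
        return(data.frame(start = as.integer(reads$start),
                          end = as.integer(reads$end),
                          strand = as.character(reads$strand),
                          stringsAsFactors = FALSE))
    }
    stop("unsupported read input", call. = FALSE)
}

# Read aligned spans from SAM/BAM via Rsamtools; each CIGAR M/=/X block
# becomes one covered interval (D/N advance the reference uncovered).
#' @importFrom Rsamtools scanBam ScanBamParam scanBamFlag asBam
readSAMReads <- function(file, annotation) {
    if (grepl("\\.sam$", file, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        file <- asBam(file, destination = dest, overwrite = TRUE,
                      indexDestination = FALSE)
    }
    p <- ScanBamParam(what = c("rname", "pos", "cigar", "strand"),
                      flag = scanBamFlag(isUnmappedQuery = FALSE))
    b <- scanBam(file, param = p)[[1]]
    if (length(b$pos) == 0L)
        return(data.frame(start = integer(), end = integer(),
                          strand = character()))
    rn <- as.character(b$rname)
    if (!all(rn %in% genomeId(annotation)))
        stop("unknown reference: reads mapped to ",
             paste(setdiff(unique(rn), genomeId(annotation)),
                   collapse = ","), call. = FALSE)
    res <- vector("list", length(b$pos))
    for (i in seq_along(b$pos)) {
        ops <- regmatches(b$cigar[i],
                          gregexpr("[0-9]+[MIDNSHP=X]", b$cigar[i]))[[1]]
        n <- as.integer(sub("[A-Z=]$", "", ops))
        op <- sub("^[0-9]+", "", ops)
        pos <- b$pos[i]
        ss <- integer(0); ee <- integer(0)
        for (k in seq_along(op)) {
            if (op[k] %in% c("M", "=", "X")) {
                ss <- c(ss, pos); ee <- c(ee, pos + n[k] - 1L)
                pos <- pos + n[k]
            } else if (op[k] %in% c("D", "N")) {
                pos <- pos + n[k]
            }
        }
        res[[i]] <- data.frame(start = ss, end = ee,
            strand = as.character(b$strand[i]), stringsAsFactors = FALSE)
    }
    do.call(rbind, res)
}

#' Read or write per-strand coverage as bedGraph
#'
#' `writeCoverageBedGraph()` writes the nonzero runs of each strand to two
#' bedGraph files; `readCoverageBedGraph()` rebuilds a
#' [CoverageTrack-class] from such a pair, so precomputed coverage can
#' bypass alignment input entirely.
#'
#' @param track a [CoverageTrack-class].
#' @param plusFile,minusFile bedGraph paths for the two strands.
#' @param annotation the matching [GenomeAnnotation-class].
#' @return `readCoverageBedGraph()` returns a [CoverageTrack-class];
#'   the writer returns the file paths invisibly.
#' @export
writeCoverageBedGraph <- function(track, plusFile, minusFile) {
    wr <- function(v, file) {
        r <- rle(as.integer(v))
        e <- cumsum(r$lengths)
        s <- e - r$lengths          # 0-based starts
        keep <- r$values != 0L
        lines <- sprintf("%s\t%d\t%d\t%d", genomeId(track),
                         s[keep], e[keep], r$values[keep])
        writeLines(lines, file)
    }
    wr(track@plus, plusFile)
    wr(track@minus, minusFile)
    invisible(c(plusFile, minusFile))
}

#' @rdname writeCoverageBedGraph
#' @export
readCoverageBedGraph <- function(plusFile, minusFile, annotation) {
    L <- genomeLength(annotation)
    rd <- function(file) {
        v <- integer(L)
        tab <- tryCatch(
            utils::read.table(file, sep = "\t", header = FALSE,
                col.names = c("chrom", "start", "end", "score")),
            error = function(e) NULL)
        if (is.null(tab) || nrow(tab) == 0L) return(v)
        stopIfNot(all(tab$chrom %in% genomeId(annotation)),
                  "unknown reference in bedGraph")
        for (i in seq_len(nrow(tab)))
            v[(tab$start[i] + 1L):tab$end[i]] <- tab$score[i]
        v
    }
    CoverageTrack(genomeId(annotation), rd(plusFile), rd(minusFile))
}

#' Estimated sequencing depth
#'
#' The estimated depth (in X) is the total read abundance summed over
#' every genome position on both strands, divided by the total coding
#' length: the length of the union of all annotated gene intervals.
#' Intergenic positions contribute to the numerator but not the
#' denominator.
#'
#' @param track a [CoverageTrack-class].
#' @param annotation a [GenomeAnnotation-class] with at least one gene.
#' @return The fold depth (numeric scalar).
#' @importFrom IRanges reduce ranges
#' @export
estimatedDepth <- function(track, annotation) {
    g <- genes(annotation)
    codingLen <- sum(width(reduce(ranges(g))))
    if (length(g) == 0L || codingLen == 0L)
        stop("no coding sequence: |T| is zero", call. = FALSE)
    (sum(as.numeric(track@plus)) + sum(as.numeric(track@minus))) / codingLen
}

#' Fraction of a region set covered by at least one read
#'
#' @param track a [CoverageTrack-class].
#' @param regions `GRanges` or `IRanges` of regions (overlaps are unioned).
#' @param strand `"both"` sums the two strands before thresholding;
#'   `"+"`/`"-"` restrict to one strand.
#' @return Fraction in `[0, 1]` of region positions with abundance >= 1.
#' @export
regionCoveredFraction <- function(track, regions, strand = "both") {
    if (inherits(regions, "GRanges")) regions <- ranges(regions)
    stopIfNot(length(regions) > 0L, "empty region set")
    regions <- reduce(regions)
    v <- switch(strand,
        both = track@plus + track@minus,
        "+" = track@plus,
        "-" = track@minus,
        stop("strand must be '+', '-' or 'both'", call. = FALSE))
    covered <- c(0, cumsum(v >= 1L))
    s <- start(regions); e <- end(regions)
    stopIfNot(all(s >= 1L) && all(e <= length(v)), "regions outside genome")
    sum(covered[e + 1L] - covered[s]) / sum(e - s + 1L)
}

#' Antisense expression fraction
#'
#' Ratio of the total read abundance over gene bodies on the strand
#' opposite each gene's annotation to the total on the annotated strand.
#' Positions outside annotated genes are excluded.
#'
#' @param track a strand-specific [CoverageTrack-class].
#' @param annotation a [GenomeAnnotation-class].
#' @return Non-negative ratio (0 when no antisense signal).
#' @export
antisenseFraction <- function(track, annotation) {
    g <- genes(annotation)
    pre <- trackPrefix(track)
    st <- as.character(strand(g))
    sense <- sum(intervalStats(pre, st, start(g), end(g))$sum)
    anti <- sum(intervalStats(pre, ifelse(st == "+", "-", "+"),
                              start(g), end(g))$sum)
    if (sense == 0)
        stop("no sense expression", call. = FALSE)
    anti / sense
}

#' Summary statistics of a coverage track
#'
#' Computes the depth/coverage characteristics commonly reported for a
#' strand-specific bacterial RNA-seq dataset: estimated depth (X), the
#' fraction of coding positions and of intergenic positions covered by at
#' least one read, and the antisense fraction.
#'
#' @param track a [CoverageTrack-class].
#' @param annotation a [GenomeAnnotation-class].
#' @return A one-row `DataFrame` with columns `estimatedDepth`,
#'   `codingCoveredFraction`, `intergenicCoveredFraction`,
#'   `antisenseFraction`.
#' @importFrom IRanges gaps
#' @export
coverageStats <- function(track, annotation) {
    g <- genes(annotation)
    coding <- reduce(ranges(g))
    inter <- gaps(coding, start = 1L, end = genomeLength(annotation))
    DataFrame(
        estimatedDepth = estimatedDepth(track, annotation),
        codingCoveredFraction = regionCoveredFraction(track, coding),
        intergenicCoveredFraction = if (length(inter))
            regionCoveredFraction(track, inter) else NA_real_,
        antisenseFraction = antisenseFraction(track, annotation))
}
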