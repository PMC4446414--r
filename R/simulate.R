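#' Configuration for the synthetic transcriptome generator
#'
#' Builds a [SimConfig-class] with defaults describing a typical
#' bacterial strand-specific RNA-seq experiment: lognormal ~0.9 kb genes,
#' ~50 bp within-TU and ~200 bp between-TU intergenic gaps, a TU-size
#' distribution with 56% single-gene TUs (and a quarter of multi-gene TUs
#' carrying five or more genes), coding GC 0.40 against intergenic GC
#' 0.33, 50 bp reads at 100X estimated depth, ~0.5% antisense signal,
#' 225 bp long-read and 170 bp paired-end-fragment spanning evidence.
#'
#' @param nGenes,geneLengthMean,geneLengthSdLog,intraGapMean,interGapMean
#'   genome layout parameters (bp).
#' @param tuSizeProbs probabilities of TU sizes 1,2,3,4,5+ (sum 1).
#' @param codingGC,intergenicGC GC content of coding/intergenic sequence.
#' @param depth,readLength short-read coverage parameters.
#' @param exprSdLog,overdispersion expression heterogeneity (lognormal sd
#'   of per-TU level; CV of extra-Poisson count noise).
#' @param boundaryGapProb probability a TU boundary stays free of
#'   read-through coverage.
#' @param antisenseRate expected antisense:sense ratio.
#' @param longReadMeanLen,fragmentMeanLen spanning-evidence mean lengths.
#' @return A [SimConfig-class].
#' @export
simConfig <- function(nGenes = 700L, geneLengthMean = 900,
                      geneLengthSdLog = 0.6, intraGapMean = 50,
                      interGapMean = 200,
                      tuSizeProbs = c(0.56, 0.17, 0.10, 0.06, 0.11),
                      codingGC = 0.40, intergenicGC = 0.33, depth = 100,
                      readLength = 50L, exprSdLog = 1.0,
                      overdispersion = 0.3, boundaryGapProb = 0.85,
                      antisenseRate = 0.005, longReadMeanLen = 225,
                      fragmentMeanLen = 170) {
    new("SimConfig", nGenes = as.integer(nGenes),
        geneLengthMean = geneLengthMean,
        geneLengthSdLog = geneLengthSdLog, intraGapMean = intraGapMean,
        interGapMean = interGapMean, tuSizeProbs = tuSizeProbs,
        codingGC = codingGC, intergenicGC = intergenicGC, depth = depth,
        readLength = as.integer(readLength), exprSdLog = exprSdLog,
        overdispersion = overdispersion,
        boundaryGapProb = boundaryGapProb, antisenseRate = antisenseRate,
        longReadMeanLen = longReadMeanLen,
        fragmentMeanLen = fragmentMeanLen)
}

#' Read a simulator configuration from YAML
#'
#' Keys mirror the [simConfig()] argument names; absent keys keep their
#' defaults.
#'
#' @param file YAML path.
#' @return A [SimConfig-class].
#' @export
simConfigFromYAML <- function(file) {
    vals <- yaml::read_yaml(file)
    known <- names(formals(simConfig))
    unknown <- setdiff(names(vals), known)
    stopIfNot(length(unknown) == 0L,
              paste("unknown config keys:", paste(unknown, collapse = ", ")))
    do.call(simConfig, vals)
}

#' Simulate a bacterial genome with known TU structure
#'
#' Lays genes out TU by TU along a single replicon: TU sizes are drawn
#' from `tuSizeProbs` (five-plus TUs get `5 + Poisson(1)` genes), each TU
#' gets a strand, genes within a TU are separated by short intragenic-TU
#' gaps and TUs by longer gaps. The nucleotide sequence is drawn with
#' `codingGC` inside genes and `intergenicGC` elsewhere. Per-TU relative
#' expression levels are lognormal with median 1. Everything is
#' deterministic given `(config, seed)`.
#'
#' @param config a [SimConfig-class].
#' @param seed integer seed.
#' @param genomeId replicon name of the simulated annotation.
#' @return A [SimTruth-class].
#' @importFrom stats rlnorm rgamma rpois runif rnorm
#' @importFrom Biostrings DNAString
#' @export
simulateGenome <- function(config, seed = 1L, genomeId = "sim_genome") {
    withSeed(seed, {
        sizes <- integer(0)
        while (sum(sizes) < config@nGenes) {
            k <- sample.int(5L, 1L, prob = config@tuSizeProbs)
            if (k == 5L) k <- 5L + rpois(1L, 1)
            sizes <- c(sizes, k)
        }
        excess <- sum(sizes) - config@nGenes
        if (excess > 0L) {
            last <- length(sizes)
            sizes[last] <- sizes[last] - excess
            if (sizes[last] == 0L) sizes <- sizes[-last]
        }
        nTU <- length(sizes)
        tuStrand <- sample(c("+", "-"), nTU, replace = TRUE)
        geneLens <- pmax(200L, as.integer(round(rlnorm(sum(sizes),
            log(config@geneLengthMean) - config@geneLengthSdLog^2 / 2,
            config@geneLengthSdLog))))
        intraGap <- function(n) pmax(2L, as.integer(round(
            rgamma(n, shape = 2, scale = config@intraGapMean / 2))))
        # between-TU gaps are heavy-tailed in real genomes (promoter /
        # terminator regions up to kilobases): lognormal around the mean
        interGap <- function(n) pmax(40L, as.integer(round(
            rlnorm(n, log(config@interGapMean) - 0.8^2 / 2, 0.8))))
        pos <- 1L + interGap(1L)
        gi <- 0L
        geneStart <- integer(sum(sizes)); geneEnd <- integer(sum(sizes))
        geneStrand <- character(sum(sizes)); geneTU <- integer(sum(sizes))
        tuStart <- integer(nTU); tuEnd <- integer(nTU)
        for (t in seq_len(nTU)) {
            tuStart[t] <- pos
            for (j in seq_len(sizes[t])) {
                gi <- gi + 1L
                geneStart[gi] <- pos
                geneEnd[gi] <- pos + geneLens[gi] - 1L
                geneStrand[gi] <- tuStrand[t]
                geneTU[gi] <- t
                pos <- geneEnd[gi] + 1L
                if (j < sizes[t]) pos <- pos + intraGap(1L)
            }
            tuEnd[t] <- geneEnd[gi]
            pos <- pos + interGap(1L)
        }
        genomeLength <- pos + 100L
        if (genomeLength > 5e7)
            stop("infeasible config: genome overflow", call. = FALSE)

        bases <- c("A", "C", "G", "T")
        pInter <- c((1 - config@intergenicGC) / 2, config@intergenicGC / 2,
                    config@intergenicGC / 2, (1 - config@intergenicGC) / 2)
        pCoding <- c((1 - config@codingGC) / 2, config@codingGC / 2,
                     config@codingGC / 2, (1 - config@codingGC) / 2)
        seqv <- sample(bases, genomeLength, replace = TRUE, prob = pInter)
        codingIdx <- unlist(lapply(seq_len(gi), function(i)
            geneStart[i]:geneEnd[i]))
        seqv[codingIdx] <- sample(bases, length(codingIdx),
                                  replace = TRUE, prob = pCoding)
        seqDNA <- DNAString(paste(seqv, collapse = ""))

        ids <- sprintf("gene_%04d", seq_len(gi))
        gr <- GRanges(genomeId, IRanges(geneStart, geneEnd),
                      strand = geneStrand)
        mcols(gr)$gene_id <- ids
        ann <- GenomeAnnotation(genomeId, genomeLength, gr,
                                sequence = seqDNA)
        tus <- DataFrame(
            tuId = sprintf("trueTU%04d", seq_len(nTU)),
            strand = tuStrand, start = tuStart, end = tuEnd,
            nGenes = sizes,
            geneIds = CharacterList(split(ids, geneTU)[
                as.character(seq_len(nTU))]))
        expr <- rlnorm(nTU, 0, config@exprSdLog)
        new("SimTruth", annotation = ann,
            trueTUs = TUSet(genomeId, tus),
            tuExpression = expr, config = config)
    })
}

#' Simulate strand-specific short-read coverage
#'
#' Places discrete reads (length `readLength`) within true TU spans at
#' rates proportional to TU expression times span length, with
#' gamma-distributed extra-Poisson noise on per-TU counts. With
#' probability `1 - boundaryGapProb` a TU reads through into its
#' downstream between-TU gap (covering it), which creates hard junctions;
#' otherwise the gap keeps a zero-coverage run. Antisense reads are added
#' inside gene bodies on the opposite strand at `antisenseRate`. The
#' total read count targets estimated depth `depth`.
#'
#' @param truth a [SimTruth-class].
#' @param config a [SimConfig-class] (defaults to the truth's config).
#' @param seed integer seed.
#' @return List with `reads` (`GRanges`, BED-ready) and `track`
#'   ([CoverageTrack-class]).
#' @importFrom stats rmultinom
#' @export
simulateCoverage <- function(truth, config = NULL, seed = 1L) {
    if (is.null(config)) config <- truth@config
    stopIfNot(config@depth > 0, "depth must be positive")
    ann <- truth@annotation
    tt <- tuTable(trueTUs(truth))
    expr <- truth@tuExpression
    L <- genomeLength(ann)
    rl <- config@readLength
    withSeed(seed, {
        nTU <- nrow(tt)
        spanS <- tt$start; spanE <- tt$end
        # read-through across the downstream boundary (transcription
        # direction): plus TUs extend their end, minus TUs their start
        ord <- order(tt$start)
        for (oi in seq_len(nTU)) {
            t <- ord[oi]
            through <- runif(1) > config@boundaryGapProb
            if (!through) next
            if (tt$strand[t] == "+") {
                nxt <- if (oi < nTU) tt$start[ord[oi + 1L]] - 1L else L
                spanE[t] <- max(spanE[t], nxt)
            } else {
                prv <- if (oi > 1L) tt$end[ord[oi - 1L]] + 1L else 1L
                spanS[t] <- min(spanS[t], prv)
            }
        }
        spanLen <- spanE - spanS + 1L
        codingLen <- sum(width(reduce(ranges(genes(ann)))))
        nReads <- as.integer(round(config@depth * codingLen / rl))
        od <- config@overdispersion
        w <- expr * spanLen
        if (od > 0)
            w <- w * rgamma(nTU, shape = 1 / od^2, rate = 1 / od^2)
        counts <- if (sum(w) > 0)
            as.vector(rmultinom(1L, nReads, w)) else integer(nTU)
        starts <- integer(0); ends <- integer(0); strands <- character(0)
        for (t in seq_len(nTU)) {
            if (counts[t] == 0L) next
            maxStart <- max(spanS[t], spanE[t] - rl + 1L)
            s <- spanS[t] + floor(runif(counts[t]) *
                                  (maxStart - spanS[t] + 1L))
            e <- pmin(s + rl - 1L, spanE[t])
            starts <- c(starts, as.integer(s))
            ends <- c(ends, as.integer(e))
            strands <- c(strands, rep(tt$strand[t], counts[t]))
        }
        nAnti <- as.integer(round(config@antisenseRate * nReads))
        if (nAnti > 0L) {
            g <- genes(ann)
            gl <- width(g)
            pick <- sample.int(length(g), nAnti, replace = TRUE,
                               prob = gl)
            maxStart <- pmax(start(g)[pick], end(g)[pick] - rl + 1L)
            s <- start(g)[pick] + floor(runif(nAnti) *
                    (maxStart - start(g)[pick] + 1L))
            e <- pmin(s + rl - 1L, end(g)[pick])
            starts <- c(starts, as.integer(s))
            ends <- c(ends, as.integer(e))
            strands <- c(strands, ifelse(
                as.character(strand(g))[pick] == "+", "-", "+"))
        }
        reads <- GRanges(genomeId(ann), IRanges(starts, ends),
                         strand = strands)
        track <- buildCoverage(reads, ann)
        list(reads = reads, track = track)
    })
}

#' Simulate spanning evidence (long reads or paired-end fragments)
#'
#' Samples evidence intervals inside true TU spans — never crossing a TU
#' boundary — from TUs chosen proportionally to expression times span
#' length. Lengths are normal around `longReadMeanLen` (type
#' `"long_read"`, strandless like 454 reads) or `fragmentMeanLen` (type
#' `"fragment"`, stranded), truncated to the containing TU span.
#'
#' @param truth a [SimTruth-class].
#' @param config a [SimConfig-class] (defaults to the truth's config).
#' @param n number of evidence intervals.
#' @param type `"long_read"` or `"fragment"`.
#' @param seed integer seed.
#' @return `GRanges` of evidence spans.
#' @export
simulateEvidence <- function(truth, config = NULL, n = 5000L,
                             type = c("long_read", "fragment"),
                             seed = 1L) {
    type <- match.arg(type)
    if (is.null(config)) config <- truth@config
    ann <- truth@annotation
    tt <- tuTable(trueTUs(truth))
    meanLen <- if (type == "long_read") config@longReadMeanLen else
        config@fragmentMeanLen
    withSeed(seed, {
        w <- truth@tuExpression * (tt$end - tt$start + 1L)
        pick <- sample.int(nrow(tt), n, replace = TRUE, prob = w)
        spanS <- tt$start[pick]; spanE <- tt$end[pick]
        spanLen <- spanE - spanS + 1L
        len <- pmin(pmax(as.integer(round(
            rnorm(n, meanLen, 0.1 * meanLen))), 30L), spanLen)
        s <- spanS + floor(runif(n) * (spanLen - len + 1L))
        GRanges(genomeId(ann), IRanges(as.integer(s),
                                       as.integer(s) + len - 1L),
                strand = if (type == "long_read") "*" else
                    tt$strand[pick])
    })
}

#' Ground-truth junction keys of a simulation
#'
#' Keys (`strand:leftId>rightId`) of every consecutive same-strand gene
#' pair whose two genes belong to the same true TU — the exact oracle for
#' junction classification.
#'
#' @param truth a [SimTruth-class].
#' @param pairs optionally the [deriveGenePairs()] table to label; when
#'   given, a logical vector along its rows is returned instead.
#' @return Character vector of joined-junction keys, or a logical vector
#'   labeling `pairs`.
#' @export
truthJunctionKeys <- function(truth, pairs = NULL) {
    keys <- tuJunctionKeys(trueTUs(truth))
    if (is.null(pairs)) return(keys)
    paste(pairs$strand, pairs$leftId, pairs$rightId,
          sep = "\r") %in% keys
}

#' Write simulation outputs to disk
#'
#' Writes `genome.fa`, `ann.gff3` and `truth_tus.tsv` (plus `reads.bed`
#' and `evidence.bed` when given) into a directory, in formats readable
#' by [loadAnnotation()] and [buildCoverage()].
#'
#' @param truth a [SimTruth-class].
#' @param dir output directory (created if missing).
#' @param reads,evidence optional `GRanges` to export as BED6.
#' @return The directory path, invisibly.
#' @importFrom Biostrings DNAStringSet writeXStringSet
#' @export
writeSimulation <- function(truth, dir, reads = NULL, evidence = NULL) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    ann <- truth@annotation
    ss <- DNAStringSet(list(genomeSequence(ann)))
    names(ss) <- genomeId(ann)
    writeXStringSet(ss, file.path(dir, "genome.fa"))
    writeAnnotationGFF3(ann, file.path(dir, "ann.gff3"))
    tt <- tuTable(trueTUs(truth))
    utils::write.table(
        data.frame(tuId = tt$tuId, strand = tt$strand, start = tt$start,
                   end = tt$end, nGenes = tt$nGenes,
                   geneIds = vapply(tt$geneIds, paste, character(1),
                                    collapse = ","),
                   expression = truth@tuExpression),
        file.path(dir, "truth_tus.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    if (!is.null(reads)) writeBED(reads, file.path(dir, "reads.bed"))
    if (!is.null(evidence))
        writeBED(evidence, file.path(dir, "evidence.bed"))
    invisible(dir)
}

#' Write intervals as BED6
#'
#' @param gr a `GRanges`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeBED <- function(gr, file) {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                     sprintf("iv%d", seq_along(gr)),
                     as.character(strand(gr)))
    writeLines(lines, file)
    invisible(file)
}
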