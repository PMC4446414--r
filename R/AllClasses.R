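#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- isSorted
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importClassesFrom Biostrings DNAString
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom GenomicRanges GRanges
NULL

setClassUnion("DNAStringOrNULL", c("DNAString", "NULL"))

#' GenomeAnnotation: ordered gene models on a single replicon
#'
#' Holds the gene models of one bacterial replicon (chromosome or plasmid)
#' as a position-sorted [GenomicRanges::GRanges] with a `gene_id` metadata
#' column, the replicon length, and optionally the nucleotide sequence
#' (needed only for GC-based placement of pseudo intergenic regions).
#' All coordinates are 1-based closed intervals, the GRanges convention.
#'
#' @slot genomeId single replicon identifier.
#' @slot genomeLength replicon length in bp.
#' @slot genes `GRanges` sorted by start, `mcols()$gene_id` unique.
#' @slot sequence `DNAString` of length `genomeLength`, or `NULL`.
#'
#' @seealso [loadAnnotation()], [deriveGenePairs()]
#' @export
setClass("GenomeAnnotation",
    representation(
        genomeId = "character",
        genomeLength = "integer",
        genes = "GRanges",
        sequence = "DNAStringOrNULL"
    )
)

setValidity("GenomeAnnotation", function(object) {
    msg <- NULL
    g <- object@genes
    if (length(object@genomeId) != 1L)
        msg <- c(msg, "genomeId must be a single string")
    if (length(object@genomeLength) != 1L || object@genomeLength < 1L)
        msg <- c(msg, "genomeLength must be a positive scalar")
    if (length(g) > 0L) {
        if (is.null(mcols(g)$gene_id))
            msg <- c(msg, "genes must carry a gene_id metadata column")
        else if (anyDuplicated(mcols(g)$gene_id))
            msg <- c(msg, "gene ids must be unique")
        if (any(start(g) < 1L) || any(end(g) > object@genomeLength))
            msg <- c(msg, "gene coordinates outside [1, genomeLength]")
        if (is.unsorted(start(g)))
            msg <- c(msg, "genes must be sorted by start")
        if (any(!as.character(strand(g)) %in% c("+", "-")))
            msg <- c(msg, "every gene needs a +/- strand")
    }
    if (!is.null(object@sequence) &&
        length(object@sequence) != object@genomeLength)
        msg <- c(msg, "sequence length must equal genomeLength")
    if (is.null(msg)) TRUE else msg
})

#' Construct a GenomeAnnotation
#'
#' @param genomeId replicon identifier.
#' @param genomeLength replicon length (bp).
#' @param genes `GRanges` with a `gene_id` metadata column (sorted on entry
#'   if not already).
#' @param sequence optional `DNAString` of length `genomeLength`.
#' @return A [GenomeAnnotation-class] object.
#' @export
GenomeAnnotation <- function(genomeId, genomeLength, genes, sequence = NULL) {
    if (length(genes) > 0L)
        genes <- genes[order(start(genes), end(genes))]
    new("GenomeAnnotation",
        genomeId = as.character(genomeId),
        genomeLength = as.integer(genomeLength),
        genes = genes,
        sequence = sequence)
}

#' CoverageTrack: per-base, per-strand read abundance
#'
#' Stores the read abundance at each single nucleotide position of the
#' genome, separately for the forward and reverse strand. Position `i` of
#' each vector is genome position `i` (1-based).
#'
#' @slot genomeId replicon identifier the track belongs to.
#' @slot plus,minus non-negative integer vectors, one entry per base.
#' @seealso [buildCoverage()], [estimatedDepth()]
#' @export
setClass("CoverageTrack",
    representation(
        genomeId = "character",
        plus = "integer",
        minus = "integer"
    )
)

setValidity("CoverageTrack", function(object) {
    msg <- NULL
    if (length(object@plus) != length(object@minus))
        msg <- c(msg, "plus and minus tracks must have equal length")
    if (length(object@plus) && (min(object@plus) < 0L ||
        min(object@minus) < 0L))
        msg <- c(msg, "coverage values must be non-negative")
    if (is.null(msg)) TRUE else msg
})

#' Construct a CoverageTrack
#'
#' @param genomeId replicon identifier.
#' @param plus,minus integer vectors of per-base abundance (equal length).
#' @return A [CoverageTrack-class] object.
#' @export
CoverageTrack <- function(genomeId, plus, minus) {
    new("CoverageTrack", genomeId = as.character(genomeId),
        plus = as.integer(plus), minus = as.integer(minus))
}

#' TUSet: a set of predicted (or true) transcription units
#'
#' A transcription unit (TU) is a maximal run of consecutive same-strand
#' genes transcribed as one RNA molecule. Within a `TUSet` every gene
#' belongs to exactly one TU, i.e. the set partitions the genes it covers.
#'
#' @slot genomeId replicon identifier.
#' @slot tus `DataFrame` with columns `tuId`, `strand`, `start`, `end`,
#'   `nGenes` and `geneIds` (a `CharacterList`, genes in genomic order).
#' @seealso [assembleTUs()], [tuSizeDistribution()], [similarityScore()]
#' @export
setClass("TUSet",
    representation(
        genomeId = "character",
        tus = "DataFrame"
    )
)

setValidity("TUSet", function(object) {
    msg <- NULL
    need <- c("tuId", "strand", "start", "end", "nGenes", "geneIds")
    if (!all(need %in% colnames(object@tus)))
        msg <- c(msg, paste("tus must have columns:",
            paste(need, collapse = ", ")))
    else {
        ids <- unlist(object@tus$geneIds)
        if (anyDuplicated(ids))
            msg <- c(msg, "a gene may belong to only one TU within a set")
        if (any(object@tus$nGenes != lengths(object@tus$geneIds)))
            msg <- c(msg, "nGenes must match length of geneIds")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a TUSet
#'
#' @param genomeId replicon identifier.
#' @param tus `DataFrame` (or data.frame) with columns `tuId`, `strand`,
#'   `start`, `end`, `nGenes`, `geneIds`.
#' @return A [TUSet-class] object.
#' @export
TUSet <- function(genomeId, tus) {
    tus <- as(tus, "DataFrame")
    new("TUSet", genomeId = as.character(genomeId), tus = tus)
}

#' TUModel: a fitted junction classifier
#'
#' Wraps a radial-basis support vector machine trained to decide whether
#' the junction between two consecutive same-strand genes is co-transcribed,
#' together with the per-feature min-max scaling fitted on the training set,
#' the hyperparameters, and the cross-validation record.
#'
#' @slot fit fitted `e1071::svm` object.
#' @slot featureNames names of the feature columns, in training order.
#' @slot scalerMin,scalerMax per-feature bounds of the min-max scaler.
#' @slot hyperparams list with `cost`, `gamma`, `classWeights`.
#' @slot mode `"illumina_only"` or `"illumina_plus_long_read"`.
#' @slot cvAccuracy overall stratified cross-validation accuracy.
#' @slot foldPredictions data.frame of held-out fold predictions
#'   (`fold`, `truth`, `score`, `predicted`).
#' @slot seed integer seed used for fold assignment (NA when unseeded).
#' @seealso [trainTUModel()], [predictPairs()]
#' @export
setClass("TUModel",
    representation(
        fit = "ANY",
        featureNames = "character",
        scalerMin = "numeric",
        scalerMax = "numeric",
        hyperparams = "list",
        mode = "character",
        cvAccuracy = "numeric",
        foldPredictions = "data.frame",
        seed = "integer"
    )
)

#' SimConfig: parameters of the synthetic transcriptome generator
#'
#' Defaults describe a typical thermophilic bacterial chromosome profiled
#' with 50 bp strand-specific short reads: ~0.9 kb genes, short (~50 bp)
#' within-TU intergenic gaps, longer (~200 bp) between-TU gaps, 56% of TUs
#' carrying a single gene, coding GC 0.40 vs intergenic GC 0.33, ~0.5%
#' antisense signal, 225 bp long-read evidence and 170 bp paired-end
#' fragment spans.
#'
#' @slot nGenes number of genes to simulate.
#' @slot geneLengthMean,geneLengthSdLog lognormal gene-length model
#'   (mean bp; sd on the log scale).
#' @slot intraGapMean,interGapMean mean length (bp) of intergenic gaps
#'   within a TU and between TUs.
#' @slot tuSizeProbs probabilities of TU gene counts 1,2,3,4,5+ (sums to 1).
#' @slot codingGC,intergenicGC GC fraction inside genes / between genes.
#' @slot depth target estimated depth (X), i.e. coverage mass over coding bp.
#' @slot readLength short-read length (bp).
#' @slot exprSdLog sd of the per-TU lognormal expression level (log scale).
#' @slot overdispersion coefficient of variation of extra-Poisson noise on
#'   per-TU read counts.
#' @slot boundaryGapProb probability that a between-TU gap stays free of
#'   read-through coverage (hard boundary).
#' @slot antisenseRate expected antisense:sense coverage ratio over genes.
#' @slot longReadMeanLen,fragmentMeanLen mean lengths (bp) of long-read and
#'   paired-end-fragment spanning evidence.
#' @seealso [simConfig()], [simulateGenome()]
#' @export
setClass("SimConfig",
    representation(
        nGenes = "integer",
        geneLengthMean = "numeric",
        geneLengthSdLog = "numeric",
        intraGapMean = "numeric",
        interGapMean = "numeric",
        tuSizeProbs = "numeric",
        codingGC = "numeric",
        intergenicGC = "numeric",
        depth = "numeric",
        readLength = "integer",
        exprSdLog = "numeric",
        overdispersion = "numeric",
        boundaryGapProb = "numeric",
        antisenseRate = "numeric",
        longReadMeanLen = "numeric",
        fragmentMeanLen = "numeric"
    )
)

setValidity("SimConfig", function(object) {
    msg <- NULL
    if (object@nGenes < 2L) msg <- c(msg, "need at least 2 genes")
    if (length(object@tuSizeProbs) != 5L ||
        abs(sum(object@tuSizeProbs) - 1) > 1e-8 ||
        any(object@tuSizeProbs < 0))
        msg <- c(msg, "tuSizeProbs must be 5 non-negative values summing to 1")
    for (s in c("codingGC", "intergenicGC", "boundaryGapProb",
                "antisenseRate")) {
        v <- slot(object, s)
        if (v < 0 || v > 1) msg <- c(msg, paste(s, "must be in [0,1]"))
    }
    if (object@depth < 0) msg <- c(msg, "depth must be non-negative")
    if (any(c(object@geneLengthMean, object@intraGapMean, object@interGapMean,
              object@longReadMeanLen, object@fragmentMeanLen,
              object@readLength) <= 0))
        msg <- c(msg, "all lengths must be positive")
    if (is.null(msg)) TRUE else msg
})

#' SimTruth: a simulated genome with known TU structure
#'
#' @slot annotation the simulated [GenomeAnnotation-class] (with sequence).
#' @slot trueTUs ground-truth [TUSet-class]; every gene in exactly one TU.
#' @slot tuExpression per-TU relative expression level (median 1).
#' @slot config the [SimConfig-class] used.
#' @seealso [simulateGenome()], [simulateCoverage()], [truthJunctionKeys()]
#' @export
setClass("SimTruth",
    representation(
        annotation = "GenomeAnnotation",
        trueTUs = "TUSet",
        tuExpression = "numeric",
        config = "SimConfig"
    )
)
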