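#' Accessors for TUfinder classes
#'
#' `genomeId()`, `genomeLength()`, `genes()`, `genomeSequence()`,
#' `plusCoverage()`, `minusCoverage()`, `tuTable()`, `trueTUs()`,
#' `tuExpression()` and `cvAccuracy()` read the corresponding slots of
#' [GenomeAnnotation-class], [CoverageTrack-class], [TUSet-class],
#' [SimTruth-class] and [TUModel-class] objects.
#'
#' @param x an object of the relevant class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname accessors
#' @export
setGeneric("genomeSequence", function(x) standardGeneric("genomeSequence"))
#' @rdname accessors
#' @export
setGeneric("plusCoverage", function(x) standardGeneric("plusCoverage"))
#' @rdname accessors
#' @export
setGeneric("minusCoverage", function(x) standardGeneric("minusCoverage"))
#' @rdname accessors
#' @export
setGeneric("tuTable", function(x) standardGeneric("tuTable"))
#' @rdname accessors
#' @export
setGeneric("trueTUs", function(x) standardGeneric("trueTUs"))
#' @rdname accessors
#' @export
setGeneric("tuExpression", function(x) standardGeneric("tuExpression"))
#' @rdname accessors
#' @export
setGeneric("cvAccuracy", function(x) standardGeneric("cvAccuracy"))

#' @rdname accessors
setMethod("genomeId", "GenomeAnnotation", function(x) x@genomeId)
#' @rdname accessors
setMethod("genomeId", "CoverageTrack", function(x) x@genomeId)
#' @rdname accessors
setMethod("genomeId", "TUSet", function(x) x@genomeId)
#' @rdname accessors
setMethod("genomeLength", "GenomeAnnotation", function(x) x@genomeLength)
#' @rdname accessors
setMethod("genomeLength", "CoverageTrack", function(x) length(x@plus))
#' @rdname accessors
setMethod("genes", "GenomeAnnotation", function(x) x@genes)
#' @rdname accessors
setMethod("genomeSequence", "GenomeAnnotation", function(x) x@sequence)
#' @rdname accessors
setMethod("plusCoverage", "CoverageTrack", function(x) x@plus)
#' @rdname accessors
setMethod("minusCoverage", "CoverageTrack", function(x) x@minus)
#' @rdname accessors
setMethod("tuTable", "TUSet", function(x) x@tus)
#' @rdname accessors
setMethod("trueTUs", "SimTruth", function(x) x@trueTUs)
#' @rdname accessors
setMethod("genes", "SimTruth", function(x) genes(x@annotation))
#' @rdname accessors
setMethod("tuExpression", "SimTruth", function(x) x@tuExpression)
#' @rdname accessors
setMethod("cvAccuracy", "TUModel", function(x) x@cvAccuracy)

#' @importFrom utils head
setMethod("show", "GenomeAnnotation", function(object) {
    cat("GenomeAnnotation:", object@genomeId,
        sprintf("(%d bp)\n", object@genomeLength))
    st <- as.character(strand(object@genes))
    cat(sprintf("  %d genes (%d +, %d -), sequence %s\n",
        length(object@genes), sum(st == "+"), sum(st == "-"),
        if (is.null(object@sequence)) "absent" else "present"))
})

setMethod("show", "CoverageTrack", function(object) {
    cat("CoverageTrack:", object@genomeId,
        sprintf("(%d bp)\n", length(object@plus)))
    cat(sprintf("  total abundance: plus %.0f, minus %.0f\n",
        sum(as.numeric(object@plus)), sum(as.numeric(object@minus))))
})

setMethod("show", "TUSet", function(object) {
    n <- nrow(object@tus)
    cat("TUSet:", n, "TUs on", object@genomeId, "\n")
    if (n > 0L) {
        sz <- object@tus$nGenes
        cat(sprintf("  genes covered: %d; multi-gene TUs: %d (%.0f%%)\n",
            sum(sz), sum(sz > 1L), 100 * mean(sz > 1L)))
    }
})

setMethod("show", "TUModel", function(object) {
    cat("TUModel (RBF SVM), mode:", object@mode, "\n")
    cat(sprintf("  features: %s\n  cost=%g gamma=%g; CV accuracy %.3f\n",
        paste(object@featureNames, collapse = ", "),
        object@hyperparams$cost, object@hyperparams$gamma,
        object@cvAccuracy))
})

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:", genomeId(object@annotation), "\n")
    cat(sprintf("  %d genes in %d true TUs\n",
        length(genes(object@annotation)), nrow(tuTable(object@trueTUs))))
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(
        "SimConfig: %d genes, depth %gX, read length %d bp\n",
        object@nGenes, object@depth, object@readLength))
    cat(sprintf("  TU size probs (1..4,5+): %s\n",
        paste(format(object@tuSizeProbs), collapse = " ")))
})
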