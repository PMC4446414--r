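#' Load a genome annotation from GFF3 or GenBank
#'
#' Reads gene models from a GFF3 file (via \pkg{rtracklayer}) or a GenBank
#' flat file, optionally attaching the genome sequence from a FASTA file.
#' Only features of the requested type(s) are kept; by default `"gene"`
#' features are used, falling back to `"CDS"` when the file carries no
#' `gene` features (common in minimal GenBank records).
#'
#' @param file path to a GFF3 (`.gff`, `.gff3`) or GenBank (`.gb`, `.gbk`,
#'   `.gbff`) file; the format is sniffed from the extension unless given.
#' @param fasta optional FASTA path supplying the genome sequence; its
#'   length must agree with the length declared by the annotation.
#' @param featureTypes feature types to read, or `NULL` for the
#'   gene-then-CDS fallback.
#' @param format `"auto"`, `"gff3"` or `"genbank"`.
#' @return A [GenomeAnnotation-class] object with genes sorted by start.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3", "##sequence-region chr 1 1000",
#'   "chr\t.\tgene\t1\t300\t.\t+\t.\tID=g1",
#'   "chr\t.\tgene\t401\t700\t.\t+\t.\tID=g2"), gff)
#' loadAnnotation(gff)
#' @importFrom Biostrings readDNAStringSet DNAString
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @export
loadAnnotation <- function(file, fasta = NULL, featureTypes = NULL,
                           format = c("auto", "gff3", "genbank")) {
    format <- match.arg(format)
    if (format == "auto") {
        format <- if (grepl("\\.(gb|gbk|gbff|genbank)$", file,
                            ignore.case = TRUE)) "genbank" else "gff3"
    }
    if (format == "genbank") {
        parsed <- parseGenBank(file)
        genomeId <- parsed$genomeId
        genomeLength <- parsed$length
        tab <- parsed$features
        seqDNA <- parsed$sequence
    } else {
        gr <- rtracklayer::import(file, format = "gff3")
        genomeId <- GenomeInfoDb::seqlevels(gr)[1]
        if (is.na(genomeId) || length(genomeId) == 0L)
            genomeId <- as.character(seqnames(gr))[1]
        sl <- GenomeInfoDb::seqlengths(gr)[1]
        genomeLength <- if (!is.na(sl)) as.integer(sl) else NA_integer_
        if (is.na(genomeLength)) {
            # rtracklayer drops the ##sequence-region pragma; recover it
            head <- readLines(file, n = 50L)
            sr <- grep("^##sequence-region", head, value = TRUE)
            if (length(sr) >= 1L) {
                toks <- strsplit(trimws(sr[1]), "\\s+")[[1]]
                if (length(toks) >= 4L)
                    genomeLength <- as.integer(toks[4])
            }
        }
        ids <- mcols(gr)$ID
        if (is.null(ids)) ids <- rep(NA_character_, length(gr))
        for (alt in c("locus_tag", "Name", "gene")) {
            if (!is.null(mcols(gr)[[alt]]))
                ids <- ifelse(is.na(ids), mcols(gr)[[alt]], ids)
        }
        tab <- data.frame(
            type = as.character(mcols(gr)$type),
            start = start(gr), end = end(gr),
            strand = as.character(strand(gr)),
            gene_id = ids, stringsAsFactors = FALSE)
        seqDNA <- NULL
    }
    if (is.null(featureTypes)) {
        featureTypes <- "gene"
        if (!any(tab$type %in% featureTypes)) featureTypes <- "CDS"
    }
    tab <- tab[tab$type %in% featureTypes & tab$strand %in% c("+", "-"), ,
               drop = FALSE]
    if (nrow(tab) == 0L)
        stop("empty annotation: no usable gene features in ", file,
             call. = FALSE)
    miss <- is.na(tab$gene_id)
    if (any(miss))
        tab$gene_id[miss] <- sprintf("feature_%05d", which(miss))
    if (!is.null(fasta)) {
        ss <- readDNAStringSet(fasta)
        seqDNA <- ss[[1]]
        if (is.na(genomeLength))
            genomeLength <- length(seqDNA)
        else if (length(seqDNA) != genomeLength)
            stop("FASTA/annotation length mismatch: sequence ",
                 length(seqDNA), " bp vs declared ", genomeLength, " bp",
                 call. = FALSE)
    }
    if (is.na(genomeLength))
        genomeLength <- max(tab$end)
    gr <- GRanges(genomeId, IRanges(tab$start, tab$end),
                  strand = tab$strand)
    mcols(gr)$gene_id <- tab$gene_id
    GenomeAnnotation(genomeId, genomeLength, gr, sequence = seqDNA)
}

#' Write a GenomeAnnotation to GFF3
#'
#' Writes one `gene` feature per gene with its `gene_id` as the GFF3 `ID`
#' attribute, plus the `##sequence-region` pragma, so that
#' [loadAnnotation()] round-trips the annotation exactly.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeAnnotationGFF3 <- function(annotation, file) {
    g <- genes(annotation)
    lines <- c(
        "##gff-version 3",
        sprintf("##sequence-region %s 1 %d", genomeId(annotation),
                genomeLength(annotation)),
        sprintf("%s\tTUfinder\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                genomeId(annotation), start(g), end(g),
                as.character(strand(g)), mcols(g)$gene_id))
    writeLines(lines, file)
    invisible(file)
}

#' Derive consecutive same-strand gene pairs
#'
#' For each strand, walks the position-ordered genes and emits one
#' candidate junction per consecutive pair (no same-strand gene in
#' between). The intergenic region (IR) between a pair spans
#' `[left end + 1, right start - 1]`; overlapping or abutting genes yield
#' an empty IR and `overlapping = TRUE`. A pair is flagged
#' `oppositeBetween` when any opposite-strand gene intersects the IR.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @return A [S4Vectors::DataFrame] with one row per candidate junction:
#'   `leftId`, `rightId`, `strand`, `leftStart`, `leftEnd`, `rightStart`,
#'   `rightEnd`, `irStart`, `irEnd`, `irLength`, `oppositeBetween`,
#'   `overlapping`.
#' @examples
#' gr <- GenomicRanges::GRanges("g", IRanges::IRanges(
#'   c(1, 401, 801), c(300, 700, 1100)), strand = c("+", "-", "+"))
#' S4Vectors::mcols(gr)$gene_id <- c("A", "B", "C")
#' ann <- GenomeAnnotation("g", 1200, gr)
#' deriveGenePairs(ann)  # one +/+ pair (A,C) with oppositeBetween TRUE
#' @export
deriveGenePairs <- function(annotation) {
    g <- genes(annotation)
    stopIfNot(length(g) >= 1L, "annotation has no genes")
    out <- list()
    for (st in c("+", "-")) {
        gs <- g[as.character(strand(g)) == st]
        if (length(gs) < 2L) next
        n <- length(gs)
        li <- seq_len(n - 1L); ri <- li + 1L
        irStart <- end(gs)[li] + 1L
        irEnd <- start(gs)[ri] - 1L
        overlapping <- irEnd < irStart
        opp <- g[as.character(strand(g)) != st]
        oppBetween <- logical(n - 1L)
        if (length(opp) > 0L) {
            irv <- IRanges(pmin(irStart, irEnd + 1L),
                           width = pmax(irEnd - irStart + 1L, 0L))
            hits <- IRanges::overlapsAny(irv, IRanges::ranges(opp))
            oppBetween <- hits
        }
        out[[st]] <- DataFrame(
            leftId = mcols(gs)$gene_id[li],
            rightId = mcols(gs)$gene_id[ri],
            strand = st,
            leftStart = start(gs)[li], leftEnd = end(gs)[li],
            rightStart = start(gs)[ri], rightEnd = end(gs)[ri],
            irStart = irStart, irEnd = irEnd,
            irLength = pmax(irEnd - irStart + 1L, 0L),
            oppositeBetween = oppBetween,
            overlapping = overlapping)
    }
    if (length(out) == 0L)
        return(DataFrame(
            leftId = character(), rightId = character(),
            strand = character(), leftStart = integer(),
            leftEnd = integer(), rightStart = integer(),
            rightEnd = integer(), irStart = integer(), irEnd = integer(),
            irLength = integer(), oppositeBetween = logical(),
            overlapping = logical()))
    do.call(rbind, unname(out))
}

#' Intergenic regions of an annotation
#'
#' Per-strand intergenic regions between consecutive same-strand genes,
#' as used for the empirical length distributions and the inside/outside
#' TU expression contrast. Zero-length regions (abutting or overlapping
#' genes) are retained with `irLength == 0`.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @return `DataFrame` with `strand`, `leftGeneId`, `rightGeneId`,
#'   `start`, `end`, `irLength`.
#' @export
intergenicRegions <- function(annotation) {
    p <- deriveGenePairs(annotation)
    DataFrame(strand = p$strand, leftGeneId = p$leftId,
              rightGeneId = p$rightId, start = p$irStart, end = p$irEnd,
              irLength = p$irLength)
}
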