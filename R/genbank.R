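# Minimal GenBank flat-file reader for prokaryotic gene models.
# Reads the LOCUS length, gene/CDS features with plain or complement()
# single-interval locations, the /locus_tag or /gene qualifier, and the
# ORIGIN sequence block. Join() locations and multi-record files are out
# of scope for bacterial single-replicon annotations.

#' @importFrom Biostrings DNAString
parseGenBank <- function(file) {
    lines <- readLines(file, warn = FALSE)
    locus <- grep("^LOCUS", lines, value = TRUE)
    stopIfNot(length(locus) >= 1L, "not a GenBank file: no LOCUS line")
    toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
    genomeId <- toks[2]
    len <- suppressWarnings(as.integer(toks[3]))
    acc <- grep("^VERSION", lines, value = TRUE)
    if (length(acc) >= 1L) {
        v <- strsplit(trimws(acc[1]), "\\s+")[[1]]
        if (length(v) >= 2L) genomeId <- v[2]
    }

    featStart <- grep("^FEATURES", lines)
    featEnd <- grep("^(ORIGIN|CONTIG|//)", lines)
    featEnd <- featEnd[featEnd > featStart[1]][1]
    stopIfNot(length(featStart) == 1L && !is.na(featEnd),
              "malformed GenBank: FEATURES block not found")
    flines <- lines[(featStart + 1L):(featEnd - 1L)]

    # A feature header has its key in columns 6-20; qualifier/continuation
    # lines start at column 22.
    isHeader <- grepl("^ {5}\\S", flines)
    idx <- which(isHeader)
    feats <- list()
    for (k in seq_along(idx)) {
        block <- flines[idx[k]:(if (k < length(idx)) idx[k + 1L] - 1L
                                else length(flines))]
        key <- sub("^ {5}(\\S+).*", "\\1", block[1])
        if (!key %in% c("gene", "CDS")) next
        loc <- sub("^ {5}\\S+\\s+", "", block[1])
        compl <- grepl("^complement\\(", loc)
        nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
        if (length(nums) < 2L) next
        qual <- NA_character_
        for (q in c("locus_tag", "gene")) {
            m <- grep(sprintf('^/%s="?([^"]+)"?', q),
                      trimws(block), value = TRUE)
            if (length(m) >= 1L) {
                qual <- sub(sprintf('^/%s="?([^"]*)"?$', q), "\\1",
                            trimws(m[1]))
                break
            }
        }
        feats[[length(feats) + 1L]] <- data.frame(
            type = key,
            start = as.integer(nums[1]),
            end = as.integer(nums[length(nums)]),
            strand = if (compl) "-" else "+",
            gene_id = qual, stringsAsFactors = FALSE)
    }
    features <- if (length(feats)) do.call(rbind, feats) else
        data.frame(type = character(), start = integer(), end = integer(),
                   strand = character(), gene_id = character())

    seqDNA <- NULL
    ori <- grep("^ORIGIN", lines)
    if (length(ori) == 1L) {
        stopLine <- grep("^//", lines)
        stopLine <- stopLine[stopLine > ori][1]
        if (!is.na(stopLine) && stopLine > ori + 1L) {
            sl <- lines[(ori + 1L):(stopLine - 1L)]
            sq <- toupper(gsub("[^A-Za-z]", "", paste(sl, collapse = "")))
            if (nchar(sq) > 0L) seqDNA <- DNAString(sq)
        }
    }
    if (is.na(len) && !is.null(seqDNA)) len <- length(seqDNA)
    list(genomeId = genomeId, length = len, features = features,
         sequence = seqDNA)
}
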