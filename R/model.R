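#' Train the RBF-SVM junction classifier
#'
#' Fits a radial-basis support vector machine on junction feature vectors
#' labeled positive (co-transcribed) or negative, after per-feature
#' min-max scaling to `[0, 1]` fitted on the training set. Reports
#' stratified k-fold cross-validation accuracy with seeded fold
#' assignment, then refits on all data.
#'
#' Default hyperparameters are the customary SVM defaults: `cost = 1`,
#' `gamma = 1/n_features`, equal class weights.
#'
#' @param features `data.frame` of feature vectors ([extractFeatures()]).
#' @param labels character/factor vector of `"positive"`/`"negative"`.
#' @param folds number of cross-validation folds (default 5).
#' @param seed optional integer seed for fold assignment.
#' @param cost,gamma,classWeights SVM hyperparameters (`gamma = NULL`
#'   means `1/n_features`; `classWeights = NULL` means equal).
#' @param mode training-data composition tag: `"illumina_only"`
#'   (constructed positives only) or `"illumina_plus_long_read"`
#'   (constructed plus spanning-evidence positives).
#' @return A [TUModel-class] with slots `cvAccuracy` and
#'   `foldPredictions` (held-out `fold`, `truth`, `score`, `predicted`).
#' @importFrom e1071 svm
#' @importFrom stats predict setNames
#' @export
trainTUModel <- function(features, labels, folds = 5L, seed = NULL,
                         cost = 1, gamma = NULL, classWeights = NULL,
                         mode = c("illumina_plus_long_read",
                                  "illumina_only")) {
    mode <- match.arg(mode)
    x <- as.matrix(as.data.frame(features)[, FEATURE_NAMES])
    y <- factor(as.character(labels), levels = c("negative", "positive"))
    stopIfNot(nrow(x) == length(y), "features/labels length mismatch")
    if (length(unique(y[!is.na(y)])) < 2L)
        stop("degenerate training set: both classes required",
             call. = FALSE)
    stopIfNot(min(table(y)) >= folds,
              "need at least `folds` examples per class")
    if (is.null(gamma)) gamma <- 1 / ncol(x)
    scMin <- apply(x, 2, min)
    scMax <- apply(x, 2, max)
    xs <- scaleMinMax(x, scMin, scMax)

    foldId <- withSeed(seed, {
        f <- integer(length(y))
        for (cl in levels(y)) {
            idx <- which(y == cl)
            f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
        }
        f
    })
    fitOne <- function(xtr, ytr) {
        w <- if (is.null(classWeights))
            setNames(c(1, 1), levels(y)) else classWeights
        svm(xtr, ytr, kernel = "radial", cost = cost, gamma = gamma,
            class.weights = w, scale = FALSE)
    }
    preds <- data.frame(fold = foldId, truth = as.character(y),
                        score = NA_real_, predicted = NA_character_)
    for (k in seq_len(folds)) {
        tr <- foldId != k
        fit <- fitOne(xs[tr, , drop = FALSE], droplevels(y[tr]))
        sc <- decisionScores(fit, xs[!tr, , drop = FALSE])
        preds$score[!tr] <- sc$score
        preds$predicted[!tr] <- sc$label
    }
    cvAcc <- mean(preds$predicted == preds$truth)
    finalFit <- fitOne(xs, y)
    new("TUModel", fit = finalFit, featureNames = FEATURE_NAMES,
        scalerMin = scMin, scalerMax = scMax,
        hyperparams = list(cost = cost, gamma = gamma,
                           classWeights = classWeights),
        mode = mode, cvAccuracy = cvAcc, foldPredictions = preds,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

scaleMinMax <- function(x, mn, mx) {
    rng <- mx - mn
    rng[rng == 0] <- 1
    sweep(sweep(x, 2, mn, "-"), 2, rng, "/")
}

# Labels plus decision scores oriented so larger = more positive.
decisionScores <- function(fit, xs) {
    pr <- predict(fit, xs, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    sc <- dv[, 1]
    # e1071 orients the decision value toward the first class name in the
    # column header "A/B": positive score means class A
    first <- sub("/.*", "", colnames(dv)[1])
    if (first == "negative") sc <- -sc
    list(label = as.character(pr), score = sc)
}

#' Predict co-transcription for candidate junctions
#'
#' Applies a fitted [TUModel-class] to junction feature vectors; features
#' are scaled with the scaler fitted at training time.
#'
#' @param model a [TUModel-class].
#' @param features `data.frame` of feature vectors.
#' @return `data.frame` with `label` (`"positive"`/`"negative"`) and
#'   `score` (real decision value, larger = more confidently
#'   co-transcribed).
#' @export
predictPairs <- function(model, features) {
    fd <- as.data.frame(features)
    stopIfNot(all(model@featureNames %in% colnames(fd)),
              "feature dimension mismatch")
    x <- as.matrix(fd[, model@featureNames])
    if (nrow(x) == 0L)
        return(data.frame(label = character(), score = numeric()))
    xs <- scaleMinMax(x, model@scalerMin, model@scalerMax)
    sc <- decisionScores(model@fit, xs)
    data.frame(label = sc$label, score = sc$score)
}

#' Assemble transcription units from junction predictions
#'
#' Chains genes into TUs: on each strand, maximal runs of genes connected
#' by junctions predicted co-transcribed become multi-gene TUs; genes with
#' no positive junction become single-gene TUs. The result partitions the
#' gene set.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param pairPredictions the [deriveGenePairs()] table with a `label`
#'   column (`"positive"` joins the pair); rows may be a subset — missing
#'   junctions are treated as negative.
#' @param splitOnOpposite force junctions with an opposite-strand gene in
#'   between to be splits regardless of the classifier (default `FALSE`).
#' @param datasetId identifier stored in TU ids.
#' @return A [TUSet-class].
#' @export
assembleTUs <- function(annotation, pairPredictions,
                        splitOnOpposite = FALSE, datasetId = "ds") {
    g <- genes(annotation)
    pp <- as.data.frame(pairPredictions)
    joined <- pp$label == "positive"
    if (splitOnOpposite) joined <- joined & !pp$oppositeBetween
    key <- paste(pp$strand, pp$leftId, pp$rightId, sep = "\r")
    joinedKeys <- key[joined]
    rows <- list()
    for (st in c("+", "-")) {
        gs <- g[as.character(strand(g)) == st]
        if (length(gs) == 0L) next
        ids <- mcols(gs)$gene_id
        n <- length(gs)
        if (n > 1L) {
            jk <- paste(st, ids[-n], ids[-1], sep = "\r")
            cut <- !(jk %in% joinedKeys)
        } else cut <- logical(0)
        tuIdx <- cumsum(c(TRUE, cut))
        for (t in unique(tuIdx)) {
            members <- which(tuIdx == t)
            rows[[length(rows) + 1L]] <- list(
                strand = st,
                start = min(start(gs)[members]),
                end = max(end(gs)[members]),
                geneIds = ids[members])
        }
    }
    if (length(rows) == 0L)
        return(TUSet(genomeId(annotation), DataFrame(
            tuId = character(), strand = character(), start = integer(),
            end = integer(), nGenes = integer(),
            geneIds = CharacterList())))
    tus <- DataFrame(
        tuId = sprintf("%s_TU%04d", datasetId, seq_along(rows)),
        strand = vapply(rows, `[[`, character(1), "strand"),
        start = vapply(rows, `[[`, integer(1), "start"),
        end = vapply(rows, `[[`, integer(1), "end"),
        nGenes = vapply(rows, function(r) length(r$geneIds), integer(1)),
        geneIds = CharacterList(lapply(rows, `[[`, "geneIds")))
    TUSet(genomeId(annotation), tus)
}

#' TU size distribution
#'
#' Percentage of TUs containing 1, 2, 3, 4 and 5-or-more genes.
#'
#' @param tuset a [TUSet-class].
#' @return Named numeric vector over `c("1","2","3","4","5+")` summing to
#'   100.
#' @export
tuSizeDistribution <- function(tuset) {
    sz <- tuTable(tuset)$nGenes
    stopIfNot(length(sz) > 0L, "empty TU set")
    cat5 <- ifelse(sz >= 5L, "5+", as.character(sz))
    counts <- table(factor(cat5, levels = c("1", "2", "3", "4", "5+")))
    setNames(100 * as.numeric(counts) / sum(counts), names(counts))
}

#' ROC curve and AUC of junction scores
#'
#' Standard receiver operating characteristic over score thresholds, with
#' the fixed orientation "larger score means positive" (an inverted
#' ranking therefore yields AUC 0, not 0.5).
#'
#' @param truth true labels (`"positive"`/`"negative"`).
#' @param scores real decision scores.
#' @return List with `fpr`, `tpr` (threshold sweep, appended endpoints)
#'   and `auc`.
#' @export
rocCurve <- function(truth, scores) {
    truth <- as.character(truth)
    if (length(unique(truth)) < 2L)
        stop("single-class truth: ROC undefined", call. = FALSE)
    r <- pROC::roc(response = truth, predictor = as.numeric(scores),
                   levels = c("negative", "positive"), direction = "<",
                   quiet = TRUE)
    list(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities),
         auc = as.numeric(r$auc))
}

#' Fit a junction model from annotation, coverage and evidence
#'
#' Convenience wrapper over the full training workflow: derives candidate
#' pairs, selects gap/fold-change negatives, builds constructed-pair
#' positives (plus spanning-evidence positives when `evidence` is given
#' and `mode = "illumina_plus_long_read"`), extracts features and trains
#' the classifier.
#'
#' @param annotation a [GenomeAnnotation-class] with sequence.
#' @param track a [CoverageTrack-class].
#' @param evidence optional `GRanges` of long-read/fragment spans.
#' @param mode `"illumina_only"` uses constructed positives only.
#' @param seed integer seed (density draws and CV folds).
#' @param folds cross-validation folds.
#' @return List with `model` ([TUModel-class]), `pairs`, `negatives`,
#'   `positivePairs`, `ctus`, `features` and `labels`.
#' @export
fitJunctionModel <- function(annotation, track, evidence = NULL,
                             mode = c("illumina_plus_long_read",
                                      "illumina_only"),
                             seed = NULL, folds = 5L) {
    mode <- match.arg(mode)
    pairs <- deriveGenePairs(annotation)
    negs <- selectNegativePairs(pairs, track)
    dens <- fitLengthDensities(annotation, pairs)
    ctus <- constructCTUs(annotation, dens, track, seed = seed)
    posPairs <- NULL
    featList <- list(extractFeatures(negs, track),
                     extractFeatures(ctus, track))
    labList <- list(rep("negative", nrow(negs)),
                    rep("positive", nrow(ctus)))
    if (mode == "illumina_plus_long_read" && !is.null(evidence)) {
        posPairs <- selectPositivePairs(pairs, evidence, track)
        # keep the labeled sets disjoint: drop spanning positives that the
        # gap filter already claimed as negatives (cannot co-occur by
        # construction, but guard anyway)
        negKey <- paste(negs$strand, negs$leftId, negs$rightId)
        posKey <- paste(posPairs$strand, posPairs$leftId, posPairs$rightId)
        posPairs <- posPairs[!posKey %in% negKey, , drop = FALSE]
        featList <- c(featList, list(extractFeatures(posPairs, track)))
        labList <- c(labList, list(rep("positive", nrow(posPairs))))
    }
    features <- do.call(rbind, featList)
    labels <- unlist(labList)
    model <- trainTUModel(features, labels, folds = folds, seed = seed,
                          mode = mode)
    list(model = model, pairs = pairs, negatives = negs,
         positivePairs = posPairs, ctus = ctus, features = features,
         labels = labels)
}

#' Predict a TU set from a fitted model
#'
#' Scores every candidate junction of the annotation against the model
#' and assembles the resulting co-transcription calls into a [TUSet-class].
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param track a [CoverageTrack-class].
#' @param model a [TUModel-class].
#' @param splitOnOpposite see [assembleTUs()].
#' @param datasetId dataset tag for TU ids.
#' @return List with `tuset` ([TUSet-class]) and `pairPredictions`.
#' @export
predictTUs <- function(annotation, track, model, splitOnOpposite = FALSE,
                       datasetId = "ds") {
    pairs <- deriveGenePairs(annotation)
    feats <- extractFeatures(pairs, track)
    pred <- predictPairs(model, feats)
    pairs$label <- pred$label
    pairs$score <- pred$score
    tuset <- assembleTUs(annotation, pairs,
                         splitOnOpposite = splitOnOpposite,
                         datasetId = datasetId)
    list(tuset = tuset, pairPredictions = pairs)
}
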