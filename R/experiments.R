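#' @importFrom SummarizedExperiment colData
NULL

# Class labels for a task from sample metadata.
.taskLabels <- function(x, labelColumn) {
    as.character(sampleData(x)[[labelColumn]])
}

#' Screen the five feature-extraction methods
#'
#' For each method, trains a linear SVM on all source-domain samples and
#' reports resubstitution accuracy on the source (training set) next to
#' accuracy on all target-domain samples (testing set) — the screening that
#' exposes the cross-domain generalisation gap and ranks feature methods by
#' their transferability.
#'
#' @param source,target [ENoseSampleSet-class] objects for the two domains.
#' @param methods feature methods to screen.
#' @param labelColumn metadata column with the class label
#'   (`"pesticide"` for the qualitative task).
#' @param C SVM cost.
#' @param nCoeffs coefficients per sensor for FT/WT.
#' @return data.frame with columns `method`, `train_accuracy`
#'   (resubstitution on source), `test_accuracy` (on target).
#' @export
screenFeatures <- function(source, target,
                           methods = c("FT", "WT", "IV", "MAX", "Mean"),
                           labelColumn = "pesticide", C = 1, nCoeffs = 8L) {
    ys <- .taskLabels(source, labelColumn)
    yt <- .taskLabels(target, labelColumn)
    rows <- lapply(methods, function(m) {
        fs <- tryCatch(featureMatrix(extractFeatures(source, m, nCoeffs = nCoeffs)),
                       error = function(e) stop("feature extraction failed for method '",
                                                m, "': ", conditionMessage(e)))
        ft <- featureMatrix(extractFeatures(target, m, nCoeffs = nCoeffs))
        fit <- fitWeightedSVM(fs, ys, C = C)
        data.frame(method = m,
                   train_accuracy = evaluateAccuracy(predict(fit, fs), ys),
                   test_accuracy = evaluateAccuracy(predict(fit, ft), yt))
    })
    do.call(rbind, rows)
}

#' Stratified target-domain train/test split
#'
#' Draws a stratified random training set of exactly `Tt` samples
#' preserving class proportions (largest-remainder allocation); all
#' remaining samples form the test set. With the full qualitative design
#' this is the 30-train / 490-test split.
#'
#' @param target an [ENoseSampleSet-class].
#' @param Tt target training size (< number of samples).
#' @param labelColumn metadata column defining the strata.
#' @param seed optional integer seed.
#' @return list with integer index vectors `train` (length `Tt`) and
#'   `test`.
#' @export
splitTarget <- function(target, Tt, labelColumn = "pesticide", seed = NULL) {
    labels <- .taskLabels(target, labelColumn)
    .withSeed(seed, .stratifiedSplit(labels, as.integer(Tt)))
}

# One TL (or N = 0 baseline) accuracy: fit on source subset + target train,
# evaluate on target test.
.fitAndScore <- function(fs, ys, ft, yt, trainIdx, testIdx, srcIdx, N, C) {
    Xt <- ft[trainIdx, , drop = FALSE]; yTr <- yt[trainIdx]
    Xs <- fs[srcIdx, , drop = FALSE]; ySr <- ys[srcIdx]
    if (N == 0L) {
        fit <- fitWeightedSVM(rbind(Xs, Xt), c(ySr, yTr), C = C)
        pred <- predict(fit, ft[testIdx, , drop = FALSE])
    } else {
        fit <- tradaBoost(Xs, ySr, Xt, yTr, N = N, C = C)
        pred <- tradaboostPredict(fit, ft[testIdx, , drop = FALSE])
    }
    evaluateAccuracy(pred, yt[testIdx])
}

#' Sweep boosting iterations and source-training size
#'
#' For every seed and every grid point (N, Ts) of the design: draw a
#' stratified target train/test split (train size `Tt`), a nested
#' stratified source subset of size Ts (subsets for increasing Ts are
#' supersets, so accuracy changes along the Ts axis reflect added samples,
#' not resampling), fit TrAdaBoost (or, at N = 0, a single SVM on the
#' uniformly weighted union — the no-boosting baseline), and score on the
#' held-out target test set.
#'
#' @param source,target [ENoseSampleSet-class] objects.
#' @param design an [ExperimentDesign-class].
#' @param C SVM cost.
#' @return data.frame with columns `task`, `method` (`"TL"`, or
#'   `"Tc-SVM"` for the N = 0 baseline), `N`, `Ts`, `seed`, `accuracy`.
#' @export
sweepParameters <- function(source, target, design, C = 0.1) {
    validObject(design)
    fe <- design@featureMethod
    fs <- featureMatrix(extractFeatures(source, fe, nCoeffs = design@nCoeffs))
    ft <- featureMatrix(extractFeatures(target, fe, nCoeffs = design@nCoeffs))
    ys <- .taskLabels(source, design@labelColumn)
    yt <- .taskLabels(target, design@labelColumn)
    rows <- list()
    for (seed in design@seeds) {
        sp <- .withSeed(.childSeed(seed, "split"),
                        .stratifiedSplit(yt, design@Tt))
        stopifnot(length(intersect(sp$train, sp$test)) == 0L)
        ord <- .withSeed(.childSeed(seed, "subset"), .stratifiedOrder(ys))
        for (Ts in design@TsGrid) {
            if (Ts > length(ys)) {
                warning("skipping Ts = ", Ts, ": source pool has only ",
                        length(ys), " samples")
                next
            }
            srcIdx <- ord[seq_len(Ts)]
            for (N in design@NGrid) {
                if (Ts == 0L && N == 0L) next
                acc <- .fitAndScore(fs, ys, ft, yt, sp$train, sp$test,
                                    srcIdx, N, C)
                rows[[length(rows) + 1L]] <- data.frame(
                    task = design@task,
                    method = if (N == 0L) "Tc-SVM" else "TL",
                    N = N, Ts = Ts, seed = seed, accuracy = acc)
            }
        }
    }
    do.call(rbind, rows)
}

#' Compare transfer learning against the three SVM baselines
#'
#' Per seed, computes four accuracies on the same held-out target test
#' split: an SVM trained on the source subset only (Ts-SVM), an SVM on the
#' `Tt` target training samples only (Tt-SVM), an SVM on their union
#' (Tc-SVM), and TrAdaBoost on the same union (TL).
#'
#' @param source,target [ENoseSampleSet-class] objects.
#' @param design an [ExperimentDesign-class] (supplies feature method,
#'   labels, `Tt` and seeds).
#' @param Ts source training size; default the largest grid value.
#' @param N boosting iterations for TL; default the largest grid value.
#' @param C SVM cost.
#' @return data.frame with columns `task`, `method` (Ts-SVM / Tt-SVM /
#'   Tc-SVM / TL), `N`, `Ts`, `seed`, `accuracy`.
#' @export
compareMethods <- function(source, target, design, Ts = max(design@TsGrid),
                           N = max(design@NGrid), C = 0.1) {
    validObject(design)
    fe <- design@featureMethod
    fs <- featureMatrix(extractFeatures(source, fe, nCoeffs = design@nCoeffs))
    ft <- featureMatrix(extractFeatures(target, fe, nCoeffs = design@nCoeffs))
    ys <- .taskLabels(source, design@labelColumn)
    yt <- .taskLabels(target, design@labelColumn)
    if (Ts > length(ys))
        stop("Ts exceeds the source pool size")
    rows <- list()
    for (seed in design@seeds) {
        sp <- .withSeed(.childSeed(seed, "split"),
                        .stratifiedSplit(yt, design@Tt))
        ord <- .withSeed(.childSeed(seed, "subset"), .stratifiedOrder(ys))
        srcIdx <- ord[seq_len(Ts)]
        Xs <- fs[srcIdx, , drop = FALSE]; ySr <- ys[srcIdx]
        Xt <- ft[sp$train, , drop = FALSE]; yTr <- yt[sp$train]
        Xte <- ft[sp$test, , drop = FALSE]; yTe <- yt[sp$test]
        accs <- c(
            "Ts-SVM" = evaluateAccuracy(
                predict(fitWeightedSVM(Xs, ySr, C = C), Xte), yTe),
            "Tt-SVM" = evaluateAccuracy(
                predict(fitWeightedSVM(Xt, yTr, C = C), Xte), yTe),
            "Tc-SVM" = evaluateAccuracy(
                predict(fitWeightedSVM(rbind(Xs, Xt), c(ySr, yTr), C = C),
                        Xte), yTe),
            "TL" = evaluateAccuracy(
                tradaboostPredict(
                    tradaBoost(Xs, ySr, Xt, yTr, N = N, C = C), Xte), yTe))
        rows[[length(rows) + 1L]] <- data.frame(
            task = design@task, method = names(accs), N = N, Ts = Ts,
            seed = seed, accuracy = unname(accs))
    }
    do.call(rbind, rows)
}

#' Semi-quantitative analysis for one pesticide
#'
#' Restricts both domains to one pesticide's samples (120 each under the
#' full design), relabels them by concentration level (3 classes), and
#' delegates to [sweepParameters()] or [compareMethods()] with Mean
#' features — the per-pesticide concentration-recognition study.
#'
#' @param pesticide one of the polluted class labels.
#' @param source,target [ENoseSampleSet-class] objects.
#' @param design an [ExperimentDesign-class]; default [semiquantDesign()].
#' @param what `"compare"` or `"sweep"`.
#' @param Ts,N passed to [compareMethods()] when `what = "compare"`.
#' @param C SVM cost.
#' @return Result data.frame with an extra `pesticide` column.
#' @export
runSemiquant <- function(pesticide, source, target,
                         design = semiquantDesign(),
                         what = c("compare", "sweep"),
                         Ts = max(design@TsGrid), N = max(design@NGrid),
                         C = 0.1) {
    what <- match.arg(what)
    okClasses <- setdiff(unique(sampleData(source)$pesticide), "none")
    if (!pesticide %in% okClasses)
        stop("unknown pesticide: '", pesticide, "' (expected one of ",
             paste(okClasses, collapse = ", "), ")")
    src <- source[sampleData(source)$pesticide == pesticide]
    tgt <- target[sampleData(target)$pesticide == pesticide]
    res <- if (what == "compare")
        compareMethods(src, tgt, design, Ts = Ts, N = N, C = C)
    else sweepParameters(src, tgt, design, C = C)
    res$pesticide <- pesticide
    res
}

#' PCA diagnostic of domain separation
#'
#' Mean-centred principal component analysis of a feature matrix, returning
#' the 2-D score coordinates and explained-variance fractions — the
#' visual check that source- and target-domain samples occupy different
#' regions of feature space.
#'
#' @param features numeric matrix (samples x features) or a
#'   `SummarizedExperiment` from [extractFeatures()].
#' @param labels optional per-sample class labels (taken from `colData`
#'   when `features` is a `SummarizedExperiment`).
#' @param domains optional per-sample domain labels (likewise).
#' @return list with `scores` (samples x 2), `explainedVariance`
#'   (fractions for PC1, PC2), `labels`, `domains`.
#' @export
pcaDiagnostic <- function(features, labels = NULL, domains = NULL) {
    if (is(features, "SummarizedExperiment")) {
        cd <- colData(features)
        if (is.null(labels)) labels <- as.character(cd$pesticide)
        if (is.null(domains)) domains <- as.character(cd$domain)
        features <- featureMatrix(features)
    }
    features <- as.matrix(features)
    if (nrow(features) < 3L || ncol(features) < 2L)
        stop("need at least 3 samples and 2 feature dimensions")
    if (all(apply(features, 2, stats::sd) < 1e-12))
        stop("degenerate input: constant feature matrix")
    pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
    ev <- pc$sdev^2 / sum(pc$sdev^2)
    list(scores = pc$x[, 1:2, drop = FALSE],
         explainedVariance = ev[1:2],
         labels = labels, domains = domains)
}
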