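#' @importFrom S4Vectors DataFrame
NULL

#' Sample metadata accessor
#' @param x an [ENoseSampleSet-class].
#' @return A `DataFrame` with one row per sample.
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname sampleData
#' @export
setMethod("sampleData", "ENoseSampleSet", function(x) x@sampleData)

#' Retrieve one raw trace matrix
#' @param x an [ENoseSampleSet-class].
#' @param i sample index or sample_id.
#' @return numeric matrix, time points x sensors.
#' @export
sampleTrace <- function(x, i) {
    if (is.character(i)) i <- match(i, x@sampleData$sample_id)
    x@traces[[i]]
}

#' @describeIn ENoseSampleSet number of samples.
#' @param x an `ENoseSampleSet`.
#' @export
setMethod("length", "ENoseSampleSet", function(x) length(x@traces))

#' @describeIn ENoseSampleSet subset samples by index or logical mask.
#' @param i indices.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "ENoseSampleSet", function(x, i, j, ..., drop = FALSE) {
    if (is.logical(i)) i <- which(i)
    new("ENoseSampleSet", traces = x@traces[i],
        sampleData = x@sampleData[i, , drop = FALSE], acq = x@acq)
})

#' @describeIn ENoseSampleSet concatenate sample sets sharing an
#'   acquisition configuration.
#' @export
setMethod("c", "ENoseSampleSet", function(x, ...) {
    rest <- list(...)
    traces <- x@traces
    md <- x@sampleData
    for (y in rest) {
        stopifnot(is(y, "ENoseSampleSet"))
        if (!identical(nTimePoints(y@acq), nTimePoints(x@acq)) ||
            !identical(y@acq@nSensors, x@acq@nSensors))
            stop("cannot combine sample sets with different acquisition shapes")
        traces <- c(traces, y@traces)
        md <- rbind(md, y@sampleData)
    }
    new("ENoseSampleSet", traces = traces, sampleData = md, acq = x@acq)
})

setMethod("show", "ENoseSampleSet", function(object) {
    cat("ENoseSampleSet with", length(object), "samples\n")
    cat("  trace shape:", nTimePoints(object@acq), "x",
        object@acq@nSensors, "(time points x sensors)\n")
    md <- object@sampleData
    if (nrow(md)) {
        cat("  domains:", paste(unique(md$domain), collapse = ", "), "\n")
        tab <- table(md$pesticide)
        cat("  classes:",
            paste(sprintf("%s (%d)", names(tab), as.integer(tab)),
                  collapse = ", "), "\n")
    }
})

setMethod("show", "AcquisitionConfig", function(object) {
    cat(sprintf("AcquisitionConfig: %g s @ %g Hz, %d sensors, vMax %g V\n",
                object@durationS, object@rateHz, object@nSensors, object@vMax))
})

setMethod("show", "DatasetDesign", function(object) {
    cat("DatasetDesign:", samplesPerDomain(object), "samples/domain\n")
    cat("  classes:", paste(object@pesticideClasses, collapse = ", "), "\n")
    cat("  concentrations (ug/L):",
        paste(object@concentrations, collapse = ", "),
        "x", object@nPerConcentration, "samples;",
        object@nUnpolluted, "unpolluted\n")
})

setMethod("show", "DomainShiftParams", function(object) {
    cat(sprintf("DomainShiftParams: magnitude %.4g\n", object@magnitude))
    cat(sprintf("  gain in [%.3f, %.3f]; offset in [%.3f, %.3f] V; interference up to %.3f V\n",
                min(object@gain), max(object@gain),
                min(object@offsetV), max(object@offsetV),
                max(object@interferenceV)))
})

setMethod("show", "LinearSVM", function(object) {
    cat(sprintf("LinearSVM: %d classes, %d features, C = %g\n",
                length(object@classes), ncol(object@W), object@cost))
})

setMethod("show", "TrAdaBoostModel", function(object) {
    cat(sprintf("TrAdaBoostModel: %d/%d iterations, %d classes, beta = %.4f\n",
                object@nTrained, object@N, length(object@classes),
                object@betaSource))
    cat(sprintf("  vote over iterations %d..%d (weights ln(1/beta_t))\n",
                .voteStart(object), object@nTrained))
})

setMethod("show", "ExperimentDesign", function(object) {
    cat(sprintf("ExperimentDesign (%s): features %s, Tt = %d\n",
                object@task, object@featureMethod, object@Tt))
    cat("  N grid:", paste(object@NGrid, collapse = ", "), "\n")
    cat("  Ts grid:", paste(object@TsGrid, collapse = ", "), "\n")
    cat("  seeds:", length(object@seeds), "\n")
})
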