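#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors metadata
NULL

.featureMethods <- c("FT", "WT", "IV", "MAX", "Mean")

#' Extract fixed-length feature vectors from e-nose samples
#'
#' Implements the five feature-extraction methods used for sensor-array
#' pattern recognition, each producing one fixed-length descriptor per
#' sample by concatenating per-sensor features across the array:
#'
#' * **Mean** — per-sensor arithmetic mean voltage (steady state).
#' * **MAX** — per-sensor maximum voltage (steady state).
#' * **IV** — per-sensor integral of the response curve, computed by the
#'   trapezoid rule on the true time grid (volt-seconds).
#' * **FT** — per-sensor magnitudes of the first `nCoeffs` discrete Fourier
#'   coefficients (DC included); phase is discarded so the features are
#'   invariant to small acquisition-start offsets.
#' * **WT** — per-sensor first `nCoeffs` approximation coefficients of a
#'   level-`wtLevel` periodised discrete wavelet decomposition.
#'
#' @param x an [ENoseSampleSet-class].
#' @param method one of `"FT"`, `"WT"`, `"IV"`, `"MAX"`, `"Mean"`.
#' @param nCoeffs transform coefficients kept per sensor (FT/WT only).
#' @param wavelet wavelet basis name for WT (`"db1"`, `"db2"`, `"db4"`).
#' @param wtLevel decomposition level for WT.
#' @return A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#'   with one assay `"features"` (features x samples), the sample metadata
#'   as `colData`, and the extraction settings in `metadata()`. Under the
#'   default 26-sensor configuration, FT/WT with `nCoeffs = 8` give 208
#'   features and the steady-state methods give 26.
#' @examples
#' acq <- acquisitionConfig(durationS = 1, rateHz = 16, nSensors = 4)
#' ds <- generateDomainDataset(datasetDesign(nUnpolluted = 2L,
#'                                           nPerConcentration = 1L),
#'                             "source", defaultResponseModel(acq),
#'                             acq = acq, seed = 1)
#' fe <- extractFeatures(ds, "Mean")
#' dim(fe)  # 4 features x 14 samples
#' @export
extractFeatures <- function(x, method = c("Mean", "MAX", "IV", "FT", "WT"),
                            nCoeffs = 8L, wavelet = "db4", wtLevel = 3L) {
    method <- match.arg(method)
    if (length(x) == 0L)
        stop("empty sample set")
    feats <- switch(method,
        Mean = vapply(x@traces, colMeans, numeric(x@acq@nSensors)),
        MAX = vapply(x@traces, function(m) apply(m, 2, max),
                     numeric(x@acq@nSensors)),
        IV = vapply(x@traces, .integralValue, numeric(x@acq@nSensors),
                    dt = 1 / x@acq@rateHz),
        FT = vapply(x@traces, .fourierMagnitudes,
                    numeric(x@acq@nSensors * nCoeffs), nCoeffs = nCoeffs),
        WT = vapply(x@traces, .waveletApprox,
                    numeric(x@acq@nSensors * nCoeffs), nCoeffs = nCoeffs,
                    wavelet = wavelet, level = wtLevel)
    )
    if (is.null(dim(feats))) feats <- matrix(feats, ncol = length(x))
    perSensor <- nrow(feats) / x@acq@nSensors
    rownames(feats) <- paste0("s", rep(seq_len(x@acq@nSensors), each = perSensor),
                              if (perSensor > 1) paste0("_c", seq_len(perSensor)) else "")
    colnames(feats) <- x@sampleData$sample_id
    SummarizedExperiment(
        assays = list(features = feats),
        colData = x@sampleData,
        metadata = list(method = method, nCoeffs = nCoeffs,
                        wavelet = wavelet, wtLevel = wtLevel))
}

# Trapezoid integral of each sensor trace over the true time grid, in V*s.
.integralValue <- function(m, dt) {
    dt * (colSums(m) - 0.5 * (m[1L, ] + m[nrow(m), ]))
}

# First nCoeffs DFT magnitudes per sensor (DC included), concatenated.
.fourierMagnitudes <- function(m, nCoeffs) {
    if (nCoeffs < 1L || nCoeffs > nrow(m))
        stop("nCoeffs must be between 1 and the trace length")
    as.numeric(Mod(stats::mvfft(m)[seq_len(nCoeffs), , drop = FALSE]))
}

# First nCoeffs level-`level` approximation coefficients per sensor.
.waveletApprox <- function(m, nCoeffs, wavelet, level) {
    out <- apply(m, 2, function(v) {
        a <- .dwtApprox(v, wavelet, level)
        if (nCoeffs > length(a))
            stop("nCoeffs (", nCoeffs, ") exceeds the ", length(a),
                 " available level-", level, " approximation coefficients")
        a[seq_len(nCoeffs)]
    })
    as.numeric(out)
}

#' Feature matrix in samples-by-features orientation
#'
#' Convenience transpose of the `"features"` assay for use with classifiers.
#' @param fe a `SummarizedExperiment` from [extractFeatures()].
#' @return numeric matrix, samples x features.
#' @export
featureMatrix <- function(fe) t(assay(fe, "features"))
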