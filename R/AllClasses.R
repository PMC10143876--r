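#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Acquisition configuration for one e-nose measurement
#'
#' Describes how a single measurement is digitised: a fixed-length record of
#' `durationS * rateHz` rows (time points) by `nSensors` columns (sensor
#' channels), each entry the conditioning-circuit output voltage. Defaults
#' follow the reference protocol: 60 s at 100 Hz over a 26-sensor
#' metal-oxide-semiconductor (MOS) array powered at 5 V, so every sample
#' matrix is 6000 x 26 and all voltages live in [0, 5].
#'
#' @slot durationS numeric(1), record duration in seconds.
#' @slot rateHz numeric(1), sampling rate in Hz.
#' @slot nSensors integer(1), number of sensor channels.
#' @slot baselineV numeric, clean-air baseline voltage per sensor (volts).
#' @slot vMax numeric(1), supply-rail voltage; traces are clipped to
#'   `[0, vMax]`.
#'
#' @seealso [acquisitionConfig()]
#' @export
setClass("AcquisitionConfig",
    representation(
        durationS = "numeric",
        rateHz = "numeric",
        nSensors = "integer",
        baselineV = "numeric",
        vMax = "numeric"
    )
)

setValidity("AcquisitionConfig", function(object) {
    msg <- character()
    if (object@durationS <= 0 || object@rateHz <= 0)
        msg <- c(msg, "durationS and rateHz must be positive")
    nrows <- object@durationS * object@rateHz
    if (!isTRUE(all.equal(nrows, round(nrows))) || nrows < 1)
        msg <- c(msg, "durationS * rateHz must be a positive integer")
    if (object@nSensors < 1L)
        msg <- c(msg, "nSensors must be >= 1")
    if (length(object@baselineV) != object@nSensors)
        msg <- c(msg, "baselineV must have one entry per sensor")
    if (any(object@baselineV < 0) || any(object@baselineV >= object@vMax))
        msg <- c(msg, "baselineV must satisfy 0 <= baselineV < vMax")
    if (length(msg)) msg else TRUE
})

#' Sampling plan for a two-domain e-nose dataset
#'
#' The design the generator realises for each domain: a set of pesticide
#' classes (including the unpolluted class `"none"`), a grid of spiked
#' concentrations, and the cell counts. Default counts reproduce the study
#' layout: per domain, 40 unpolluted samples plus 4 pesticide classes x
#' 3 concentrations x 40 samples = 520 samples.
#'
#' @slot pesticideClasses character, class labels; must contain `"none"`.
#' @slot concentrations numeric, spiked concentrations in micrograms/litre
#'   for the polluted classes (the unpolluted class has concentration 0).
#' @slot nUnpolluted integer(1), unpolluted samples per domain.
#' @slot nPerConcentration integer(1), samples per (class, concentration)
#'   cell per domain.
#'
#' @seealso [datasetDesign()], [reducedDesign()]
#' @export
setClass("DatasetDesign",
    representation(
        pesticideClasses = "character",
        concentrations = "numeric",
        nUnpolluted = "integer",
        nPerConcentration = "integer"
    )
)

setValidity("DatasetDesign", function(object) {
    msg <- character()
    if (!"none" %in% object@pesticideClasses)
        msg <- c(msg, "pesticideClasses must contain 'none'")
    if (anyDuplicated(object@pesticideClasses))
        msg <- c(msg, "pesticideClasses must be unique")
    if (length(object@concentrations) < 1 ||
        any(object@concentrations <= 0) ||
        is.unsorted(object@concentrations, strictly = TRUE))
        msg <- c(msg, "concentrations must be positive and strictly increasing")
    if (object@nUnpolluted < 0L || object@nPerConcentration < 0L)
        msg <- c(msg, "counts must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Generative model of the sensor array's response
#'
#' The synthetic instrument. Each sensor's trace rises first-order from its
#' baseline towards a plateau: `baseline + A * (1 - exp(-t / tau))`, where
#' the plateau amplitude `A` couples a per-(sensor, class) sensitivity (volts
#' at the reference concentration) with a saturating concentration response
#' `log1p(c / conc0) / log1p(concMax / conc0)` normalised to 1 at `concMax`.
#' Sample-to-sample realism comes from three stochastic terms: additive
#' Gaussian measurement noise per time point, lognormal amplitude jitter
#' (one global draw per sample plus one per sensor, emulating headspace and
#' sensor-state variability), and a per-sample Gaussian baseline drift.
#'
#' @slot sensitivity matrix, sensors x pesticide classes, response amplitude
#'   in volts at the reference concentration; all entries >= 0.
#' @slot tauS numeric, per-sensor rise time constant in seconds; > 0.
#' @slot conc0 numeric(1), softness of the logarithmic concentration
#'   response (micrograms/litre).
#' @slot concMax numeric(1), reference concentration at which the
#'   concentration multiplier equals 1.
#' @slot noiseSd numeric(1), measurement noise s.d. in volts.
#' @slot ampJitterSd numeric(1), s.d. of per-sensor lognormal amplitude
#'   jitter (log scale) for typical samples.
#' @slot scaleJitterSd numeric(1), s.d. of the per-sample global lognormal
#'   amplitude jitter (log scale).
#' @slot baselineJitterSd numeric(1), s.d. of per-sample baseline drift in
#'   volts.
#' @slot outlierProb numeric(1), probability that a sample is a degraded
#'   replicate (poor headspace delivery / disturbed sensor state).
#' @slot outlierJitterSd numeric(1), per-sensor amplitude jitter s.d. used
#'   for degraded replicates.
#' @slot driftLoadings matrix, sensors x latent factors: correlated
#'   amplitude drift directions (background volatiles / sensor state)
#'   shared by all samples of an instrument.
#' @slot driftSd numeric(1), s.d. of each latent drift factor (volts).
#'
#' @seealso [responseModel()], [defaultResponseModel()]
#' @export
setClass("SensorResponseModel",
    representation(
        sensitivity = "matrix",
        tauS = "numeric",
        conc0 = "numeric",
        concMax = "numeric",
        noiseSd = "numeric",
        ampJitterSd = "numeric",
        scaleJitterSd = "numeric",
        baselineJitterSd = "numeric",
        outlierProb = "numeric",
        outlierJitterSd = "numeric",
        driftLoadings = "matrix",
        driftSd = "numeric"
    )
)

setValidity("SensorResponseModel", function(object) {
    msg <- character()
    if (any(object@sensitivity < 0))
        msg <- c(msg, "sensitivity amplitudes must be >= 0")
    if (length(object@tauS) != nrow(object@sensitivity))
        msg <- c(msg, "tauS must have one entry per sensor")
    if (any(object@tauS <= 0))
        msg <- c(msg, "tauS must be positive")
    if (object@conc0 <= 0 || object@concMax <= 0)
        msg <- c(msg, "conc0 and concMax must be positive")
    if (object@noiseSd < 0 || object@ampJitterSd < 0 ||
        object@scaleJitterSd < 0 || object@baselineJitterSd < 0 ||
        object@outlierJitterSd < 0)
        msg <- c(msg, "noise standard deviations must be >= 0")
    if (object@outlierProb < 0 || object@outlierProb > 1)
        msg <- c(msg, "outlierProb must lie in [0, 1]")
    if (nrow(object@driftLoadings) > 0 &&
        nrow(object@driftLoadings) != nrow(object@sensitivity))
        msg <- c(msg, "driftLoadings must have one row per sensor")
    if (object@driftSd < 0)
        msg <- c(msg, "driftSd must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Between-domain response shift
#'
#' Parameterises how the shifted (target) domain's responses differ from the
#' source domain's: a per-sensor multiplicative gain on the response
#' amplitude, a per-sensor additive plateau offset, and a per-sensor additive
#' interference amplitude from domain-specific background volatiles. A scalar
#' `magnitude` records how far the parameters sit from the identity;
#' `magnitude = 0` forces gain 1, offset 0 and interference 0 everywhere.
#'
#' @slot gain numeric, per-sensor multiplicative factor (1 = no shift).
#' @slot offsetV numeric, per-sensor additive plateau shift (volts).
#' @slot interferenceV numeric, per-sensor additive response amplitude from
#'   background volatiles (volts).
#' @slot magnitude numeric(1), scalar distance from the identity shift.
#'
#' @seealso [domainShift()], [calibrateShift()]
#' @export
setClass("DomainShiftParams",
    representation(
        gain = "numeric",
        offsetV = "numeric",
        interferenceV = "numeric",
        magnitude = "numeric"
    )
)

setValidity("DomainShiftParams", function(object) {
    msg <- character()
    n <- length(object@gain)
    if (length(object@offsetV) != n || length(object@interferenceV) != n)
        msg <- c(msg, "gain, offsetV and interferenceV must share a length")
    if (object@magnitude < 0)
        msg <- c(msg, "magnitude must be >= 0")
    if (object@magnitude == 0 &&
        (any(object@gain != 1) || any(object@offsetV != 0) ||
         any(object@interferenceV != 0)))
        msg <- c(msg, "magnitude 0 requires the identity shift")
    if (length(msg)) msg else TRUE
})

#' A set of e-nose measurements with sample metadata
#'
#' Container pairing raw trace matrices (rows = time points, columns =
#' sensors, values = volts) with per-sample metadata: `sample_id`, `domain`
#' (source/target), `pesticide` class and `concentration_ug_L`. Supports
#' `length()`, `[` subsetting and `c()` concatenation; metadata is retrieved
#' with [sampleData()] and individual traces with [sampleTrace()].
#'
#' @slot traces list of numeric matrices, one per sample, each
#'   `(durationS * rateHz) x nSensors` with entries in `[0, vMax]`.
#' @slot sampleData DataFrame with columns `sample_id`, `domain`,
#'   `pesticide`, `concentration_ug_L`.
#' @slot acq the [AcquisitionConfig-class] the traces were generated under.
#'
#' @seealso [generateDomainDataset()], [readManifest()]
#' @export
setClass("ENoseSampleSet",
    representation(
        traces = "list",
        sampleData = "DataFrame",
        acq = "AcquisitionConfig"
    )
)

setValidity("ENoseSampleSet", function(object) {
    msg <- character()
    if (length(object@traces) != nrow(object@sampleData))
        msg <- c(msg, "one metadata row per trace required")
    need <- c("sample_id", "domain", "pesticide", "concentration_ug_L")
    if (!all(need %in% colnames(object@sampleData)))
        msg <- c(msg, paste("sampleData must have columns:",
                            paste(need, collapse = ", ")))
    nr <- as.integer(object@acq@durationS * object@acq@rateHz)
    nc <- object@acq@nSensors
    for (i in seq_along(object@traces)) {
        m <- object@traces[[i]]
        if (!is.matrix(m) || nrow(m) != nr || ncol(m) != nc) {
            msg <- c(msg, sprintf("trace %d is not a %d x %d matrix", i, nr, nc))
            break
        }
        if (!all(is.finite(m)) || min(m) < 0 || max(m) > object@acq@vMax) {
            msg <- c(msg, sprintf(
                "trace %d has entries outside [0, vMax] or non-finite", i))
            break
        }
    }
    if (length(msg)) msg else TRUE
})

#' Per-sample-weighted linear support vector machine
#'
#' A linear-kernel maximum-margin classifier fitted in the primal with an
#' L2-regularised, per-sample-weighted squared-hinge loss; multiclass
#' problems are handled one-vs-rest with argmax decision values. Features
#' are standardised with weighted training-set statistics stored in the
#' model, so prediction applies the same transform.
#'
#' @slot classes character, class labels in canonical (sorted) order.
#' @slot W matrix, classes x features, hyperplane normals on the
#'   standardised scale.
#' @slot b numeric, per-class intercepts.
#' @slot center,scale numeric, weighted feature means / s.d.s used for
#'   standardisation.
#' @slot cost numeric(1), misclassification cost.
#'
#' @seealso [fitWeightedSVM()]
#' @export
setClass("LinearSVM",
    representation(
        classes = "character",
        W = "matrix",
        b = "numeric",
        center = "numeric",
        scale = "numeric",
        cost = "numeric"
    )
)

#' Multiclass TrAdaBoost ensemble over weighted linear SVMs
#'
#' Instance-based transfer model: an ordered list of base hypotheses fitted
#' on re-weighted source + target data, the per-iteration target-error
#' ratios `beta_t = eps_t / (1 - eps_t)`, and the fixed source discount
#' `beta = 1 / (1 + sqrt(2 ln(n_source) / N))`. Prediction is a plurality
#' vote with weights `ln(1 / beta_t)` over the last half of the completed
#' iterations.
#'
#' @slot hypotheses list of [LinearSVM-class] base classifiers, in
#'   iteration order.
#' @slot betaT numeric, per-iteration target-error ratios, each in (0, 1).
#' @slot betaSource numeric(1), the fixed source discount in (0, 1]
#'   (1 when the source set is empty).
#' @slot N integer(1), maximum iterations requested.
#' @slot nTrained integer(1), iterations actually completed (early stopping
#'   can make this < N).
#' @slot classes character, class labels in canonical order.
#'
#' @seealso [tradaBoost()], [sourceDiscount()]
#' @export
setClass("TrAdaBoostModel",
    representation(
        hypotheses = "list",
        betaT = "numeric",
        betaSource = "numeric",
        N = "integer",
        nTrained = "integer",
        classes = "character"
    )
)

setValidity("TrAdaBoostModel", function(object) {
    msg <- character()
    if (length(object@hypotheses) != object@nTrained ||
        length(object@betaT) != object@nTrained)
        msg <- c(msg, "hypotheses and betaT must have length nTrained")
    if (object@nTrained > object@N)
        msg <- c(msg, "nTrained cannot exceed N")
    if (object@nTrained >= 1L &&
        (any(object@betaT <= 0) || any(object@betaT >= 1)))
        msg <- c(msg, "every betaT must lie in (0, 1)")
    if (object@betaSource <= 0 || object@betaSource > 1)
        msg <- c(msg, "betaSource must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Design of a sweep / comparison experiment
#'
#' Houses the experiment-level knobs: the task (qualitative 5-class
#' pesticide recognition or semi-quantitative 3-class concentration
#' recognition), the boosting-iteration grid `NGrid`, the source-training-set
#' size grid `TsGrid`, the fixed target training size `Tt`, the feature
#' method, which metadata column provides the class labels, and the seeds
#' over which stochastic results are averaged.
#'
#' @slot task character(1), `"qualitative"` or `"semiquant"`.
#' @slot NGrid integer, boosting iteration counts (0 = no-boosting baseline).
#' @slot TsGrid integer, source training sizes.
#' @slot Tt integer(1), target training size.
#' @slot featureMethod character(1), one of FT, WT, IV, MAX, Mean.
#' @slot nCoeffs integer(1), transform coefficients per sensor (FT/WT).
#' @slot labelColumn character(1), metadata column holding the class label.
#' @slot seeds integer, seeds for stochastic replication.
#'
#' @seealso [qualitativeDesign()], [semiquantDesign()]
#' @export
setClass("ExperimentDesign",
    representation(
        task = "character",
        NGrid = "integer",
        TsGrid = "integer",
        Tt = "integer",
        featureMethod = "character",
        nCoeffs = "integer",
        labelColumn = "character",
        seeds = "integer"
    )
)

setValidity("ExperimentDesign", function(object) {
    msg <- character()
    if (!object@task %in% c("qualitative", "semiquant"))
        msg <- c(msg, "task must be 'qualitative' or 'semiquant'")
    if (any(object@NGrid < 0L))
        msg <- c(msg, "NGrid entries must be >= 0")
    if (any(object@TsGrid < 0L))
        msg <- c(msg, "TsGrid entries must be >= 0")
    if (object@Tt < 1L)
        msg <- c(msg, "Tt must be >= 1")
    if (!object@featureMethod %in% c("FT", "WT", "IV", "MAX", "Mean"))
        msg <- c(msg, "featureMethod must be one of FT, WT, IV, MAX, Mean")
    if (length(object@seeds) < 1L)
        msg <- c(msg, "at least one seed is required")
    if (length(msg)) msg else TRUE
})
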