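#' Create an acquisition configuration
#'
#' @param durationS record duration in seconds.
#' @param rateHz sampling rate in Hz.
#' @param nSensors number of sensor channels.
#' @param baselineV clean-air baseline voltage per sensor; recycled to
#'   `nSensors`. Defaults to an evenly spaced spread in (0.5, 1.5) V.
#' @param vMax supply-rail voltage in volts.
#' @return An [AcquisitionConfig-class] object.
#' @examples
#' acq <- acquisitionConfig()
#' nTimePoints(acq)  # 6000
#' @export
acquisitionConfig <- function(durationS = 60, rateHz = 100, nSensors = 26L,
                              baselineV = NULL, vMax = 5.0) {
    nSensors <- as.integer(nSensors)
    if (is.null(baselineV))
        baselineV <- seq(0.5, 1.5, length.out = max(nSensors, 2L))[seq_len(nSensors)]
    baselineV <- rep_len(baselineV, nSensors)
    new("AcquisitionConfig", durationS = durationS, rateHz = rateHz,
        nSensors = nSensors, baselineV = baselineV, vMax = vMax)
}

#' Number of time points per trace
#' @param acq an [AcquisitionConfig-class].
#' @return integer, `durationS * rateHz`.
#' @export
nTimePoints <- function(acq) as.integer(round(acq@durationS * acq@rateHz))

#' Default pesticide classes
#'
#' The five classes of the study design: unpolluted plus four pesticides.
#' @return character vector of class labels.
#' @export
pesticideClasses <- function() {
    c("none", "chlorpyrifos", "malathion", "chlorothalonil", "lindane")
}

#' Create a dataset sampling design
#'
#' Defaults reproduce the study layout: per domain, 40 unpolluted samples
#' plus 4 pesticide classes x {100, 500, 1000} ug/L x 40 samples = 520.
#'
#' @param pesticideClasses class labels including `"none"`.
#' @param concentrations spiked concentrations in ug/L.
#' @param nUnpolluted unpolluted samples per domain.
#' @param nPerConcentration samples per (class, concentration) cell.
#' @return A [DatasetDesign-class].
#' @examples
#' d <- datasetDesign()
#' samplesPerDomain(d)  # 520
#' @export
datasetDesign <- function(pesticideClasses = enoseTransfer::pesticideClasses(),
                          concentrations = c(100, 500, 1000),
                          nUnpolluted = 40L, nPerConcentration = 40L) {
    new("DatasetDesign", pesticideClasses = pesticideClasses,
        concentrations = as.numeric(concentrations),
        nUnpolluted = as.integer(nUnpolluted),
        nPerConcentration = as.integer(nPerConcentration))
}

#' Reduced design for fast benchmarking
#'
#' Same class/concentration structure as [datasetDesign()] with all cell
#' counts divided by four: 10 unpolluted + 4 x 3 x 10 = 130 samples per
#' domain. Used for calibration and seed-averaged benchmark runs.
#' @return A [DatasetDesign-class].
#' @export
reducedDesign <- function() {
    datasetDesign(nUnpolluted = 10L, nPerConcentration = 10L)
}

#' Samples per domain implied by a design
#' @param design a [DatasetDesign-class].
#' @return integer sample count for one domain.
#' @export
samplesPerDomain <- function(design) {
    nClassesPolluted <- length(design@pesticideClasses) - 1L
    design@nUnpolluted +
        nClassesPolluted * length(design@concentrations) * design@nPerConcentration
}

#' Create a sensor response model
#'
#' See [SensorResponseModel-class] for the meaning of each parameter.
#'
#' @param sensitivity sensors x polluted-classes matrix of response
#'   amplitudes (volts at `concMax`); column names are the class labels.
#' @param tauS per-sensor rise time constants in seconds.
#' @param conc0,concMax parameters of the saturating concentration response.
#' @param noiseSd measurement noise s.d. (volts).
#' @param ampJitterSd,scaleJitterSd lognormal amplitude jitter s.d.s
#'   (log scale): per-sensor and global-per-sample.
#' @param baselineJitterSd per-sample baseline drift s.d. (volts).
#' @param outlierProb fraction of degraded replicates.
#' @param outlierJitterSd per-sensor amplitude jitter s.d. for degraded
#'   replicates.
#' @param driftLoadings sensors x factors matrix of correlated amplitude
#'   drift directions; a 0-row matrix disables drift.
#' @param driftSd s.d. of each latent drift factor (volts).
#' @return A [SensorResponseModel-class].
#' @export
responseModel <- function(sensitivity, tauS, conc0 = 100, concMax = 1000,
                          noiseSd = 0.02, ampJitterSd = 0.06,
                          scaleJitterSd = 0.04, baselineJitterSd = 0.05,
                          outlierProb = 0, outlierJitterSd = 0.4,
                          driftLoadings = matrix(numeric(0), 0L, 0L),
                          driftSd = 0.25) {
    new("SensorResponseModel", sensitivity = sensitivity, tauS = tauS,
        conc0 = conc0, concMax = concMax, noiseSd = noiseSd,
        ampJitterSd = ampJitterSd, scaleJitterSd = scaleJitterSd,
        baselineJitterSd = baselineJitterSd, outlierProb = outlierProb,
        outlierJitterSd = outlierJitterSd, driftLoadings = driftLoadings,
        driftSd = driftSd)
}

#' The frozen default instrument
#'
#' MOS arrays are strongly cross-sensitive: every sensor responds to every
#' analyte with broadly similar magnitude, and class discrimination rides
#' on modest deviations around a shared response profile. The default
#' instrument draws one per-sensor base amplitude profile from
#' Uniform(0.2, 2) V and gives each pesticide class a sensitivity
#' `base * (1 + deviationScale * z)` with z ~ N(0, 1), floored at 0.05 V;
#' rise time constants come from Uniform(2, 10) s. The array has two
#' sensor families, as commercial MOS line-ups do: one half of the array
#' responds strongly to the organophosphates (chlorpyrifos, malathion; the
#' other classes see it weakly) and the other half to the organochlorines
#' (chlorothalonil, lindane). Within the organophosphate family the two
#' fingerprints differ by a per-sensor ratio vector — chemically related
#' analytes excite the family in proportionally related ways — which is
#' what lets a between-domain gain pattern on that family collide one
#' class's source fingerprint with the other's target fingerprint (see
#' [domainShift()]). All draws happen under a fixed internal seed, so
#' every analysis and test shares a single reproducible "instrument".
#'
#' @param acq the acquisition configuration (supplies the sensor count).
#' @param classes pesticide class labels; the `"none"` class has zero
#'   sensitivity by construction and is excluded from the matrix.
#' @param deviationScale relative size of class-specific sensitivity
#'   deviations around the shared profile.
#' @param ... further arguments passed to [responseModel()] (noise and
#'   jitter levels).
#' @return A [SensorResponseModel-class].
#' @examples
#' m <- defaultResponseModel()
#' dim(m@sensitivity)  # 26 x 4
#' @export
defaultResponseModel <- function(acq = acquisitionConfig(),
                                 classes = pesticideClasses(),
                                 deviationScale = 0.18, ...) {
    polluted <- setdiff(classes, "none")
    nS <- acq@nSensors
    .withSeed(104729, {
        base <- stats::runif(nS, 0.2, 2.0)
        z <- matrix(stats::rnorm(nS * length(polluted)), nrow = nS,
                    dimnames = list(NULL, polluted))
        sens <- pmax(base * (1 + deviationScale * z), 0.05)
        if (identical(polluted, c("chlorpyrifos", "malathion",
                                  "chlorothalonil", "lindane"))) {
            half <- nS %/% 2L
            opFam <- c(rep(1, half), rep(0.12, nS - half))
            ocFam <- c(rep(0.12, half), rep(1, nS - half))
            fam <- cbind(chlorpyrifos = opFam, malathion = opFam,
                         chlorothalonil = ocFam, lindane = ocFam)
            # the organochlorine fingerprints are strongly correlated:
            # closely related volatile profiles excite the family almost
            # alike, so telling them apart needs many training samples
            zLin <- 0.3 * z[, "chlorothalonil"] + 0.954 * z[, "lindane"]
            sens[, "lindane"] <- pmax(base * (1 + deviationScale * zLin),
                                      0.05)
            sens <- pmax(sens * fam, 0.02)
            ratio <- pmin(pmax(1 + 2 * deviationScale * stats::rnorm(nS),
                               0.5), 2)
            sens[, "malathion"] <- pmin(pmax(ratio * sens[, "chlorpyrifos"],
                                             0.02), 3)
        }
        tau <- stats::runif(nS, 2, 10)
        drift <- matrix(stats::rnorm(nS * 3L, 0, 1), nS, 3L)
        responseModel(sensitivity = sens, tauS = tau,
                      driftLoadings = drift, ...)
    })
}

#' Construct a between-domain shift of a given magnitude
#'
#' The shift direction (per-sensor relative gains, offsets and interference
#' amplitudes) is fixed once per instrument and scaled by `magnitude`, so a
#' bisection over `magnitude` moves along a fixed ray; `magnitude = 0` is
#' exactly the identity shift.
#'
#' When a [SensorResponseModel-class] is supplied, the gain component is
#' anchored to the instrument: the target domain's background modulates
#' per-sensor gains along the ratio between two pesticide classes'
#' sensitivity patterns, `gain = 1 + (magnitude/2) * (sens_B/sens_A - 1)`
#' (plus a small random per-sensor gain), so that with growing magnitude
#' one class's source-domain fingerprint progressively collides with
#' another class's target-domain fingerprint. This reproduces the
#' hallmark of real two-region e-nose data where cross-domain models
#' confuse unrelated classes rather than merely losing precision. Without
#' a model, a purely random frozen gain direction of comparable size is
#' used. Offsets are drawn from N(0, 0.08) V and interference amplitudes
#' from |N(0, 0.05)| V per unit magnitude, under a fixed internal seed.
#'
#' @param magnitude non-negative scalar; 0 means no shift.
#' @param nSensors number of sensors the shift applies to.
#' @param model optional [SensorResponseModel-class] anchoring the gain
#'   direction to the instrument's class fingerprints.
#' @param collidePair length-2 character, the (source, target) class pair
#'   whose fingerprints the gain morphs between (model-anchored form only).
#' @return A [DomainShiftParams-class].
#' @examples
#' identityShift <- domainShift(0)
#' all(identityShift@gain == 1)  # TRUE
#' @export
domainShift <- function(magnitude, nSensors = 26L, model = NULL,
                        collidePair = c("chlorpyrifos", "malathion")) {
    nSensors <- as.integer(nSensors)
    if (magnitude == 0) {
        return(new("DomainShiftParams", gain = rep(1, nSensors),
                   offsetV = rep(0, nSensors),
                   interferenceV = rep(0, nSensors), magnitude = 0))
    }
    .withSeed(224737 + nSensors, {
        gDir <- if (!is.null(model)) {
            sens <- model@sensitivity
            a <- sens[, collidePair[1L]]
            b <- sens[, collidePair[2L]]
            others <- sens[, setdiff(colnames(sens), collidePair),
                           drop = FALSE]
            # gains act where the colliding pair dominates the array's
            # response; the other classes' fingerprints are left intact
            mask <- as.numeric(a + b > rowSums(others))
            ratio <- pmin(pmax(b / a, 0.4), 2.5)
            (ratio - 1) / 2 * mask + stats::rnorm(nSensors, 0, 0.005)
        } else stats::rnorm(nSensors, 0, 0.12)
        o <- stats::rnorm(nSensors, 0, 0.005)
        # background volatiles in the shifted domain excite the same
        # sensors the colliding pair does, so unpolluted target samples
        # mimic weak pollution when judged by a source-trained model
        iDir <- if (!is.null(model)) {
            sens <- model@sensitivity
            a <- sens[, collidePair[1L]]
            b <- sens[, collidePair[2L]]
            others <- sens[, setdiff(colnames(sens), collidePair),
                           drop = FALSE]
            as.numeric(a + b > rowSums(others)) *
                abs(stats::rnorm(nSensors, 0, 0.11))
        } else abs(stats::rnorm(nSensors, 0, 0.015))
        i <- iDir
        new("DomainShiftParams",
            gain = pmax(1 + magnitude * gDir, 0.05),
            offsetV = magnitude * o,
            interferenceV = magnitude * i,
            magnitude = magnitude)
    })
}

#' Qualitative-task experiment design
#'
#' Grids and sizes of the qualitative (5-class pesticide type) study:
#' N in {0, 10, 20, 30, 40, 50}, Ts in {104, 208, 312, 416, 520}, Tt = 30,
#' FT features. For a reduced benchmark pass `TsGrid` scaled to the pool.
#'
#' @param NGrid boosting-iteration grid.
#' @param TsGrid source-training-size grid.
#' @param Tt target training size.
#' @param featureMethod feature extraction method.
#' @param seeds seeds for stochastic replication.
#' @return An [ExperimentDesign-class].
#' @export
qualitativeDesign <- function(NGrid = c(0L, 10L, 20L, 30L, 40L, 50L),
                              TsGrid = c(104L, 208L, 312L, 416L, 520L),
                              Tt = 30L, featureMethod = "FT",
                              nCoeffs = 8L, seeds = 1:20) {
    new("ExperimentDesign", task = "qualitative",
        NGrid = as.integer(NGrid), TsGrid = as.integer(TsGrid),
        Tt = as.integer(Tt), featureMethod = featureMethod,
        nCoeffs = as.integer(nCoeffs),
        labelColumn = "pesticide", seeds = as.integer(seeds))
}

#' Semi-quantitative-task experiment design
#'
#' Grids and sizes of the semi-quantitative (3-class concentration) study
#' for one pesticide: Ts in {24, 48, 72, 96, 120}, Tt = 30, Mean features.
#'
#' @inheritParams qualitativeDesign
#' @return An [ExperimentDesign-class].
#' @export
semiquantDesign <- function(NGrid = c(0L, 10L, 20L, 30L, 40L, 50L),
                            TsGrid = c(24L, 48L, 72L, 96L, 120L),
                            Tt = 30L, featureMethod = "Mean",
                            nCoeffs = 8L, seeds = 1:20) {
    new("ExperimentDesign", task = "semiquant",
        NGrid = as.integer(NGrid), TsGrid = as.integer(TsGrid),
        Tt = as.integer(Tt), featureMethod = featureMethod,
        nCoeffs = as.integer(nCoeffs),
        labelColumn = "concentration_ug_L", seeds = as.integer(seeds))
}
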