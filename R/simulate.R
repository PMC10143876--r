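#' @importFrom stats rnorm runif
NULL

# Saturating concentration response, normalised to 1 at concMax.
.concMultiplier <- function(model, conc) {
    if (conc == 0) return(0)
    log1p(conc / model@conc0) / log1p(model@concMax / model@conc0)
}

# First-order rise matrix (time x sensors), cached by the dataset generator.
.riseMatrix <- function(acq, model) {
    t <- (seq_len(nTimePoints(acq)) - 1) / acq@rateHz
    1 - exp(-outer(t, 1 / model@tauS))
}

#' Simulate one e-nose measurement
#'
#' Each sensor's trace rises first-order from baseline to a plateau,
#' `baseline + A_eff * (1 - exp(-t / tau))`, where the effective amplitude
#' couples the instrument sensitivity, the saturating concentration
#' response, sample-level jitter, and the domain shift:
#' `A_eff = gain * (sensitivity * concMult * jitter + interference)`.
#' Gaussian measurement noise is added per time point and the result is
#' clipped to `[0, vMax]`. Randomness is taken from the current RNG state;
#' seed upstream (e.g. via [generateDomainDataset()]) for reproducibility.
#'
#' @param model a [SensorResponseModel-class].
#' @param shift a [DomainShiftParams-class]; use `domainShift(0)` for an
#'   unshifted (source-domain) sample.
#' @param acq an [AcquisitionConfig-class].
#' @param pesticide class label; `"none"` for an unpolluted sample.
#' @param concentration spiked concentration in ug/L; must be 0 iff
#'   `pesticide == "none"`.
#' @param sampleId identifier stored with the sample.
#' @return A one-sample [ENoseSampleSet-class].
#' @examples
#' acq <- acquisitionConfig(durationS = 2, rateHz = 10, nSensors = 3)
#' m <- defaultResponseModel(acq)
#' set.seed(1)
#' s <- simulateSample(m, domainShift(0, 3), acq, "chlorpyrifos", 500)
#' dim(sampleTrace(s, 1))  # 20 x 3
#' @export
simulateSample <- function(model, shift, acq, pesticide, concentration,
                           sampleId = "sample_1") {
    validObject(acq)
    polluted <- colnames(model@sensitivity)
    if (!pesticide %in% c("none", polluted))
        stop("unknown pesticide class: '", pesticide, "'")
    if ((pesticide == "none") != (concentration == 0))
        stop("concentration must be 0 if and only if pesticide is 'none'")
    if (length(shift@gain) != acq@nSensors)
        stop("shift parameters do not match the sensor count")
    mat <- .simulateTrace(model, shift, acq, pesticide, concentration,
                          .riseMatrix(acq, model))
    md <- S4Vectors::DataFrame(
        sample_id = sampleId,
        domain = if (shift@magnitude == 0) "source" else "target",
        pesticide = pesticide,
        concentration_ug_L = concentration)
    new("ENoseSampleSet", traces = list(mat), sampleData = md, acq = acq)
}

# Core trace synthesis; riseMat passed in so batch generation computes the
# kinetics once per configuration.
.simulateTrace <- function(model, shift, acq, pesticide, concentration,
                           riseMat) {
    nS <- acq@nSensors
    amp <- if (pesticide == "none") rep(0, nS)
           else model@sensitivity[, pesticide] * .concMultiplier(model, concentration)
    gScale <- if (model@scaleJitterSd > 0) exp(rnorm(1, 0, model@scaleJitterSd)) else 1
    jitSd <- if (model@outlierProb > 0 && runif(1) < model@outlierProb)
        model@outlierJitterSd else model@ampJitterSd
    jit <- if (jitSd > 0) exp(rnorm(nS, 0, jitSd)) else rep(1, nS)
    bDrift <- if (model@baselineJitterSd > 0) rnorm(nS, 0, model@baselineJitterSd) else rep(0, nS)
    ampDrift <- if (ncol(model@driftLoadings) > 0L && model@driftSd > 0)
        drop(model@driftLoadings %*% rnorm(ncol(model@driftLoadings), 0, model@driftSd))
    else rep(0, nS)
    effAmp <- shift@gain * (amp * gScale * jit + ampDrift + shift@interferenceV)
    m <- sweep(riseMat, 2, effAmp, "*")
    m <- sweep(m, 2, acq@baselineV + bDrift + shift@offsetV, "+")
    if (model@noiseSd > 0)
        m <- m + rnorm(length(m), 0, model@noiseSd)
    m[m < 0] <- 0
    m[m > acq@vMax] <- acq@vMax
    m
}

#' Generate all samples of one domain
#'
#' Realises a [DatasetDesign-class] for one domain: `nUnpolluted` samples of
#' class `"none"` plus `nPerConcentration` samples for every (pesticide,
#' concentration) cell. By fixed convention the source domain is the
#' unshifted one: when `domain == "source"` the identity shift is used
#' regardless of `shift`; the target domain uses the supplied shift.
#'
#' @param design a [DatasetDesign-class].
#' @param domain `"source"` or `"target"`.
#' @param model a [SensorResponseModel-class].
#' @param shift a [DomainShiftParams-class] applied to the target domain.
#' @param acq an [AcquisitionConfig-class].
#' @param seed optional integer; when given, generation is reproducible and
#'   the caller's RNG state is untouched.
#' @return An [ENoseSampleSet-class] with `samplesPerDomain(design)` samples.
#' @examples
#' acq <- acquisitionConfig(durationS = 1, rateHz = 20, nSensors = 5)
#' ds <- generateDomainDataset(reducedDesign(), "source",
#'                             defaultResponseModel(acq), domainShift(0, 5),
#'                             acq, seed = 1)
#' length(ds)  # 130
#' @export
generateDomainDataset <- function(design, domain = c("source", "target"),
                                  model, shift = domainShift(0),
                                  acq = acquisitionConfig(), seed = NULL) {
    domain <- match.arg(domain)
    validObject(design)
    if (domain == "source") shift <- domainShift(0, acq@nSensors)
    .withSeed(seed, {
        riseMat <- .riseMatrix(acq, model)
        cells <- data.frame(pesticide = "none", concentration = 0,
                            n = design@nUnpolluted)
        for (cl in setdiff(design@pesticideClasses, "none"))
            cells <- rbind(cells, data.frame(
                pesticide = cl, concentration = design@concentrations,
                n = design@nPerConcentration))
        total <- sum(cells$n)
        traces <- vector("list", total)
        ids <- character(total); pest <- character(total); conc <- numeric(total)
        k <- 0L
        for (r in seq_len(nrow(cells))) {
            for (i in seq_len(cells$n[r])) {
                k <- k + 1L
                traces[[k]] <- .simulateTrace(model, shift, acq,
                                              cells$pesticide[r],
                                              cells$concentration[r], riseMat)
                ids[k] <- sprintf("%s_%s_%04d_%03d", domain, cells$pesticide[r],
                                  cells$concentration[r], i)
                pest[k] <- cells$pesticide[r]
                conc[k] <- cells$concentration[r]
            }
        }
        new("ENoseSampleSet", traces = traces,
            sampleData = S4Vectors::DataFrame(
                sample_id = ids, domain = rep(domain, total),
                pesticide = pest, concentration_ug_L = conc),
            acq = acq)
    })
}
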