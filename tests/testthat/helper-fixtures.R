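suppressPackageStartupMessages(library(SummarizedExperiment))

# Shared fixtures, computed lazily and cached for the whole test run.
# Fast tests use a short acquisition window; acceptance tests use the full
# 60 s x 100 Hz protocol.

.fixtures <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
    if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
    get(key, envir = .fixtures)
}

# 160-point records (8 s x 20 Hz): fast, and divisible by 2^3 for the
# level-3 wavelet decomposition.
smallAcq <- function() acquisitionConfig(durationS = 8, rateHz = 20)

smallModel <- function() defaultResponseModel(smallAcq())

# a deterministic model: every stochastic term switched off
noiselessModel <- function(acq = smallAcq()) {
    m <- defaultResponseModel(acq)
    responseModel(m@sensitivity, m@tauS, conc0 = m@conc0, concMax = m@concMax,
                  noiseSd = 0, ampJitterSd = 0, scaleJitterSd = 0,
                  baselineJitterSd = 0, outlierProb = 0,
                  driftLoadings = matrix(numeric(0), 0L, 0L), driftSd = 0)
}

smallSource <- function() .cached("smallSource",
    generateDomainDataset(reducedDesign(), "source", smallModel(),
                          acq = smallAcq(), seed = 401))

# full default design at the small acquisition scale (520 samples/domain)
smallFullSource <- function() .cached("smallFullSource",
    generateDomainDataset(datasetDesign(), "source", smallModel(),
                          acq = smallAcq(), seed = 402))

# --- full-protocol fixtures shared by the acceptance tests ---

fullAcq <- function() acquisitionConfig()

fullModel <- function() .cached("fullModel", defaultResponseModel(fullAcq()))

calibratedShift <- function() .cached("calibratedShift",
    calibrateShift(fullModel(), fullAcq(), seed = 11L))

benchSource <- function() .cached("benchSource",
    generateDomainDataset(reducedDesign(), "source", fullModel(),
                          acq = fullAcq(), seed = 2101))

benchTarget <- function() .cached("benchTarget",
    generateDomainDataset(reducedDesign(), "target", fullModel(),
                          calibratedShift(), acq = fullAcq(), seed = 2102))

# Overlapping 3-class data in the plane, used by the boosting tests.
boostingData <- function(seed = 1, nPerClass = 15, spread = 1.2) {
    set.seed(seed)
    centers <- rbind(c(0, 0), c(3, 0), c(1.5, 2.5))
    X <- do.call(rbind, lapply(1:3, function(k)
        sweep(matrix(rnorm(nPerClass * 2, sd = spread), nPerClass),
              2, centers[k, ], "+")))
    list(X = X, y = rep(c("a", "b", "c"), each = nPerClass))
}

# Two gaussian clusters with controllable separation.
toyClusters <- function(n = 20, d = 2, gap = 5, seed = 1) {
    set.seed(seed)
    X <- rbind(matrix(rnorm(n * d), n), matrix(rnorm(n * d, gap), n))
    list(X = X, y = rep(c("a", "b"), each = n))
}

# Reference AdaBoost (Freund & Schapire beta-update with the same weighted
# base learner and last-half log(1/beta) vote) used as the empty-source
# oracle for TrAdaBoost.
referenceAdaBoost <- function(X, y, N, C, epsMin) {
    y <- as.character(y)
    w <- rep(1 / nrow(X), nrow(X))
    hyps <- vector("list", N)
    betas <- numeric(N)
    for (t in seq_len(N)) {
        w <- w / sum(w)
        h <- fitWeightedSVM(X, y, weights = w, C = C)
        miss <- predict(h, X) != y
        eps <- min(max(sum(w[miss]), epsMin), 0.499)
        b <- eps / (1 - eps)
        # FS-style: correctly classified weights shrink by beta
        w[!miss] <- w[!miss] * b
        hyps[[t]] <- h
        betas[t] <- b
    }
    list(hypotheses = hyps, betaT = betas)
}

adaVote <- function(ref, X, N) {
    classes <- sort(unique(unlist(lapply(ref$hypotheses, function(h) h@classes))))
    votes <- matrix(0, nrow(X), length(classes), dimnames = list(NULL, classes))
    for (t in ceiling(N / 2):N) {
        p <- predict(ref$hypotheses[[t]], X)
        idx <- cbind(seq_len(nrow(X)), match(p, classes))
        votes[idx] <- votes[idx] + log(1 / ref$betaT[t])
    }
    classes[max.col(votes, ties.method = "first")]
}
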