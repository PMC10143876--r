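test_that("the source discount matches its closed form", {
    expect_lt(abs(sourceDiscount(520, 50) -
                  1 / (1 + sqrt(2 * log(520) / 50))), 1e-12)
    expect_equal(sourceDiscount(520, 50), 0.6666, tolerance = 1e-4)
    expect_identical(sourceDiscount(0, 10), 1)
})

test_that("stored beta_t equal eps_t/(1 - eps_t) recomputed from the fits", {
    src <- boostingData(1); tgt <- boostingData(2)
    fit <- tradaBoost(src$X, src$y, tgt$X, tgt$y, N = 4L, C = 0.2,
                      epsMin = 0.05, recordWeights = TRUE)
    hist <- attr(fit, "weightHistory")
    for (t in seq_len(fit@nTrained)) {
        h <- hist[[t]]
        w <- h$pre
        # pre-update weights are the normalised weights the round was fit on
        miss <- predict(fit@hypotheses[[t]],
                        rbind(src$X, tgt$X)) != c(src$y, tgt$y)
        eps <- sum(w[h$isTarget & miss]) / sum(w[h$isTarget])
        eps <- min(max(eps, 0.05), 0.499)
        expect_equal(fit@betaT[t], eps / (1 - eps), tolerance = 1e-12)
    }
})

test_that("with no source and one round the model is a single weighted SVM", {
    tgt <- boostingData(3)
    fit <- tradaBoost(NULL, NULL, tgt$X, tgt$y, N = 1L, C = 0.5)
    single <- fitWeightedSVM(tgt$X, tgt$y, C = 0.5)
    grid <- boostingData(4)$X
    expect_identical(tradaboostPredict(fit, grid), predict(single, grid))
    expect_identical(fit@betaSource, 1)
})

test_that("the binary vote equals the classical product-form final hypothesis", {
    set.seed(99)
    for (rep in 1:50) {
        K <- sample(3:7, 1)
        hyps <- lapply(seq_len(K), function(i) {
            d <- toyClusters(n = 8, gap = runif(1, 1, 4), seed = 1000 * rep + i)
            fitWeightedSVM(d$X, d$y)
        })
        betaT <- runif(K, 0.05, 0.95)
        model <- new("TrAdaBoostModel", hypotheses = hyps, betaT = betaT,
                     betaSource = 0.7, N = K, nTrained = K,
                     classes = c("a", "b"))
        Xnew <- matrix(rnorm(20, 2), 10, 2)
        got <- tradaboostPredict(model, Xnew)
        # independent oracle: h_f(x) = 1 iff prod beta_t^{-h_t} >= prod beta_t^{-1/2}
        rng <- ceiling(K / 2):K
        H <- sapply(rng, function(t) as.numeric(predict(hyps[[t]], Xnew) == "b"))
        lhs <- exp(H %*% (-log(betaT[rng])))
        rhs <- prod(betaT[rng]^(-0.5))
        oracle <- ifelse(lhs >= rhs, "b", "a")
        expect_identical(got, as.vector(oracle))
    }
})

test_that("equal beta_t reduce the vote to an unweighted majority", {
    hyps <- lapply(1:5, function(i) {
        d <- toyClusters(n = 10, gap = 2, seed = 50 + i)
        fitWeightedSVM(d$X, d$y)
    })
    model <- new("TrAdaBoostModel", hypotheses = hyps,
                 betaT = rep(0.3, 5), betaSource = 0.7, N = 5L,
                 nTrained = 5L, classes = c("a", "b"))
    Xnew <- matrix(rnorm(30, 1), 15, 2)
    preds <- sapply(3:5, function(t) predict(hyps[[t]], Xnew))
    majority <- apply(preds, 1, function(p) {
        tab <- table(factor(p, levels = c("a", "b")))
        names(tab)[which.max(tab)]  # ties go to "a", the lowest label
    })
    expect_identical(tradaboostPredict(model, Xnew), unname(majority))
})

test_that("empty-source TrAdaBoost matches a reference AdaBoost vote", {
    tgt <- boostingData(7, nPerClass = 14, spread = 1.0)
    N <- 8L; C <- 1; epsMin <- 0.05
    fit <- tradaBoost(NULL, NULL, tgt$X, tgt$y, N = N, C = C, epsMin = epsMin)
    ref <- referenceAdaBoost(tgt$X, tgt$y, N, C, epsMin)
    grid <- boostingData(8, nPerClass = 20)$X
    expect_equal(fit@betaT, ref$betaT, tolerance = 1e-10)
    expect_identical(tradaboostPredict(fit, grid), adaVote(ref, grid, N))
})

test_that("weight updates move in the documented directions every iteration", {
    src <- boostingData(10, nPerClass = 25, spread = 1.8)
    tgt <- boostingData(11, nPerClass = 8, spread = 1.8)
    fit <- tradaBoost(src$X, src$y, tgt$X, tgt$y, N = 10L, C = 0.2,
                      recordWeights = TRUE)
    hist <- attr(fit, "weightHistory")
    expect_gt(length(hist), 0L)
    for (h in hist) {
        expect_equal(sum(h$pre), 1, tolerance = 1e-12)
        expect_true(all(h$pre > 0))
        srcMiss <- !h$isTarget & h$miss
        tgtMiss <- h$isTarget & h$miss
        expect_true(all(h$post[srcMiss] <= h$pre[srcMiss]))
        expect_true(all(h$post[tgtMiss] >= h$pre[tgtMiss]))
        expect_identical(h$post[!h$miss], h$pre[!h$miss])
    }
})

test_that("persistently bad target error triggers early stopping", {
    src <- boostingData(20, nPerClass = 60, spread = 0.4)
    tgt <- boostingData(21, nPerClass = 6, spread = 0.4)
    # invert the target labels so the dominant source concept is always wrong
    flip <- c(a = "b", b = "c", c = "a")
    fit <- tradaBoost(src$X, src$y, tgt$X, unname(flip[tgt$y]), N = 30L,
                      C = 0.05)
    expect_lt(fit@nTrained, 30L)
})

test_that("fits and predictions are deterministic", {
    src <- boostingData(30); tgt <- boostingData(31)
    f1 <- tradaBoost(src$X, src$y, tgt$X, tgt$y, N = 6L, C = 0.2)
    f2 <- tradaBoost(src$X, src$y, tgt$X, tgt$y, N = 6L, C = 0.2)
    expect_identical(f1@betaT, f2@betaT)
    grid <- boostingData(32)$X
    expect_identical(tradaboostPredict(f1, grid), tradaboostPredict(f2, grid))
})

test_that("transfer from an identically distributed source never hurts on average", {
    acq <- smallAcq()
    m <- smallModel()
    src <- smallSource()
    tgt <- generateDomainDataset(reducedDesign(), "source", m, acq = acq,
                                 seed = 403)
    fs <- featureMatrix(extractFeatures(src, "Mean"))
    ft <- featureMatrix(extractFeatures(tgt, "Mean"))
    ys <- sampleData(src)$pesticide
    yt <- sampleData(tgt)$pesticide
    gains <- sapply(1:20, function(s) {
        sp <- splitTarget(tgt, 30L, seed = s)
        Xt <- ft[sp$train, ]; yTr <- yt[sp$train]
        Xte <- ft[sp$test, ]; yTe <- yt[sp$test]
        tl <- tradaBoost(fs, ys, Xt, yTr, N = 10L, C = 0.1)
        evaluateAccuracy(tradaboostPredict(tl, Xte), yTe) -
            evaluateAccuracy(predict(fitWeightedSVM(Xt, yTr, C = 0.1), Xte), yTe)
    })
    expect_gte(mean(gains), 0)
})

test_that("malformed boosting inputs are rejected", {
    src <- boostingData(1)
    expect_error(tradaBoost(src$X, src$y, src$X[0, ], character(0), N = 3L),
                 "non-empty")
    expect_error(tradaBoost(src$X, src$y, src$X[1:5, ], rep("a", 5), N = 3L),
                 "2 classes")
    fit <- tradaBoost(NULL, NULL, src$X, src$y, N = 2L)
    expect_error(tradaboostPredict(fit, matrix(0, 2, 9)), "dimension")
})
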