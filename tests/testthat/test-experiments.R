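test_that("target splits have the study sizes and respect stratification", {
    full <- smallFullSource()            # 520 samples, full class structure
    sp <- splitTarget(full, 30L, seed = 1)
    expect_length(sp$train, 30L)
    expect_length(sp$test, 490L)
    expect_length(intersect(sp$train, sp$test), 0L)
    # class proportions approximately preserved in the training split
    md <- sampleData(full)
    trainTab <- table(md$pesticide[sp$train])
    expect_true(all(trainTab[c("chlorpyrifos", "malathion",
                               "chlorothalonil", "lindane")] == 7L))
    expect_equal(unname(trainTab[["none"]]), 2L)
    # per-pesticide semiquant pool: 120 samples, test size 90
    sub <- full[md$pesticide == "malathion"]
    sps <- splitTarget(sub, 30L, labelColumn = "concentration_ug_L", seed = 2)
    expect_length(sps$test, 90L)
    expect_error(splitTarget(sub, 120L, labelColumn = "concentration_ug_L"),
                 "smaller")
    one <- full[c(which(md$pesticide == "none")[1],
                  which(md$pesticide == "malathion")[1:5])]
    expect_error(splitTarget(one, 2L), "fewer than 2")
})

test_that("saturation can blind MAX while Mean stays informative", {
    # two classes with equal clipped plateaus but different rise amplitudes:
    # the maximum saturates at the supply rail, the mean keeps the ordering
    acq <- acquisitionConfig(durationS = 8, rateHz = 20, nSensors = 1,
                             baselineV = 1, vMax = 4)
    sens <- matrix(c(3.0, 4.5), 1, 2, dimnames = list(NULL, c("a", "b")))
    m <- responseModel(sens, tauS = 2, noiseSd = 0.01, ampJitterSd = 0.02,
                       scaleJitterSd = 0, baselineJitterSd = 0,
                       outlierProb = 0, driftSd = 0)
    design <- datasetDesign(pesticideClasses = c("none", "a", "b"),
                            concentrations = 1000,
                            nUnpolluted = 0L, nPerConcentration = 25L)
    ds <- generateDomainDataset(design, "source", m, acq = acq, seed = 5)
    screen <- screenFeatures(ds, ds, methods = c("MAX", "Mean"))
    accMax <- screen$test_accuracy[screen$method == "MAX"]
    accMean <- screen$test_accuracy[screen$method == "Mean"]
    expect_gt(accMean, accMax)
})

test_that("the sweep emits one row per grid point and skips oversized Ts", {
    src <- smallSource()
    tgt <- generateDomainDataset(reducedDesign(), "target", smallModel(),
                                 domainShift(1, 26, smallModel()),
                                 acq = smallAcq(), seed = 404)
    des <- qualitativeDesign(NGrid = c(0L, 1L, 2L), TsGrid = c(20L, 40L),
                             Tt = 20L, featureMethod = "Mean", seeds = 1L)
    res <- sweepParameters(src, tgt, des)
    expect_equal(nrow(res), 6L)
    expect_setequal(unique(res$method[res$N == 0]), "Tc-SVM")
    expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
    desBad <- qualitativeDesign(NGrid = 1L, TsGrid = c(20L, 999L),
                                Tt = 20L, featureMethod = "Mean", seeds = 1L)
    expect_warning(resBad <- sweepParameters(src, tgt, desBad), "skipping")
    expect_equal(nrow(resBad), 1L)
})

test_that("a source-free sweep row at N = 1 equals the target-only baseline", {
    src <- smallSource()
    tgt <- generateDomainDataset(reducedDesign(), "target", smallModel(),
                                 domainShift(1, 26, smallModel()),
                                 acq = smallAcq(), seed = 405)
    des <- qualitativeDesign(NGrid = 1L, TsGrid = 0L, Tt = 25L,
                             featureMethod = "Mean", seeds = 3L)
    res <- sweepParameters(src, tgt, des)
    sp <- enoseTransfer:::.withSeed(enoseTransfer:::.childSeed(3L, "split"),
        enoseTransfer:::.stratifiedSplit(sampleData(tgt)$pesticide, 25L))
    ft <- featureMatrix(extractFeatures(tgt, "Mean"))
    yt <- sampleData(tgt)$pesticide
    base <- evaluateAccuracy(
        predict(fitWeightedSVM(ft[sp$train, ], yt[sp$train], C = 0.1),
                ft[sp$test, ]), yt[sp$test])
    expect_equal(res$accuracy, base, tolerance = 1e-12)
})

test_that("without domain shift all four methods perform alike", {
    # an easy instrument whose learning curve saturates well below Tt = 30,
    # so sample-size effects cannot masquerade as a transfer problem
    acq <- smallAcq()
    m <- defaultResponseModel(acq, deviationScale = 0.4, ampJitterSd = 0.02,
                              scaleJitterSd = 0.02, driftSd = 0)
    src <- generateDomainDataset(reducedDesign(), "source", m, acq = acq,
                                 seed = 410)
    tgt <- generateDomainDataset(reducedDesign(), "source", m, acq = acq,
                                 seed = 406)
    des <- qualitativeDesign(TsGrid = 130L, Tt = 30L, featureMethod = "Mean",
                             seeds = 1:20)
    res <- compareMethods(src, tgt, des, Ts = 130L, N = 5L)
    means <- tapply(res$accuracy, res$method, mean)
    expect_lt(max(means) - min(means), 0.05)
    # aggregation sanity: the mean lies inside the per-seed range
    for (meth in names(means)) {
        accs <- res$accuracy[res$method == meth]
        expect_true(means[[meth]] >= min(accs) && means[[meth]] <= max(accs))
    }
})

test_that("experiment tables are reproducible for a fixed design", {
    src <- smallSource()
    tgt <- generateDomainDataset(reducedDesign(), "target", smallModel(),
                                 domainShift(1, 26, smallModel()),
                                 acq = smallAcq(), seed = 407)
    des <- qualitativeDesign(NGrid = c(0L, 2L), TsGrid = 60L, Tt = 20L,
                             featureMethod = "Mean", seeds = 1:2)
    expect_identical(sweepParameters(src, tgt, des),
                     sweepParameters(src, tgt, des))
})

test_that("semi-quantitative runs restrict to one pesticide's three levels", {
    full <- smallFullSource()
    tgtFull <- generateDomainDataset(datasetDesign(), "target", smallModel(),
                                     domainShift(1, 26, smallModel()),
                                     acq = smallAcq(), seed = 408)
    des <- semiquantDesign(NGrid = 2L, TsGrid = 120L, Tt = 30L, seeds = 1L)
    res <- runSemiquant("chlorothalonil", full, tgtFull, des,
                        what = "compare", Ts = 120L, N = 2L)
    expect_setequal(res$method, c("Ts-SVM", "Tt-SVM", "Tc-SVM", "TL"))
    expect_true(all(res$pesticide == "chlorothalonil"))
    sub <- sampleData(full[sampleData(full)$pesticide == "chlorothalonil"])
    expect_equal(nrow(sub), 120L)
    expect_setequal(unique(sub$concentration_ug_L), c(100, 500, 1000))
    expect_false("none" %in% sub$pesticide)
    expect_error(runSemiquant("atrazine", full, tgtFull, des), "unknown")
})

test_that("PCA scores separate strongly shifted domains and behave sanely", {
    acq <- smallAcq()
    m <- smallModel()
    src <- smallSource()
    bigShift <- new("DomainShiftParams", gain = rep(1.3, 26),
                    offsetV = rep(0.8, 26), interferenceV = rep(0.4, 26),
                    magnitude = 3)
    tgt <- generateDomainDataset(reducedDesign(), "target", m, bigShift,
                                 acq = acq, seed = 409)
    fe <- extractFeatures(c(src, tgt), "Mean")
    p <- pcaDiagnostic(fe)
    expect_true(p$explainedVariance[1] >= p$explainedVariance[2])
    expect_lte(sum(p$explainedVariance), 1)
    sil <- cluster::silhouette(as.integer(factor(p$domains)), dist(p$scores))
    expect_gt(mean(sil[, 3]), 0.5)
    # duplicated samples land on identical scores
    dup <- pcaDiagnostic(rbind(p$scores, p$scores))
    n <- nrow(p$scores)
    expect_equal(dup$scores[seq_len(n), ], dup$scores[n + seq_len(n), ])
    expect_error(pcaDiagnostic(matrix(1, 10, 4)), "degenerate")
})
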