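#' @importFrom data.table fwrite fread
#' @importFrom utils write.csv read.csv
NULL

#' Write a sample set to disk as CSV files plus a manifest
#'
#' Each sample becomes one header-less numeric CSV (time points x sensors,
#' volts) under `dir/samples/`; the manifest CSV lists `sample_id`,
#' `domain`, `pesticide`, `concentration_ug_L` and the relative `path` of
#' every sample file.
#'
#' @param x an [ENoseSampleSet-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @seealso [readManifest()]
#' @export
writeManifest <- function(x, dir) {
    sdir <- file.path(dir, "samples")
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    md <- as.data.frame(sampleData(x))
    md$path <- file.path("samples", paste0(md$sample_id, ".csv"))
    for (i in seq_len(length(x)))
        fwrite(as.data.frame(x@traces[[i]]), file.path(dir, md$path[i]),
               col.names = FALSE)
    manifest <- file.path(dir, "manifest.csv")
    write.csv(md, manifest, row.names = FALSE)
    invisible(manifest)
}

#' Read a sample set from a manifest
#'
#' Validates that the manifest has the required columns, that every
#' referenced sample file exists, and that every matrix parses to the shape
#' declared by `acq`; errors name the offending `sample_id`.
#'
#' @param path manifest CSV path.
#' @param acq the expected [AcquisitionConfig-class].
#' @return An [ENoseSampleSet-class] (empty manifest gives an empty set).
#' @export
readManifest <- function(path, acq = acquisitionConfig()) {
    md <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "domain", "pesticide", "concentration_ug_L", "path")
    miss <- setdiff(need, colnames(md))
    if (length(miss))
        stop("manifest is missing columns: ", paste(miss, collapse = ", "))
    base <- dirname(path)
    nr <- nTimePoints(acq); nc <- acq@nSensors
    traces <- vector("list", nrow(md))
    for (i in seq_len(nrow(md))) {
        f <- file.path(base, md$path[i])
        if (!file.exists(f))
            stop("sample '", md$sample_id[i], "': file not found: ", f)
        m <- as.matrix(fread(f, header = FALSE))
        dimnames(m) <- NULL
        if (nrow(m) != nr || ncol(m) != nc)
            stop("sample '", md$sample_id[i], "': expected a ", nr, " x ",
                 nc, " matrix, got ", nrow(m), " x ", ncol(m))
        traces[[i]] <- m
    }
    new("ENoseSampleSet", traces = traces,
        sampleData = S4Vectors::DataFrame(
            sample_id = as.character(md$sample_id),
            domain = as.character(md$domain),
            pesticide = as.character(md$pesticide),
            concentration_ug_L = as.numeric(md$concentration_ug_L)),
        acq = acq)
}

#' Build a pipeline run configuration
#'
#' A validated list of every knob of the end-to-end pipeline; serialisable
#' to YAML losslessly with [writeRunConfig()] / [readRunConfig()].
#'
#' @param seed root seed; every stage derives its own named child stream.
#' @param nUnpolluted,nPerConcentration dataset design cell counts.
#' @param durationS,rateHz,nSensors acquisition settings.
#' @param featureQualitative,featureSemiquant feature methods per task.
#' @param nCoeffs transform coefficients per sensor for FT/WT features.
#' @param N boosting iterations; `Tt` target training size.
#' @param C SVM cost.
#' @param seeds experiment replication seeds.
#' @param withinFloor,crossCeiling calibration constraints.
#' @return A named list of class `enose_run_config`.
#' @export
runConfig <- function(seed = 1L, nUnpolluted = 10L, nPerConcentration = 10L,
                      durationS = 60, rateHz = 100, nSensors = 26L,
                      featureQualitative = "FT", featureSemiquant = "Mean",
                      nCoeffs = 1L, N = 20L, Tt = 30L, C = 0.1, seeds = 1:5,
                      withinFloor = 0.933, crossCeiling = 0.667) {
    cfg <- list(seed = as.integer(seed),
                nUnpolluted = as.integer(nUnpolluted),
                nPerConcentration = as.integer(nPerConcentration),
                durationS = durationS, rateHz = rateHz,
                nSensors = as.integer(nSensors),
                featureQualitative = featureQualitative,
                featureSemiquant = featureSemiquant,
                nCoeffs = as.integer(nCoeffs),
                N = as.integer(N), Tt = as.integer(Tt), C = C,
                seeds = as.integer(seeds),
                withinFloor = withinFloor, crossCeiling = crossCeiling)
    .validateRunConfig(cfg)
    class(cfg) <- "enose_run_config"
    cfg
}

.validateRunConfig <- function(cfg) {
    if (!cfg$featureQualitative %in% .featureMethods)
        stop("unknown feature method: '", cfg$featureQualitative, "'")
    if (!cfg$featureSemiquant %in% .featureMethods)
        stop("unknown feature method: '", cfg$featureSemiquant, "'")
    if (cfg$durationS <= 0 || cfg$rateHz <= 0)
        stop("durationS and rateHz must be positive")
    if (cfg$N < 0L) stop("N must be >= 0")
    if (!(cfg$crossCeiling > 0 && cfg$crossCeiling < cfg$withinFloor))
        stop("need 0 < crossCeiling < withinFloor")
    invisible(cfg)
}

#' @rdname runConfig
#' @param path YAML file path.
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    do.call(runConfig, cfg)
}

#' @rdname runConfig
#' @param cfg a configuration from [runConfig()].
#' @export
writeRunConfig <- function(cfg, path) {
    yaml::write_yaml(unclass(cfg), path)
    invisible(path)
}

#' Run the full two-step recognition pipeline
#'
#' Executes the end-to-end workflow on synthetic data: generate the source
#' domain, calibrate the between-domain shift, generate the target domain,
#' screen the five feature methods, run the qualitative (pesticide type)
#' sweep and method comparison, then the per-pesticide semi-quantitative
#' (concentration) comparisons — qualitative before semi-quantitative, as
#' in the two-step methodology. All result tables are written as CSV under
#' `outDir` together with a `summary.yaml` recording the configuration,
#' calibrated magnitude, per-stage wall times and headline accuracies. Any
#' stage failure halts with the stage name; artifacts already written are
#' preserved.
#'
#' @param cfg a configuration from [runConfig()].
#' @param outDir output directory.
#' @param writeData also write the generated datasets via [writeManifest()].
#' @return Invisibly, a list with the result tables and the summary.
#' @export
runPipeline <- function(cfg, outDir, writeData = FALSE) {
    .validateRunConfig(cfg)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    timings <- c()
    stage <- function(name, expr) {
        t0 <- Sys.time()
        message("[", name, "] started")
        out <- tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
        dt <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2)
        timings[[name]] <<- dt
        message("[", name, "] done in ", dt, " s")
        out
    }
    acq <- acquisitionConfig(cfg$durationS, cfg$rateHz, cfg$nSensors)
    design <- datasetDesign(nUnpolluted = cfg$nUnpolluted,
                            nPerConcentration = cfg$nPerConcentration)
    model <- defaultResponseModel(acq)

    shift <- stage("calibrate", calibrateShift(
        model, acq, withinFloor = cfg$withinFloor,
        crossCeiling = cfg$crossCeiling, design = design,
        seed = .childSeed(cfg$seed, "calibration"), C = cfg$C))
    src <- stage("generate_source", generateDomainDataset(
        design, "source", model, acq = acq,
        seed = .childSeed(cfg$seed, "source")))
    tgt <- stage("generate_target", generateDomainDataset(
        design, "target", model, shift, acq = acq,
        seed = .childSeed(cfg$seed, "target")))
    if (writeData) {
        stage("write_data", {
            writeManifest(src, file.path(outDir, "data", "source"))
            writeManifest(tgt, file.path(outDir, "data", "target"))
        })
    }
    screen <- stage("screen_features",
                    screenFeatures(src, tgt, C = cfg$C))
    write.csv(screen, file.path(outDir, "screen.csv"), row.names = FALSE)

    qdes <- qualitativeDesign(
        NGrid = c(0L, cfg$N), TsGrid = length(src),
        Tt = cfg$Tt, featureMethod = cfg$featureQualitative,
        nCoeffs = cfg$nCoeffs, seeds = cfg$seeds)
    qsweep <- stage("qualitative_sweep", sweepParameters(src, tgt, qdes, C = cfg$C))
    write.csv(qsweep, file.path(outDir, "qualitative_sweep.csv"), row.names = FALSE)
    qcomp <- stage("qualitative_compare",
                   compareMethods(src, tgt, qdes, Ts = length(src),
                                  N = cfg$N, C = cfg$C))
    write.csv(qcomp, file.path(outDir, "qualitative_compare.csv"), row.names = FALSE)

    semiPool <- length(design@concentrations) * design@nPerConcentration
    sdes <- semiquantDesign(
        NGrid = c(0L, cfg$N), TsGrid = semiPool,
        Tt = min(cfg$Tt, semiPool %/% 2L),
        featureMethod = cfg$featureSemiquant,
        nCoeffs = cfg$nCoeffs, seeds = cfg$seeds)
    semis <- list()
    for (p in setdiff(design@pesticideClasses, "none")) {
        semis[[p]] <- stage(paste0("semiquant_", p),
                            runSemiquant(p, src, tgt, sdes, what = "compare",
                                         Ts = max(sdes@TsGrid), N = cfg$N,
                                         C = cfg$C))
    }
    semi <- do.call(rbind, semis)
    write.csv(semi, file.path(outDir, "semiquant_compare.csv"), row.names = FALSE)

    aggAcc <- function(tab) {
        means <- tapply(tab$accuracy, tab$method, mean)
        as.list(round(means, 4))
    }
    summary <- list(
        config = unclass(cfg),
        shift_magnitude = shift@magnitude,
        calibration = list(within = attr(shift, "within"),
                           cross = attr(shift, "cross")),
        qualitative_mean_accuracy = aggAcc(qcomp),
        semiquant_mean_accuracy = lapply(semis, aggAcc),
        stage_seconds = as.list(timings))
    yaml::write_yaml(summary, file.path(outDir, "summary.yaml"))
    invisible(list(screen = screen, qualitative_sweep = qsweep,
                   qualitative_compare = qcomp, semiquant_compare = semi,
                   shift = shift, summary = summary))
}
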