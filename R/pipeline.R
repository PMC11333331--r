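#' Default pipeline configuration
#'
#' Modelling defaults mirror the standard software settings: 100 bootstrap
#' replicates, 75% training fraction, 500 iterations, 1e-5 convergence
#' tolerance, 10,000 background points, logistic output, fixed class edges
#' 0.2/0.4/0.6, total-suitable threshold 0.04. Synthetic-scene sizes are
#' deliberately modest so a demo run completes quickly on one CPU.
#'
#' @return named list of settings, overridable via \code{\link{runPipeline}}.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    # maxent settings
    reps = 100L, trainFraction = 0.75, maxIter = 500L, tol = 1e-5,
    nBackground = 10000L, nKnots = 50L,
    # zoning
    classBreaks = c(0.2, 0.4, 0.6), useJenks = FALSE,
    # centroid
    centroidThreshold = 0.04,
    # fingerprint
    rtTolerance = 0.2, minHeight = 1, minProminence = 0.5,
    # quality zoning
    maskThreshold = 0.2, kGrades = 4L,
    # synthetic scene sizes (demo mode)
    gridRows = 80L, gridCols = 80L, nOccurrences = 298L, nSamples = 11L,
    nPeaks = 21L
  )
}

.validateConfig <- function(cfg) {
  stopifnot(
    cfg$reps >= 1L, cfg$trainFraction > 0, cfg$trainFraction < 1,
    cfg$maxIter >= 1L, cfg$tol > 0, cfg$nBackground >= 1L,
    all(diff(cfg$classBreaks) > 0),
    cfg$centroidThreshold >= 0, cfg$centroidThreshold <= 1,
    cfg$maskThreshold >= 0, cfg$maskThreshold <= 1, cfg$kGrades >= 2L
  )
  invisible(cfg)
}

# small deterministic hash of the configuration for artifact stamping
.configHash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x)
    paste(format(x, digits = 12), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline on a synthetic scene
#'
#' Generates (or accepts) the inputs, then runs the stages in dependency
#' order: variable screening, bootstrap maximum-entropy ensemble,
#' suitability zoning and class areas, scenario comparison and centroid
#' migration, fingerprint similarity, and environment-metabolite quality
#' zoning. Every artifact is written under \code{outputDir} and stamped
#' with the configuration hash and seed; a stage failure is recorded in the
#' run log and the completed artifacts are left in place.
#'
#' @param outputDir output directory (created if needed).
#' @param config overrides merged onto \code{\link{defaultPipelineConfig}}.
#' @param stack optional \linkS4class{EnvStack}; synthesized when omitted.
#' @param occ optional \linkS4class{OccurrenceSet}; simulated when omitted.
#' @param scenarioStack optional future-scenario \linkS4class{EnvStack}
#'   (same grid); a warmed perturbation of \code{stack} when omitted.
#' @return invisible list of in-memory stage results.
#' @export
runPipeline <- function(outputDir, config = list(), stack = NULL,
                        occ = NULL, scenarioStack = NULL) {
  cfg <- .validateConfig(utils::modifyList(defaultPipelineConfig(), config))
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outputDir, "run.log")
  stamp <- paste0("config ", .configHash(cfg), " seed ", cfg$seed)
  logLine <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(msg, "\n", file = logPath, append = TRUE, sep = "")
    message(msg)
  }
  logLine("pipeline start [", stamp, "]")
  results <- list(config = cfg)
  fail <- function(stage, e) {
    logLine("STAGE FAILED [", stage, "]: ", conditionMessage(e))
    cat(paste0("stage=", stage, " error=", conditionMessage(e), "\n"),
        file = file.path(outputDir, "failure_report.txt"), append = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  # --- synthetic scene -----------------------------------------------------
  tryCatch({
    if (is.null(stack)) {
      cc <- diag(7)
      cc[1, 2] <- cc[2, 1] <- 0.85   # a collinear pair, as bioclim sets have
      cc[3, 4] <- cc[4, 3] <- 0.6
      stack <- makeEnvStack(crossCorr = cc, nrows = cfg$gridRows,
                            ncols = cfg$gridCols, seed = cfg$seed,
                            names = c("bio4", "bio6", "bio12", "elev",
                                      "s_oc", "srad2", "srad4"))
    }
    if (is.null(occ)) {
      occ <- simulateOccurrences(
        stack, trueBeta = c(bio6 = 3, bio12 = 1.2), intercept = -6,
        n = cfg$nOccurrences, seed = .childSeed(cfg$seed, 11))
      writeOccurrences(occ, file.path(outputDir, "occurrences.csv"))
    }
    logLine("inputs ready: ", length(stack@layers), " layers, ",
            nrow(occPoints(occ)), " occurrences")
  }, error = function(e) fail("inputs", e))

  # --- variable screening --------------------------------------------------
  tryCatch({
    cells <- sampleCellValues(stack, n = 10000L, seed = cfg$seed)
    corr <- pairwiseCorrelation(cells)
    # preliminary contributions from a quick all-variable fit
    ev <- extractValues(stack, occ, method = "nearest")
    X <- as.matrix(ev[!ev$incomplete, layerNames(stack), drop = FALSE])
    bg0 <- sampleBackground(stack, n = min(cfg$nBackground, 2000L),
                            seed = cfg$seed)
    pre <- fitMaxent(X, bg0, list(maxIter = 100L, nKnots = 10L))
    contr <- variableContributions(pre)
    sel <- selectUncorrelated(corr, contr, threshold = 0.8)
    utils::write.csv(sel$dropLog, file.path(outputDir, "drop_log.csv"),
                     row.names = FALSE)
    results$selection <- sel
    stack <- envStack(lapply(sel$retained, getLayer, x = stack))
    logLine("variable screening: retained ",
            paste(sel$retained, collapse = ", "))
  }, error = function(e) fail("varselect", e))

  # --- maxent ensemble -----------------------------------------------------
  tryCatch({
    ens <- bootstrapEnsemble(occ, stack, reps = cfg$reps,
                             trainFraction = cfg$trainFraction,
                             seed = cfg$seed, nBackground = cfg$nBackground,
                             config = list(maxIter = cfg$maxIter,
                                           tol = cfg$tol,
                                           nKnots = cfg$nKnots))
    writeEsriAscii(ens$meanRaster, file.path(outputDir, "suitability.asc"))
    results$ensemble <- ens
    logLine("ensemble: mean test AUC ",
            round(mean(ens$testAUC), 3), " over ", cfg$reps, " reps")
  }, error = function(e) fail("sdm", e))

  # --- zoning --------------------------------------------------------------
  tryCatch({
    suit <- results$ensemble$meanRaster
    breaks <- if (cfg$useJenks)
      jenksBreaks(suit@values[!is.na(suit@values)], 4L) else cfg$classBreaks
    cm <- classifySuitability(suit, breaks = breaks)
    writeEsriAscii(cm@classes, file.path(outputDir, "suitability_class.asc"),
                   decimals = 0L)
    utils::write.csv(data.frame(class = names(cm@areasKm2),
                                area_km2 = as.numeric(cm@areasKm2)),
                     file.path(outputDir, "class_areas.csv"),
                     row.names = FALSE)
    results$classMap <- cm
    logLine("zoning: breaks ", paste(round(breaks, 3), collapse = "/"))
  }, error = function(e) fail("zone", e))

  # --- scenario comparison + centroid migration ----------------------------
  tryCatch({
    suit <- results$ensemble$meanRaster
    if (is.null(scenarioStack)) {
      # a uniform warming-like perturbation of the dominant drivers
      scenarioStack <- envStack(lapply(stack@layers, function(l) {
        l@values <- l@values + if (l@name %in% c("bio6", "bio4")) 0.5 else 0
        l
      }))
    }
    model1 <- results$ensemble$models[[1L]]
    scSuit <- predictSuitability(model1, scenarioStack)
    scCm <- classifySuitability(scSuit, breaks = results$classMap@breaks)
    chg <- changeStatistics(results$classMap@areasKm2, scCm@areasKm2)
    utils::write.csv(chg, file.path(outputDir, "change_statistics.csv"),
                     row.names = FALSE)
    base <- centroidOfMask(binarizeSuitability(suit, cfg$centroidThreshold),
                           suit)
    scen <- centroidOfMask(binarizeSuitability(scSuit,
                                               cfg$centroidThreshold),
                           scSuit)
    mig <- migrationTable(base, list(scenario = scen))
    utils::write.csv(mig, file.path(outputDir, "migration.csv"),
                     row.names = FALSE)
    results$change <- chg
    results$migration <- mig
    logLine("centroid shift ", round(mig$distance_km[1L], 2), " km")
  }, error = function(e) fail("centroid", e))

  # --- evaluation report ---------------------------------------------------
  tryCatch({
    model1 <- results$ensemble$models[[1L]]
    rep <- evaluationReport(model1, seed = cfg$seed)
    jsonlite::write_json(
      list(auc_train = rep$auc_train,
           mean_test_auc = mean(results$ensemble$testAUC),
           contributions = as.list(rep$contributions),
           permutation_importance = as.list(rep$permutation_importance)),
      file.path(outputDir, "evaluation.json"),
      auto_unbox = TRUE, digits = NA)
    results$evaluation <- rep
    logLine("evaluation written")
  }, error = function(e) fail("evaluate", e))

  # --- fingerprints --------------------------------------------------------
  tryCatch({
    scene <- simulateFingerprintScene(nSamples = cfg$nSamples,
                                      nPeaks = cfg$nPeaks,
                                      seed = cfg$seed)
    tabs <- lapply(scene$chromatograms, detectPeaks,
                   minHeight = cfg$minHeight,
                   minProminence = cfg$minProminence)
    cpm <- alignPeakTables(tabs, referenceSample = 1L,
                           rtTolerance = cfg$rtTolerance)
    S <- similarityMatrix(cpm)
    utils::write.csv(round(S, 3), file.path(outputDir, "similarity.csv"))
    results$peakMatrix <- cpm
    results$similarity <- S
    logLine("fingerprints: ", ncol(cpm@areas), " common peaks, similarity ",
            round(min(S[nrow(S), -nrow(S)]), 3), "-",
            round(max(S[nrow(S), -nrow(S)][-nrow(S)]), 3))
  }, error = function(e) fail("fingerprint", e))

  # --- quality zoning ------------------------------------------------------
  tryCatch({
    vars <- layerNames(stack)
    nSites <- 60L
    d <- gridDim(stack)
    siteCells <- .withSeed(.childSeed(cfg$seed, 400),
                           sample(which(validMask(stack)), nSites))
    row <- (siteCells - 1L) %% d[1L] + 1L
    col <- (siteCells - 1L) %/% d[1L] + 1L
    ctr <- .cellCenter(stack@layers[[1L]], row, col)
    sites <- data.frame(id = paste0("site", seq_len(nSites)),
                        lon = ctr$lon, lat = ctr$lat)
    envTab <- extractValues(stack, cbind(sites$lon, sites$lat))[, vars]
    beta <- list()
    driver <- intersect(c("bio6", "bio12", vars), vars)[1:2]
    beta[["Ch.a"]] <- stats::setNames(2.0, driver[1L])
    beta[["Hyp"]] <- stats::setNames(-1.5, driver[2L])
    panel <- simulateContents(envTab, beta, noiseSd = 0.3,
                              seed = .childSeed(cfg$seed, 500),
                              sites = sites)
    ct <- correlationTable(panel, envTab)
    utils::write.csv(ct, file.path(outputDir, "correlation_table.csv"),
                     row.names = FALSE)
    fits <- lapply(names(beta), function(cp)
      stepwiseFit(panel, envTab, cp))
    names(fits) <- names(beta)
    rasters <- lapply(fits, predictContentRaster, stack = stack)
    qz <- overlayQualityZoning(rasters, results$ensemble$meanRaster,
                               maskThreshold = cfg$maskThreshold,
                               kGrades = cfg$kGrades)
    writeEsriAscii(qz@score, file.path(outputDir, "quality_score.asc"))
    writeEsriAscii(qz@grades, file.path(outputDir, "quality_grade.asc"),
                   decimals = 0L)
    results$quality <- qz
    logLine("quality zoning written")
  }, error = function(e) fail("quality", e))

  logLine("pipeline complete [", stamp, "]")
  invisible(results)
}
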