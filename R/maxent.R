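#' Sample background cells from a stack
#'
#' Uniform sample of jointly valid cells without replacement, reproducible
#' given the seed. If fewer valid cells than requested exist, all are taken
#' (with a warning), in deterministic row-major order.
#'
#' @param stack an \linkS4class{EnvStack}.
#' @param n background points requested (default 10000).
#' @param seed integer seed.
#' @return a \code{BackgroundSample}: list with \code{points} (cell-center
#'   lon/lat), \code{X} (covariate rows), \code{n}, \code{seed}.
#' @export
sampleBackground <- function(stack, n = 10000L, seed = 1L) {
  mask <- validMask(stack)
  idx <- which(mask)  # column-major over the grid
  if (!length(idx))
    stop("stack has no jointly valid cells", call. = FALSE)
  if (length(idx) <= n) {
    if (length(idx) < n)
      warning("only ", length(idx), " valid cells available; taking all",
              call. = FALSE)
    take <- idx
  } else {
    take <- sort(idx[.withSeed(seed, sample.int(length(idx), n))])
  }
  d <- gridDim(stack)
  row <- (take - 1L) %% d[1L] + 1L
  col <- (take - 1L) %/% d[1L] + 1L
  ref <- stack@layers[[1L]]
  ctr <- .cellCenter(ref, row, col)
  X <- vapply(stack@layers, function(l) l@values[take],
              numeric(length(take)))
  if (is.null(dim(X))) X <- matrix(X, nrow = length(take))
  colnames(X) <- layerNames(stack)
  structure(list(points = cbind(lon = ctr$lon, lat = ctr$lat),
                 X = X, n = length(take), seed = seed),
            class = "BackgroundSample")
}

# stable log-sum-exp
.logSumExp <- function(s) {
  m <- max(s)
  m + log(sum(exp(s - m)))
}

#' Fit a presence-background maximum-entropy model
#'
#' Maximizes the L1-penalized log likelihood
#' \deqn{\frac{1}{m}\sum_i \log q(x_i) - \sum_j \beta_j |\lambda_j|,\qquad
#'       q(x) = \exp(\sum_j \lambda_j f_j(x)) / Z}
#' over the background by proximal gradient ascent with backtracking — a
#' convex problem, so the optimizer choice does not change the optimum.
#' Iteration stops when the improvement in regularized gain falls below
#' \code{tol} or \code{maxIter} is reached. Per-feature regularization
#' follows the canonical schedule (linear/quadratic/product interpolated by
#' presence count, hinge constant 0.5), scaled as
#' \eqn{\beta_j = mult \cdot \beta_{class} \cdot \sqrt{s^2_j / m}} with
#' \eqn{s^2_j} the feature variance over presences.
#'
#' @param presenceX matrix/data.frame of presence covariate rows.
#' @param background a \code{BackgroundSample} from
#'   \code{\link{sampleBackground}}, or a bare covariate matrix.
#' @param config list of settings: \code{maxIter} (500), \code{tol}
#'   (\code{1e-5}), \code{regMultiplier} (1), \code{classes},
#'   \code{nKnots} (50), \code{addSamples} (\code{TRUE} — presence rows are
#'   appended to the normalization background, the usual default).
#' @return a \linkS4class{MaxentModel}.
#' @export
fitMaxent <- function(presenceX, background, config = list()) {
  cfg <- utils::modifyList(list(
    maxIter = 500L, tol = 1e-5, regMultiplier = 1,
    classes = c("linear", "quadratic", "product", "hinge"),
    nKnots = 50L, addSamples = TRUE), config)
  P <- as.matrix(presenceX)
  B <- if (inherits(background, "BackgroundSample")) background$X
       else as.matrix(background)
  if (nrow(P) < 2L) stop("need at least 2 presence rows", call. = FALSE)
  if (is.null(colnames(P))) colnames(P) <- colnames(B)
  B <- B[, colnames(P), drop = FALSE]
  if (any(!is.finite(P)) || any(!is.finite(B)))
    stop("non-finite covariate values", call. = FALSE)
  bgAll <- if (isTRUE(cfg$addSamples)) rbind(B, P) else B
  fs <- buildFeatureSet(rbind(P, B), classes = cfg$classes,
                        nKnots = cfg$nKnots)
  Fp <- featureMatrix(fs, P)
  Fb <- featureMatrix(fs, bgAll)
  m <- nrow(Fp)
  nBg <- nrow(Fb)
  fbarP <- colMeans(Fp)
  sdP <- apply(Fp, 2L, stats::sd)
  betaC <- unname(vapply(fs$table$type, .betaClass, numeric(1), m = m))
  beta <- cfg$regMultiplier * betaC * pmax(unname(sdP) / sqrt(m), 1e-6)

  J <- ncol(Fb)
  lambda <- numeric(J)
  s <- as.vector(Fb %*% lambda)
  logZ <- .logSumExp(s)
  objective <- function(lam, lz)
    sum(lam * fbarP) - lz + log(nBg) - sum(beta * abs(lam))
  gain <- objective(lambda, logZ)
  gainTraj <- numeric(0)
  varGain <- stats::setNames(numeric(length(fs$vars)), fs$vars)
  shares <- .featureVarShares(fs)
  converged <- FALSE
  t <- 1
  for (it in seq_len(cfg$maxIter)) {
    w <- exp(s - logZ)                 # q over background
    g <- fbarP - as.vector(crossprod(Fb, w))
    # proximal (soft-threshold) step with backtracking on the full objective
    repeat {
      lamNew <- lambda + t * g
      lamNew <- sign(lamNew) * pmax(abs(lamNew) - t * beta, 0)
      sNew <- as.vector(Fb %*% lamNew)
      lzNew <- .logSumExp(sNew)
      gNew <- objective(lamNew, lzNew)
      if (gNew >= gain || t < 1e-10) break
      t <- t / 2
    }
    if (gNew < gain - 1e-8) {          # could not improve at all
      gainTraj <- c(gainTraj, gain)
      break
    }
    dGain <- gNew - gain
    dlMax <- max(abs(lamNew - lambda))
    dl <- abs((lamNew - lambda) * g)
    if (sum(dl) > 0 && dGain > 0)
      varGain <- varGain + dGain * as.vector(crossprod(shares, dl)) / sum(dl)
    lambda <- lamNew; s <- sNew; logZ <- lzNew; gain <- gNew
    gainTraj <- c(gainTraj, gain)
    t <- min(t * 2, 1e4)
    # tol > 0: the configured gain-improvement rule; tol = 0: iterate on the
    # gradient until the weight update itself stalls (the objective is flat
    # to double precision well before lambda stops moving)
    if (cfg$tol > 0) {
      if (it > 1L && dGain < cfg$tol) { converged <- TRUE; break }
    } else if (dlMax < 1e-10) { converged <- TRUE; break }
  }
  if (!converged && cfg$maxIter > 0L && length(gainTraj) == cfg$maxIter)
    converged <- TRUE                   # stopped by the iteration cap, as configured
  w <- exp(s - logZ)
  H <- -sum(w * (s - logZ))
  new("MaxentModel", features = fs, lambda = lambda, regBeta = beta,
      logZ = logZ, entropyH = H, gainTrajectory = gainTraj,
      varGain = varGain, presenceX = P,
      backgroundX = B, nNorm = as.numeric(nBg), converged = converged)
}

#' Raw (relative occurrence rate) prediction
#'
#' \eqn{q(x) = \exp(\lambda \cdot f(x) - \log Z)} with the training-time
#' normalizer, so background rows sum to ~1.
#'
#' @param model a \linkS4class{MaxentModel}.
#' @param rows covariate matrix/data.frame containing the model variables.
#' @return numeric vector of q values.
#' @export
predictRaw <- function(model, rows) {
  F <- featureMatrix(model@features, as.matrix(rows))
  exp(as.vector(F %*% model@lambda) - model@logZ)
}

#' Logistic suitability prediction
#'
#' The Phillips–Dudík logistic transform with \eqn{\tau = 0.5}:
#' \eqn{p = e^H q / (1 + e^H q)} where \eqn{H} is the entropy of the fitted
#' distribution. A uniform model yields \eqn{p = 0.5} everywhere, and the
#' transform is strictly monotone in \eqn{q} (rank-preserving, hence
#' AUC-preserving).
#'
#' @inheritParams predictRaw
#' @return numeric vector of suitabilities in (0, 1).
#' @export
predictLogistic <- function(model, rows) {
  q <- predictRaw(model, rows)
  eh <- exp(model@entropyH)
  eh * q / (1 + eh * q)
}

#' Predict a suitability raster over a stack
#'
#' @param model a \linkS4class{MaxentModel}.
#' @param stack an \linkS4class{EnvStack} carrying the model variables.
#' @param type \code{"logistic"} or \code{"raw"}.
#' @return a \linkS4class{RasterGrid} named \code{"suitability"}.
#' @export
predictSuitability <- function(model, stack, type = c("logistic", "raw")) {
  type <- match.arg(type)
  mask <- validMask(stack)
  idx <- which(mask)
  X <- vapply(stack@layers, function(l) l@values[idx], numeric(length(idx)))
  if (is.null(dim(X))) X <- matrix(X, nrow = length(idx))
  colnames(X) <- layerNames(stack)
  p <- if (type == "logistic") predictLogistic(model, X)
       else predictRaw(model, X)
  ref <- stack@layers[[1L]]
  out <- matrix(NA_real_, nrow(ref@values), ncol(ref@values))
  out[idx] <- p
  rasterGrid(out, name = "suitability", xll = ref@xll, yll = ref@yll,
             cellsize = ref@cellsize, nodata = ref@nodata)
}

#' Bootstrap ensemble of maximum-entropy fits
#'
#' Each replicate resamples the occurrences with replacement to 75% training
#' size, holds out the records never drawn for test AUC, fits a model and
#' predicts; the ensemble surface is the cell-wise mean of the logistic
#' outputs.
#'
#' @param occ an \linkS4class{OccurrenceSet}.
#' @param stack an \linkS4class{EnvStack}.
#' @param reps replicates (default 100, the conventional setting).
#' @param trainFraction training fraction (default 0.75).
#' @param seed integer seed.
#' @param nBackground background points per fit.
#' @param config fit settings forwarded to \code{\link{fitMaxent}}.
#' @return list: \code{meanRaster} (\linkS4class{RasterGrid}),
#'   \code{testAUC} (per-rep), \code{models} (fitted replicates).
#' @export
bootstrapEnsemble <- function(occ, stack, reps = 100L, trainFraction = 0.75,
                              seed = 1L, nBackground = 10000L,
                              config = list()) {
  if (reps < 1L) stop("'reps' must be at least 1", call. = FALSE)
  pts <- occPoints(occ)
  if (nrow(pts) < 8L) stop("need at least 8 occurrences", call. = FALSE)
  ev <- extractValues(stack, pts, method = "nearest")
  keep <- !ev$incomplete
  if (!all(keep))
    warning(sum(!keep), " occurrence(s) on nodata cells dropped",
            call. = FALSE)
  X <- as.matrix(ev[keep, layerNames(stack), drop = FALSE])
  m <- nrow(X)
  bg <- sampleBackground(stack, n = nBackground, seed = .childSeed(seed, 0))
  mTrain <- max(2L, round(trainFraction * m))
  acc <- NULL
  aucs <- numeric(reps)
  models <- vector("list", reps)
  for (r in seq_len(reps)) {
    trainIdx <- .withSeed(.childSeed(seed, r),
                          sample.int(m, mTrain, replace = TRUE))
    testIdx <- setdiff(seq_len(m), unique(trainIdx))
    fit <- fitMaxent(X[trainIdx, , drop = FALSE], bg, config)
    models[[r]] <- fit
    sTest <- if (length(testIdx))
      predictLogistic(fit, X[testIdx, , drop = FALSE])
      else predictLogistic(fit, X[trainIdx, , drop = FALSE])
    sBg <- predictLogistic(fit, bg$X)
    aucs[r] <- aucScore(sTest, sBg)
    ras <- predictSuitability(fit, stack)
    acc <- if (is.null(acc)) ras@values else acc + ras@values
  }
  ref <- stack@layers[[1L]]
  meanRaster <- rasterGrid(acc / reps, name = "suitability",
                           xll = ref@xll, yll = ref@yll,
                           cellsize = ref@cellsize, nodata = ref@nodata)
  list(meanRaster = meanRaster, testAUC = aucs, models = models)
}

#' Serialize / restore a fitted model
#'
#' Plain-text JSON round-trip of the feature table, weights, normalizer and
#' entropy (evaluation data matrices are not serialized).
#'
#' @param model a \linkS4class{MaxentModel}.
#' @param path output path.
#' @export
writeMaxentModel <- function(model, path) {
  obj <- list(
    vars = model@features$vars,
    range = model@features$range,
    table = model@features$table,
    lambda = model@lambda,
    regBeta = model@regBeta,
    logZ = model@logZ,
    entropyH = model@entropyH,
    gainTrajectory = model@gainTrajectory,
    varGain = as.list(model@varGain),
    nNorm = model@nNorm,
    converged = model@converged
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(path)
}

#' @rdname writeMaxentModel
#' @return \code{readMaxentModel}: a \linkS4class{MaxentModel} usable for
#'   prediction (evaluation slots empty).
#' @export
readMaxentModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rng <- as.matrix(obj$range)
  rownames(rng) <- c("min", "max")
  colnames(rng) <- obj$vars
  fs <- list(vars = obj$vars, range = rng,
             table = as.data.frame(obj$table))
  new("MaxentModel", features = fs, lambda = as.numeric(obj$lambda),
      regBeta = as.numeric(obj$regBeta), logZ = obj$logZ,
      entropyH = obj$entropyH,
      gainTrajectory = as.numeric(obj$gainTrajectory),
      varGain = unlist(obj$varGain),
      presenceX = matrix(numeric(0), 0, 0),
      backgroundX = matrix(numeric(0), 0, 0),
      nNorm = as.numeric(obj$nNorm),
      converged = isTRUE(obj$converged))
}
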