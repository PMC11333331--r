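#' Smooth Gaussian random field
#'
#' Mean-0, sd-1 spatially correlated field by spectral synthesis: white
#' noise is filtered in the Fourier domain with a Gaussian kernel of the
#' requested correlation length (in cells), then standardized. As the
#' correlation length tends to 0 the field tends to white noise.
#'
#' @param nrows,ncols grid dimensions (>= 8).
#' @param correlationLength kernel scale in cells (> 0).
#' @param seed integer seed; fields are bit-reproducible given the seed.
#' @param name,xll,yll,cellsize,nodata raster georeferencing, as in
#'   \code{\link{rasterGrid}}.
#' @return a \linkS4class{RasterGrid}.
#' @export
gaussianField <- function(nrows, ncols, correlationLength = 8, seed = 1L,
                          name = "field", xll = 0, yll = 0, cellsize = 0.05,
                          nodata = -9999) {
  if (nrows < 8L || ncols < 8L)
    stop("field dimensions must be at least 8", call. = FALSE)
  if (correlationLength <= 0)
    stop("correlationLength must be positive", call. = FALSE)
  z <- .withSeed(seed, matrix(stats::rnorm(nrows * ncols), nrows, ncols))
  # Gaussian transfer function on the torus frequencies
  fr <- c(0:(floor(nrows / 2)), -((ceiling(nrows / 2) - 1L):1L)) / nrows
  fc <- c(0:(floor(ncols / 2)), -((ceiling(ncols / 2) - 1L):1L)) / ncols
  k2 <- outer(fr^2, fc^2, "+")
  H <- exp(-2 * (pi * correlationLength)^2 * k2)
  f <- Re(stats::fft(stats::fft(z) * H, inverse = TRUE)) / (nrows * ncols)
  f <- (f - mean(f)) / stats::sd(f)
  rasterGrid(f, name = name, xll = xll, yll = yll, cellsize = cellsize,
             nodata = nodata)
}

#' Synthetic environment stack with controlled cross-correlation
#'
#' Mixes independent Gaussian fields through the Cholesky factor of a
#' target correlation matrix, emulating the collinearity structure of
#' bioclimatic layer sets (some pairs at or above 0.8) so variable
#' screening can be exercised realistically.
#'
#' @param k number of layers; ignored if \code{crossCorr} is given.
#' @param crossCorr symmetric positive-definite k x k target correlation
#'   matrix (default identity).
#' @param nrows,ncols grid dimensions.
#' @param correlationLength spatial correlation length in cells.
#' @param seed integer seed.
#' @param names layer names (default \code{env1..envk}).
#' @param xll,yll,cellsize georeferencing.
#' @return an \linkS4class{EnvStack}.
#' @export
makeEnvStack <- function(k = 7L, crossCorr = NULL, nrows = 100L,
                         ncols = 100L, correlationLength = 8, seed = 1L,
                         names = NULL, xll = 100, yll = 20,
                         cellsize = 0.05) {
  if (is.null(crossCorr)) crossCorr <- diag(k)
  k <- nrow(crossCorr)
  if (!isSymmetric(unname(crossCorr)))
    stop("crossCorr must be symmetric", call. = FALSE)
  ch <- tryCatch(chol(crossCorr),
                 error = function(e) stop("crossCorr must be positive-definite",
                                          call. = FALSE))
  if (is.null(names)) names <- paste0("env", seq_len(k))
  fields <- lapply(seq_len(k), function(i)
    gaussianField(nrows, ncols, correlationLength,
                  seed = .childSeed(seed, i))@values)
  Z <- vapply(fields, as.vector, numeric(nrows * ncols))
  X <- Z %*% ch
  layers <- lapply(seq_len(k), function(i)
    rasterGrid(matrix(X[, i], nrows, ncols), name = names[i],
               xll = xll, yll = yll, cellsize = cellsize))
  envStack(layers)
}

#' Simulate occurrences from a known suitability law
#'
#' Presence probability proportional to the logistic of a linear predictor
#' \eqn{\beta \cdot x} over the valid cells; cells are drawn with
#' replacement by that weight and points jittered uniformly within the
#' sampled cell. A smooth logistic truth keeps the recovered response
#' curves smooth.
#'
#' @param stack an \linkS4class{EnvStack}.
#' @param trueBeta named numeric, weights on (a subset of) the stack's
#'   layers.
#' @param intercept intercept of the linear predictor; negative values make
#'   the species range-restricted (the default -6 with the standard scene
#'   weights puts ~6\% of the landscape at high suitability, the usual
#'   situation for a ranged species).
#' @param n number of presence points.
#' @param seed integer seed.
#' @param species species label.
#' @return an \linkS4class{OccurrenceSet}; the truth (beta, intercept, the
#'   probability surface) is attached as attribute \code{truth}.
#' @export
simulateOccurrences <- function(stack, trueBeta, intercept = -6,
                                n = 298L, seed = 1L,
                                species = "Lonicera japonica") {
  if (n < 1L) stop("'n' must be at least 1", call. = FALSE)
  vars <- names(trueBeta)
  miss <- setdiff(vars, layerNames(stack))
  if (length(miss))
    stop("trueBeta names missing from stack: ",
         paste(miss, collapse = ", "), call. = FALSE)
  mask <- validMask(stack)
  idx <- which(mask)
  eta <- rep(intercept, length(idx))
  for (v in vars) eta <- eta + trueBeta[[v]] * getLayer(stack, v)@values[idx]
  wt <- stats::plogis(eta)
  if (sum(wt) <= 0)
    stop("degenerate suitability law: all weights zero", call. = FALSE)
  ref <- stack@layers[[1L]]
  d <- gridDim(stack)
  draw <- .withSeed(seed, {
    cells <- sample(seq_along(idx), n, replace = TRUE, prob = wt)
    jit <- matrix(stats::runif(2L * n, -0.5, 0.5), n, 2L)
    list(cells = cells, jit = jit)
  })
  ci <- idx[draw$cells]
  row <- (ci - 1L) %% d[1L] + 1L
  col <- (ci - 1L) %/% d[1L] + 1L
  ctr <- .cellCenter(ref, row, col)
  pts <- cbind(lon = ctr$lon + draw$jit[, 1L] * ref@cellsize,
               lat = ctr$lat + draw$jit[, 2L] * ref@cellsize)
  occ <- new("OccurrenceSet", species = species, points = pts)
  surf <- matrix(NA_real_, d[1L], d[2L])
  surf[idx] <- wt
  attr(occ, "truth") <- list(
    trueBeta = trueBeta, intercept = intercept,
    trueSurface = rasterGrid(surf, name = "true_suitability",
                             xll = ref@xll, yll = ref@yll,
                             cellsize = ref@cellsize),
    seed = seed)
  occ
}

#' Simulate an HPLC chromatogram with planted peaks
#'
#' Sum of Gaussian peaks plus a linear drift and white noise over a run of
#' the given duration (default 50 min, matching a typical gradient end
#' time).
#'
#' @param peakSpec data.frame with columns \code{rt} (min), \code{width}
#'   (Gaussian sd, min), \code{area}.
#' @param noiseSd white-noise standard deviation.
#' @param drift total linear baseline drift over the run.
#' @param seed integer seed.
#' @param duration run length in minutes.
#' @param rate sampling rate, points per minute.
#' @param sampleId sample identifier.
#' @return a \linkS4class{Chromatogram}; the generating peak table is
#'   attached as attribute
#'   \code{truth}.
#' @export
simulateChromatogram <- function(peakSpec, noiseSd = 0, drift = 0,
                                 seed = 1L, duration = 50, rate = 20,
                                 sampleId = "sample") {
  if (nrow(peakSpec) && any(peakSpec$rt < 0 | peakSpec$rt > duration))
    stop("peak retention times must lie within the run duration",
         call. = FALSE)
  t <- seq(0, duration, by = 1 / rate)
  y <- drift * t / duration
  for (i in seq_len(nrow(peakSpec)))
    y <- y + peakSpec$area[i] *
      stats::dnorm(t, peakSpec$rt[i], peakSpec$width[i])
  if (noiseSd > 0)
    y <- y + .withSeed(seed, stats::rnorm(length(t), 0, noiseSd))
  ch <- chromatogram(t, y, sampleId = sampleId,
                     meta = list(wavelength_nm = 245, column_temp_C = 38,
                                 flow_mL_min = 1, injection_uL = 10))
  attr(ch, "truth") <- list(peakSpec = peakSpec, noiseSd = noiseSd,
                            drift = drift, seed = seed)
  ch
}

#' Simulate a multi-sample fingerprint scene
#'
#' A panel of chromatograms sharing \code{nPeaks} true peaks whose areas
#' vary between samples by a lognormal factor (\code{areaSpread} on the log
#' scale), plus a few per-sample spurious peaks at random retention times —
#' the structure behind a common-peak analysis. At a low spread (~0.1) the
#' samples stay close to the reference fingerprint; at ~0.25 the similarity
#' range approaches what region-to-region herbal panels typically show.
#'
#' @param nSamples number of samples (default 11 regions).
#' @param nPeaks shared true peaks (default 21).
#' @param areaSpread sd of the per-sample log-area perturbation.
#' @param noiseSd chromatogram white-noise sd.
#' @param nSpurious spurious (non-shared) peaks per sample.
#' @param seed integer seed.
#' @return list: \code{chromatograms} (list of
#'   \linkS4class{Chromatogram}), \code{trueRT} (planted retention times),
#'   \code{trueAreas} (samples x peaks matrix of planted areas).
#' @export
simulateFingerprintScene <- function(nSamples = 11L, nPeaks = 21L,
                                     areaSpread = 0.25, noiseSd = 0.2,
                                     nSpurious = 3L, seed = 1L) {
  rts <- seq(4, 46, length.out = nPeaks)
  chroms <- vector("list", nSamples)
  areas <- matrix(0, nSamples, nPeaks)
  for (s in seq_len(nSamples)) {
    a <- 60 * exp(.withSeed(.childSeed(seed, 100 + s),
                            stats::rnorm(nPeaks, 0, areaSpread)))
    areas[s, ] <- a
    spec <- data.frame(rt = rts, width = 0.12, area = a)
    if (nSpurious > 0L) {
      sp <- .withSeed(.childSeed(seed, 300 + s),
                      stats::runif(nSpurious, 2, 48))
      spec <- rbind(spec, data.frame(rt = sp, width = 0.1, area = 30))
    }
    chroms[[s]] <- simulateChromatogram(
      spec, noiseSd = noiseSd, drift = 2,
      seed = .childSeed(seed, 200 + s),
      sampleId = paste0("S", s))
  }
  names(chroms) <- paste0("S", seq_len(nSamples))
  rownames(areas) <- names(chroms)
  list(chromatograms = chroms, trueRT = rts, trueAreas = areas)
}

#' Simulate per-site compound contents with known environmental dependence
#'
#' \eqn{content = \beta \cdot x + intercept + \epsilon}, floored at 0.
#'
#' @param envAtSites data.frame/matrix of ecological-factor values per
#'   site.
#' @param contentBeta named list, per compound a named numeric of factor
#'   coefficients.
#' @param intercepts named numeric intercept per compound (default 5).
#' @param noiseSd Gaussian noise sd (scalar or per compound).
#' @param seed integer seed.
#' @param sites optional data.frame \code{id}, \code{lon}, \code{lat}; a
#'   placeholder frame is built when omitted.
#' @return a \linkS4class{CompoundPanel}; truth attached as attribute.
#' @export
simulateContents <- function(envAtSites, contentBeta, intercepts = NULL,
                             noiseSd = 0, seed = 1L, sites = NULL) {
  env <- as.matrix(envAtSites)
  n <- nrow(env)
  cps <- names(contentBeta)
  if (is.null(intercepts))
    intercepts <- stats::setNames(rep(5, length(cps)), cps)
  if (length(noiseSd) == 1L)
    noiseSd <- stats::setNames(rep(noiseSd, length(cps)), cps)
  contents <- matrix(0, n, length(cps), dimnames = list(NULL, cps))
  for (j in seq_along(cps)) {
    b <- contentBeta[[cps[j]]]
    mu <- rep(intercepts[[cps[j]]], n)
    for (f in names(b)) mu <- mu + b[[f]] * env[, f]
    eps <- if (noiseSd[[cps[j]]] > 0)
      .withSeed(.childSeed(seed, j), stats::rnorm(n, 0, noiseSd[[cps[j]]]))
      else 0
    contents[, j] <- pmax(mu + eps, 0)
  }
  if (is.null(sites))
    sites <- data.frame(id = paste0("site", seq_len(n)),
                        lon = rep(0, n), lat = rep(0, n))
  rownames(contents) <- sites$id
  panel <- new("CompoundPanel", sites = sites, contents = contents)
  attr(panel, "truth") <- list(contentBeta = contentBeta,
                               intercepts = intercepts, noiseSd = noiseSd,
                               seed = seed)
  panel
}
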