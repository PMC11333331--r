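#' @import methods
NULL

#' Georeferenced raster grid
#'
#' A single gridded layer in geographic (WGS84 decimal-degree) coordinates,
#' cell-registered: \code{xll}/\code{yll} give the lower-left *corner* of the
#' grid. Values are stored north-to-south (row 1 is the northernmost row) with
#' \code{NA} marking nodata cells; the \code{nodata} slot records the sentinel
#' used on disk.
#'
#' @slot name single character, layer identifier (e.g. \code{"bio6"}).
#' @slot xll,yll numeric, lower-left corner in decimal degrees.
#' @slot cellsize numeric, degrees per cell (square cells).
#' @slot nodata numeric, the on-disk nodata sentinel.
#' @slot values numeric matrix, \code{nrows x ncols}, row 1 = north.
#' @exportClass RasterGrid
setClass("RasterGrid",
  representation(
    name = "character",
    xll = "numeric",
    yll = "numeric",
    cellsize = "numeric",
    nodata = "numeric",
    values = "matrix"
  ),
  prototype(name = "layer", xll = 0, yll = 0, cellsize = 1, nodata = -9999)
)

setValidity("RasterGrid", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@cellsize) != 1L || !is.finite(object@cellsize) ||
      object@cellsize <= 0)
    msg <- c(msg, "'cellsize' must be a single positive number")
  if (nrow(object@values) < 1L || ncol(object@values) < 1L)
    msg <- c(msg, "grid must have at least one row and one column")
  if (!is.numeric(object@values))
    msg <- c(msg, "'values' must be numeric")
  if (length(object@nodata) != 1L || !is.finite(object@nodata))
    msg <- c(msg, "'nodata' must be a single finite number")
  v <- object@values
  if (any(v[is.finite(v)] == object@nodata))
    msg <- c(msg, "finite cell values must not equal the nodata sentinel")
  if (length(msg)) msg else TRUE
})

#' Stack of aligned environmental layers
#'
#' An ordered collection of \linkS4class{RasterGrid} layers sharing one grid
#' (identical dimensions, origin and cell size) with unique names. The joint
#' validity mask (cells observed in every layer) is available via
#' \code{\link{validMask}}.
#'
#' @slot layers list of \linkS4class{RasterGrid}.
#' @exportClass EnvStack
setClass("EnvStack", representation(layers = "list"))

setValidity("EnvStack", function(object) {
  msg <- character()
  ls <- object@layers
  if (length(ls) < 1L) return("stack must contain at least one layer")
  if (!all(vapply(ls, is, logical(1), "RasterGrid")))
    return("all layers must be RasterGrid objects")
  nm <- vapply(ls, function(l) l@name, character(1))
  if (anyDuplicated(nm))
    msg <- c(msg, "layer names must be unique")
  ref <- ls[[1L]]
  same <- vapply(ls, function(l) {
    identical(dim(l@values), dim(ref@values)) &&
      isTRUE(all.equal(l@xll, ref@xll)) &&
      isTRUE(all.equal(l@yll, ref@yll)) &&
      isTRUE(all.equal(l@cellsize, ref@cellsize))
  }, logical(1))
  if (!all(same))
    msg <- c(msg, "all layers must share one grid (dims, origin, cellsize)")
  if (length(msg)) msg else TRUE
})

#' Species occurrence records
#'
#' Presence points in WGS84 decimal degrees. Duplicated coordinates are
#' permitted (and flagged by \code{show}) since herbarium data often repeat
#' localities.
#'
#' @slot species single character.
#' @slot points numeric matrix with columns \code{lon}, \code{lat}.
#' @exportClass OccurrenceSet
setClass("OccurrenceSet",
  representation(species = "character", points = "matrix"))

setValidity("OccurrenceSet", function(object) {
  p <- object@points
  if (ncol(p) != 2L) return("'points' must have two columns (lon, lat)")
  if (nrow(p) < 1L) return("at least one occurrence point is required")
  if (any(!is.finite(p))) return("coordinates must be finite")
  if (any(p[, 1L] < -180 | p[, 1L] > 180))
    return("longitudes must lie in [-180, 180]")
  if (any(p[, 2L] < -90 | p[, 2L] > 90))
    return("latitudes must lie in [-90, 90]")
  TRUE
})

#' Fitted maximum-entropy distribution model
#'
#' Presence-background Gibbs distribution over the background cells,
#' \eqn{q(x) = \exp(\sum_j \lambda_j f_j(x)) / Z}, fitted by L1-regularized
#' convex optimization. The entropy \eqn{H} of the fitted distribution drives
#' the logistic output transform.
#'
#' @slot features feature set built by \code{\link{buildFeatureSet}}: scaling
#'   bounds per variable plus the expanded feature table.
#' @slot lambda numeric, one weight per feature.
#' @slot regBeta numeric, per-feature L1 regularization amounts.
#' @slot logZ single numeric, log partition over the background.
#' @slot entropyH single numeric, entropy of the fitted distribution.
#' @slot gainTrajectory numeric, regularized training gain per iteration.
#' @slot varGain named numeric, per-variable attributed gain (for
#'   \code{\link{variableContributions}}).
#' @slot presenceX,backgroundX numeric matrices of raw covariates retained for
#'   evaluation (permutation importance, response curves).
#' @slot nNorm single numeric, size of the normalization set behind \code{logZ}
#'   (background plus appended presences, when enabled).
#' @slot converged logical flag; a failed decrease is carried as a warning in
#'   the model, not an error.
#' @exportClass MaxentModel
setClass("MaxentModel",
  representation(
    features = "list",
    lambda = "numeric",
    regBeta = "numeric",
    logZ = "numeric",
    entropyH = "numeric",
    gainTrajectory = "numeric",
    varGain = "numeric",
    presenceX = "matrix",
    backgroundX = "matrix",
    nNorm = "numeric",
    converged = "logical"
  )
)

setValidity("MaxentModel", function(object) {
  if (length(object@lambda) != nrow(object@features$table))
    return("one lambda per feature is required")
  if (length(object@regBeta) != length(object@lambda))
    return("one regularization amount per feature is required")
  TRUE
})

#' Classified suitability map
#'
#' Integer-coded suitability classes (0 = no, 1 = low, 2 = medium, 3 = high by
#' default) with the break values used and per-class areas in km².
#'
#' @slot classes \linkS4class{RasterGrid} of integer codes.
#' @slot breaks numeric, strictly increasing interior break values in [0, 1].
#' @slot areasKm2 named numeric, km² per class.
#' @exportClass SuitabilityClassMap
setClass("SuitabilityClassMap",
  representation(classes = "RasterGrid", breaks = "numeric",
                 areasKm2 = "numeric"))

setValidity("SuitabilityClassMap", function(object) {
  b <- object@breaks
  if (length(b) && (any(diff(b) <= 0) || any(b < 0 | b > 1)))
    return("breaks must be strictly increasing within [0, 1]")
  if (any(object@areasKm2 < 0)) return("class areas must be nonnegative")
  TRUE
})

#' HPLC chromatogram
#'
#' A detector trace: strictly increasing retention times (minutes) and the
#' matching signal. Acquisition metadata (wavelength nm, column temperature
#' °C, flow mL/min, injection µL, gradient program) ride along in \code{meta}.
#'
#' @slot sampleId single character.
#' @slot time numeric, minutes, strictly increasing.
#' @slot signal numeric, same length as \code{time}.
#' @slot meta list of acquisition metadata.
#' @exportClass Chromatogram
setClass("Chromatogram",
  representation(sampleId = "character", time = "numeric",
                 signal = "numeric", meta = "list"),
  prototype(meta = list()))

setValidity("Chromatogram", function(object) {
  if (length(object@time) != length(object@signal))
    return("'time' and 'signal' must have equal length")
  if (length(object@time) < 2L)
    return("a chromatogram needs at least two points")
  if (any(diff(object@time) <= 0))
    return("'time' must be strictly increasing")
  TRUE
})

#' Common-peak area matrix
#'
#' Samples-by-peaks matrix of baseline-subtracted areas for the peaks present
#' in every sample after retention-time correction, plus the consensus
#' retention time per column and the map from identified marker compounds to
#' peak columns.
#'
#' @slot areas numeric matrix, samples x common peaks; no missing entries.
#' @slot peakRT numeric, consensus retention time per column.
#' @slot compoundMap named integer, compound name -> column index.
#' @exportClass CommonPeakMatrix
setClass("CommonPeakMatrix",
  representation(areas = "matrix", peakRT = "numeric",
                 compoundMap = "integer"),
  prototype(compoundMap = integer()))

setValidity("CommonPeakMatrix", function(object) {
  if (anyNA(object@areas)) return("common-peak areas must have no missing entries")
  if (length(object@peakRT) != ncol(object@areas))
    return("one retention time per peak column is required")
  cm <- object@compoundMap
  if (length(cm) && (any(cm < 1L) || any(cm > ncol(object@areas))))
    return("compoundMap indices must address peak columns")
  TRUE
})

#' Per-site compound content panel
#'
#' Site coordinates and a site-by-compound table of contents (mg/g) for the
#' marker compounds.
#'
#' @slot sites data.frame with columns \code{id}, \code{lon}, \code{lat}.
#' @slot contents numeric matrix, sites x compounds, nonnegative.
#' @exportClass CompoundPanel
setClass("CompoundPanel",
  representation(sites = "data.frame", contents = "matrix"))

setValidity("CompoundPanel", function(object) {
  if (!all(c("id", "lon", "lat") %in% names(object@sites)))
    return("'sites' must have columns id, lon, lat")
  if (nrow(object@sites) != nrow(object@contents))
    return("one content row per site is required")
  if (any(object@contents[is.finite(object@contents)] < 0))
    return("contents must be nonnegative")
  TRUE
})

#' Quality zoning map
#'
#' Quality score in [0, 1] over the suitable region (suitability at or above
#' the masking threshold) plus its graded classification and provenance.
#'
#' @slot score \linkS4class{RasterGrid} of quality scores.
#' @slot grades \linkS4class{RasterGrid} of integer grade codes.
#' @slot breaks numeric grade break values.
#' @slot provenance list: models used, masking threshold, weights.
#' @exportClass QualityZoningMap
setClass("QualityZoningMap",
  representation(score = "RasterGrid", grades = "RasterGrid",
                 breaks = "numeric", provenance = "list"))

setValidity("QualityZoningMap", function(object) {
  sv <- object@score@values
  gv <- object@grades@values
  if (!identical(dim(sv), dim(gv)))
    return("score and grade rasters must share one grid")
  if (any(is.na(sv) != is.na(gv)))
    return("grades must cover exactly the scored cells")
  TRUE
})
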