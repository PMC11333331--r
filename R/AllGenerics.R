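#' @include AllClasses.R
NULL

#' Accessors for raster grids and stacks
#'
#' \code{gridValues} returns the value matrix (row 1 = north, \code{NA} =
#' nodata); \code{gridDim} the \code{c(nrows, ncols)}; \code{cellSize} the
#' cell size in degrees; \code{gridOrigin} the lower-left corner
#' \code{c(xll, yll)}; \code{noDataValue} the on-disk sentinel;
#' \code{layerNames} the layer identifiers of a stack; \code{getLayer} one
#' layer by name.
#'
#' @param x a \linkS4class{RasterGrid} or \linkS4class{EnvStack}.
#' @param name layer name for \code{getLayer}.
#' @return See details above.
#' @name raster-accessors
#' @rdname raster-accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname raster-accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname raster-accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @rdname raster-accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname raster-accessors
#' @export
setGeneric("noDataValue", function(x) standardGeneric("noDataValue"))

#' @rdname raster-accessors
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @rdname raster-accessors
#' @export
setGeneric("getLayer", function(x, name) standardGeneric("getLayer"))

#' @rdname raster-accessors
#' @export
setMethod("gridValues", "RasterGrid", function(x) x@values)

#' @rdname raster-accessors
#' @export
setMethod("gridDim", "RasterGrid", function(x) dim(x@values))

#' @rdname raster-accessors
#' @export
setMethod("cellSize", "RasterGrid", function(x) x@cellsize)

#' @rdname raster-accessors
#' @export
setMethod("gridOrigin", "RasterGrid", function(x) c(xll = x@xll, yll = x@yll))

#' @rdname raster-accessors
#' @export
setMethod("noDataValue", "RasterGrid", function(x) x@nodata)

#' @rdname raster-accessors
#' @export
setMethod("layerNames", "EnvStack",
  function(x) vapply(x@layers, function(l) l@name, character(1)))

#' @rdname raster-accessors
#' @export
setMethod("getLayer", "EnvStack", function(x, name) {
  i <- match(name, layerNames(x))
  if (is.na(i)) stop("no layer named '", name, "' in stack", call. = FALSE)
  x@layers[[i]]
})

#' @rdname raster-accessors
#' @export
setMethod("gridDim", "EnvStack", function(x) dim(x@layers[[1L]]@values))

#' @rdname raster-accessors
#' @export
setMethod("cellSize", "EnvStack", function(x) x@layers[[1L]]@cellsize)

#' @rdname raster-accessors
#' @export
setMethod("gridOrigin", "EnvStack",
  function(x) c(xll = x@layers[[1L]]@xll, yll = x@layers[[1L]]@yll))

#' Accessors for occurrence sets
#'
#' @param x an \linkS4class{OccurrenceSet}.
#' @return \code{occPoints}: two-column matrix of lon/lat;
#'   \code{occSpecies}: the species label.
#' @name occurrence-accessors
#' @rdname occurrence-accessors
#' @export
setGeneric("occPoints", function(x) standardGeneric("occPoints"))

#' @rdname occurrence-accessors
#' @export
setGeneric("occSpecies", function(x) standardGeneric("occSpecies"))

#' @rdname occurrence-accessors
#' @export
setMethod("occPoints", "OccurrenceSet", function(x) x@points)

#' @rdname occurrence-accessors
#' @export
setMethod("occSpecies", "OccurrenceSet", function(x) x@species)

setMethod("show", "RasterGrid", function(object) {
  d <- dim(object@values)
  nvalid <- sum(!is.na(object@values))
  cat("RasterGrid '", object@name, "': ", d[1L], " x ", d[2L],
      " cells, cellsize ", format(object@cellsize), "°\n", sep = "")
  cat("  origin (xll, yll): ", format(object@xll), ", ",
      format(object@yll), "; valid cells: ", nvalid, "/", prod(d),
      "\n", sep = "")
  if (nvalid) {
    r <- range(object@values, na.rm = TRUE)
    cat("  value range: [", format(r[1L]), ", ", format(r[2L]), "]\n",
        sep = "")
  }
})

setMethod("show", "EnvStack", function(object) {
  d <- gridDim(object)
  cat("EnvStack: ", length(object@layers), " layers on a ", d[1L], " x ",
      d[2L], " grid\n", sep = "")
  cat("  layers: ", paste(layerNames(object), collapse = ", "), "\n",
      sep = "")
  cat("  jointly valid cells: ", sum(validMask(object)), "/", prod(d),
      "\n", sep = "")
})

setMethod("show", "OccurrenceSet", function(object) {
  n <- nrow(object@points)
  ndup <- n - nrow(unique(object@points))
  cat("OccurrenceSet '", object@species, "': ", n, " points",
      if (ndup) paste0(" (", ndup, " duplicated coordinates)"), "\n",
      sep = "")
})

setMethod("show", "MaxentModel", function(object) {
  nz <- sum(abs(object@lambda) > 1e-12)
  cat("MaxentModel: ", length(object@lambda), " features (", nz,
      " active), ", length(object@features$vars), " variables\n", sep = "")
  cat("  entropy H = ", format(object@entropyH), ", final gain = ",
      format(utils::tail(object@gainTrajectory, 1L)), ", iterations = ",
      length(object@gainTrajectory),
      if (!object@converged) " [convergence warning]", "\n", sep = "")
})

setMethod("show", "SuitabilityClassMap", function(object) {
  cat("SuitabilityClassMap: breaks ",
      paste(format(object@breaks), collapse = " / "), "\n", sep = "")
  a <- object@areasKm2
  for (k in names(a))
    cat(sprintf("  %-8s %12.1f km2\n", k, a[[k]]))
})

setMethod("show", "Chromatogram", function(object) {
  cat("Chromatogram '", object@sampleId, "': ", length(object@time),
      " points, ", format(min(object@time)), "-", format(max(object@time)),
      " min\n", sep = "")
})

setMethod("show", "CommonPeakMatrix", function(object) {
  cat("CommonPeakMatrix: ", nrow(object@areas), " samples x ",
      ncol(object@areas), " common peaks\n", sep = "")
  if (length(object@compoundMap))
    cat("  identified: ",
        paste(names(object@compoundMap), "(peak",
              object@compoundMap, ")", collapse = ", "), "\n", sep = "")
})

setMethod("show", "CompoundPanel", function(object) {
  cat("CompoundPanel: ", nrow(object@sites), " sites x ",
      ncol(object@contents), " compounds (",
      paste(colnames(object@contents), collapse = ", "), ")\n", sep = "")
})

setMethod("show", "QualityZoningMap", function(object) {
  nsc <- sum(!is.na(object@score@values))
  cat("QualityZoningMap: ", nsc, " scored cells, ",
      length(object@breaks) + 1L, " grades\n", sep = "")
})
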