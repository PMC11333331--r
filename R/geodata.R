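#' Construct a raster grid
#'
#' @param values numeric matrix, row 1 = northernmost row; \code{NA} marks
#'   nodata cells.
#' @param name layer identifier.
#' @param xll,yll lower-left corner (decimal degrees, cell-registered).
#' @param cellsize degrees per (square) cell.
#' @param nodata on-disk nodata sentinel.
#' @return a \linkS4class{RasterGrid}.
#' @examples
#' g <- rasterGrid(matrix(1:4, 2, 2), name = "elev")
#' gridDim(g)
#' @export
rasterGrid <- function(values, name = "layer", xll = 0, yll = 0,
                       cellsize = 1, nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("RasterGrid", name = name, xll = xll, yll = yll,
      cellsize = cellsize, nodata = nodata, values = values)
}

#' Construct an environment stack from aligned layers
#'
#' @param ... \linkS4class{RasterGrid} layers, or a single list of them.
#' @return an \linkS4class{EnvStack}.
#' @export
envStack <- function(...) {
  ls <- list(...)
  if (length(ls) == 1L && is.list(ls[[1L]]) && !is(ls[[1L]], "RasterGrid"))
    ls <- ls[[1L]]
  names(ls) <- vapply(ls, function(l) l@name, character(1))
  new("EnvStack", layers = ls)
}

#' Joint validity mask of a stack
#'
#' A cell is valid only if it is observed in every layer: any layer's nodata
#' invalidates the cell, because the distribution model needs all covariates
#' at every background cell.
#'
#' @param x an \linkS4class{EnvStack} (or a single \linkS4class{RasterGrid}).
#' @return logical matrix, \code{TRUE} where all layers are observed.
#' @export
validMask <- function(x) {
  if (is(x, "RasterGrid")) return(!is.na(x@values))
  m <- !is.na(x@layers[[1L]]@values)
  for (l in x@layers[-1L]) m <- m & !is.na(l@values)
  m
}

#' Read an ESRI ASCII grid
#'
#' Parses the 6-line header (\code{ncols}, \code{nrows}, \code{xllcorner},
#' \code{yllcorner}, \code{cellsize}, \code{NODATA_value}; keys matched
#' case-insensitively) followed by \code{nrows} whitespace-separated data
#' rows, north first. The \code{xllcenter}/\code{yllcenter} dialect is
#' converted to the corner convention (\code{corner = center - cellsize/2}).
#'
#' @param path file path.
#' @param name layer identifier; defaults to the file name without extension.
#' @return a \linkS4class{RasterGrid}; nodata cells become \code{NA}.
#' @export
readEsriAscii <- function(path, name = NULL) {
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7L)
    stop("malformed ESRI ASCII grid '", path,
         "': fewer than 7 lines", call. = FALSE)
  hdr <- list()
  for (i in 1:6) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(tok) != 2L)
      stop("malformed header line ", i, ": '", lines[i], "'", call. = FALSE)
    val <- suppressWarnings(as.numeric(tok[2L]))
    if (is.na(val))
      stop("malformed header line ", i, ": non-numeric value '", tok[2L],
           "'", call. = FALSE)
    hdr[[tolower(tok[1L])]] <- val
  }
  need <- c("ncols", "nrows", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("malformed header: missing key(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  ncols <- as.integer(hdr$ncols)
  nrows <- as.integer(hdr$nrows)
  cellsize <- hdr$cellsize
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
    else if (!is.null(hdr$xllcenter)) hdr$xllcenter - cellsize / 2
    else stop("malformed header: missing xllcorner/xllcenter", call. = FALSE)
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
    else if (!is.null(hdr$yllcenter)) hdr$yllcenter - cellsize / 2
    else stop("malformed header: missing yllcorner/yllcenter", call. = FALSE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nrows)
    stop("expected ", nrows, " data rows, found ", length(body),
         call. = FALSE)
  vals <- matrix(NA_real_, nrows, ncols)
  for (r in seq_len(nrows)) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(body[r]), "\\s+")[[1L]]))
    if (length(row) != ncols || anyNA(row))
      stop("data row ", r, ": expected ", ncols, " numeric values, found ",
           length(row), call. = FALSE)
    vals[r, ] <- row
  }
  vals[vals == nodata] <- NA_real_
  rasterGrid(vals, name = name, xll = xll, yll = yll,
             cellsize = cellsize, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param grid a \linkS4class{RasterGrid}.
#' @param path output path.
#' @param decimals digits after the decimal point for data values.
#' @return the path, invisibly.
#' @export
writeEsriAscii <- function(grid, path, decimals = 6L) {
  stopifnot(is(grid, "RasterGrid"))
  v <- grid@values
  d <- dim(v)
  out <- v
  out[is.na(out)] <- grid@nodata
  fmt <- function(x) {
    s <- formatC(x, format = "f", digits = decimals)
    has.dot <- grepl(".", s, fixed = TRUE)
    s[has.dot] <- sub("\\.?0+$", "", s[has.dot])
    s
  }
  rows <- apply(out, 1L, function(r) paste(fmt(r), collapse = " "))
  hdr <- c(
    paste("ncols", d[2L]),
    paste("nrows", d[1L]),
    paste("xllcorner", format(grid@xll, scientific = FALSE)),
    paste("yllcorner", format(grid@yll, scientific = FALSE)),
    paste("cellsize", format(grid@cellsize, scientific = FALSE)),
    paste("NODATA_value", format(grid@nodata, scientific = FALSE))
  )
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(c(hdr, rows), con)
  invisible(path)
}

#' Read/write occurrence CSVs
#'
#' The MaxEnt samples dialect: a header \code{species,longitude,latitude}
#' followed by one row per record.
#'
#' @param path CSV path.
#' @return \code{readOccurrences}: an \linkS4class{OccurrenceSet}.
#' @export
readOccurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("species", "longitude", "latitude")
  if (!all(need %in% names(df)))
    stop("occurrence CSV must have columns species,longitude,latitude",
         call. = FALSE)
  new("OccurrenceSet", species = df$species[1L],
      points = cbind(lon = df$longitude, lat = df$latitude))
}

#' @rdname readOccurrences
#' @param occ an \linkS4class{OccurrenceSet}.
#' @export
writeOccurrences <- function(occ, path) {
  df <- data.frame(species = occ@species,
                   longitude = occ@points[, 1L],
                   latitude = occ@points[, 2L])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# row/col of the cell containing a point; row counted from the north
.cellIndex <- function(grid, lon, lat) {
  d <- dim(grid@values)
  col <- floor((lon - grid@xll) / grid@cellsize) + 1L
  rowS <- floor((lat - grid@yll) / grid@cellsize) + 1L  # from the south
  # points on the exact top/right edge belong to the outermost cell
  col[lon == grid@xll + d[2L] * grid@cellsize] <- d[2L]
  rowS[lat == grid@yll + d[1L] * grid@cellsize] <- d[1L]
  list(row = d[1L] + 1L - rowS, col = as.integer(col))
}

# center coordinates of cell (row from north, col)
.cellCenter <- function(grid, row, col) {
  d <- dim(grid@values)
  list(lon = grid@xll + (col - 0.5) * grid@cellsize,
       lat = grid@yll + (d[1L] - row + 0.5) * grid@cellsize)
}

#' Extract layer values at point coordinates
#'
#' \code{nearest} returns the containing cell's value; \code{bilinear}
#' interpolates the four surrounding cell centers. Rows that hit nodata are
#' flagged in the \code{incomplete} column rather than dropped.
#'
#' @param stack an \linkS4class{EnvStack}.
#' @param points two-column matrix or data.frame of lon/lat, or an
#'   \linkS4class{OccurrenceSet}.
#' @param method \code{"nearest"} or \code{"bilinear"}.
#' @return data.frame: \code{lon}, \code{lat}, one column per layer,
#'   \code{incomplete} flag.
#' @export
extractValues <- function(stack, points, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  if (is(points, "OccurrenceSet")) points <- points@points
  points <- as.matrix(points)
  ref <- stack@layers[[1L]]
  d <- dim(ref@values)
  xmax <- ref@xll + d[2L] * ref@cellsize
  ymax <- ref@yll + d[1L] * ref@cellsize
  bad <- points[, 1L] < ref@xll | points[, 1L] > xmax |
         points[, 2L] < ref@yll | points[, 2L] > ymax
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("point (%g, %g) lies outside the grid extent [%g, %g] x [%g, %g]",
                 points[i, 1L], points[i, 2L], ref@xll, xmax, ref@yll, ymax),
         call. = FALSE)
  }
  nms <- layerNames(stack)
  out <- data.frame(lon = points[, 1L], lat = points[, 2L])
  for (nm in nms) {
    layer <- getLayer(stack, nm)
    out[[nm]] <- if (method == "nearest")
      .extractNearest(layer, points) else .extractBilinear(layer, points)
  }
  out$incomplete <- rowSums(is.na(as.matrix(out[, nms, drop = FALSE]))) > 0L
  out
}

.extractNearest <- function(layer, points) {
  idx <- .cellIndex(layer, points[, 1L], points[, 2L])
  layer@values[cbind(idx$row, idx$col)]
}

.extractBilinear <- function(layer, points) {
  d <- dim(layer@values)
  cs <- layer@cellsize
  # fractional position in units of cells, measured from the first center
  fx <- (points[, 1L] - (layer@xll + cs / 2)) / cs
  fy <- (points[, 2L] - (layer@yll + cs / 2)) / cs
  x0 <- pmin(pmax(floor(fx), 0), d[2L] - 2L)
  y0 <- pmin(pmax(floor(fy), 0), d[1L] - 2L)
  if (d[2L] == 1L) x0 <- rep(0L, length(fx))
  if (d[1L] == 1L) y0 <- rep(0L, length(fy))
  tx <- pmin(pmax(fx - x0, 0), 1)
  ty <- pmin(pmax(fy - y0, 0), 1)
  rowOf <- function(ys) d[1L] - ys  # south-index -> north-count row
  v00 <- layer@values[cbind(rowOf(y0), x0 + 1L)]
  v10 <- layer@values[cbind(rowOf(y0), pmin(x0 + 2L, d[2L]))]
  v01 <- layer@values[cbind(rowOf(pmin(y0 + 1L, d[1L] - 1L)), x0 + 1L)]
  v11 <- layer@values[cbind(rowOf(pmin(y0 + 1L, d[1L] - 1L)),
                            pmin(x0 + 2L, d[2L]))]
  (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
}

#' Latitude-corrected cell area
#'
#' Area of one cell in a given row on a spherical Earth:
#' \eqn{((\pi R / 180) \cdot cellsize)^2 \cos\phi}, with \eqn{\phi} the
#' latitude of the row's cell centers and \eqn{R = 6371} km.
#'
#' @param grid a \linkS4class{RasterGrid}.
#' @param row row index (1 = northernmost), or a vector of rows.
#' @return km² per cell in each requested row.
#' @examples
#' g <- rasterGrid(matrix(0, 1, 1), yll = -0.5) # one 1-degree equatorial cell
#' cellAreaKm2(g, 1) # ~ 12364.3 km2
#' @export
cellAreaKm2 <- function(grid, row) {
  d <- dim(grid@values)
  if (any(row < 1L | row > d[1L]))
    stop("row index out of range [1, ", d[1L], "]", call. = FALSE)
  latc <- grid@yll + (d[1L] - row + 0.5) * grid@cellsize
  (pi * 6371.0 / 180 * grid@cellsize)^2 * cos(latc * pi / 180)
}

# matrix of per-cell areas for a whole grid
.areaMatrix <- function(grid) {
  d <- dim(grid@values)
  matrix(cellAreaKm2(grid, seq_len(d[1L])), d[1L], d[2L])
}
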