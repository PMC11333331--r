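#' Marker compounds used throughout
#'
#' Column order of content panels: chlorogenic acid (Ch.a), rutin (Rt),
#' hyperoside (Hyp), cynaroside (Cyn), isochlorogenic acid A (Isa A).
#' @export
markerCompounds <- c("Ch.a", "Rt", "Hyp", "Cyn", "Isa A")

#' Build a per-site compound content panel
#'
#' Either passes through a supplied contents table or quantifies a
#' common-peak matrix via \code{\link{quantifyCompounds}}. Sample ids must
#' correspond 1:1 to site ids.
#'
#' @param sites data.frame with columns \code{id}, \code{lon}, \code{lat}.
#' @param contents site-by-compound matrix of contents (mg/g), rownames =
#'   site ids; or \code{NULL} to quantify \code{peakMatrix}.
#' @param peakMatrix optional \linkS4class{CommonPeakMatrix}.
#' @param standards,sampleMassG,extractVolumeML forwarded to
#'   \code{\link{quantifyCompounds}} when quantifying.
#' @return a \linkS4class{CompoundPanel}.
#' @export
buildPanel <- function(sites, contents = NULL, peakMatrix = NULL,
                       standards = NULL, sampleMassG = 1.0,
                       extractVolumeML = 50) {
  if (is.null(contents)) {
    if (is.null(peakMatrix) || is.null(standards))
      stop("supply either contents or peakMatrix + standards",
           call. = FALSE)
    contents <- quantifyCompounds(peakMatrix, standards,
                                  sampleMassG, extractVolumeML)
  }
  contents <- as.matrix(contents)
  if (!is.null(rownames(contents))) {
    miss <- setdiff(sites$id, rownames(contents))
    if (length(miss))
      stop("site id(s) without contents: ", paste(miss, collapse = ", "),
           call. = FALSE)
    contents <- contents[as.character(sites$id), , drop = FALSE]
  } else if (nrow(contents) != nrow(sites)) {
    stop("contents rows must match sites 1:1", call. = FALSE)
  }
  known <- intersect(markerCompounds, colnames(contents))
  if (length(known))
    contents <- contents[, c(known, setdiff(colnames(contents), known)),
                         drop = FALSE]
  new("CompoundPanel", sites = sites, contents = contents)
}

#' Stepwise environment–metabolite regression
#'
#' Ordinary least squares with stepwise factor selection by AIC or BIC
#' (forward, backward or both, via \code{stats::step}): iteratively adds or
#' removes the single factor giving the best criterion improvement until no
#' move improves.
#'
#' @param panel a \linkS4class{CompoundPanel}.
#' @param envTable data.frame of ecological-factor values per site (same row
#'   order as the panel's sites).
#' @param compound compound column to model.
#' @param direction \code{"both"}, \code{"forward"} or \code{"backward"}.
#' @param criterion \code{"AIC"} or \code{"BIC"}.
#' @return list: \code{compound}, \code{factors} (selected), \code{coef}
#'   (with intercept), \code{r_squared}, \code{aic}, \code{model} (the lm
#'   fit).
#' @export
stepwiseFit <- function(panel, envTable, compound,
                        direction = c("both", "forward", "backward"),
                        criterion = c("AIC", "BIC")) {
  direction <- match.arg(direction)
  criterion <- match.arg(criterion)
  if (!compound %in% colnames(panel@contents))
    stop("unknown compound '", compound, "'", call. = FALSE)
  env <- as.data.frame(envTable)
  n <- nrow(env)
  if (n != nrow(panel@contents))
    stop("envTable rows must match the panel's sites", call. = FALSE)
  if (n <= ncol(env) + 2L)
    stop("need more sites than candidate factors + 2", call. = FALSE)
  dat <- cbind(.y = panel@contents[, compound], env)
  k <- if (criterion == "AIC") 2 else log(n)
  full <- stats::as.formula(paste(".y ~", paste(colnames(env),
                                                collapse = " + ")))
  start <- if (direction == "forward") stats::lm(.y ~ 1, data = dat)
           else stats::lm(full, data = dat)
  scope <- list(lower = .y ~ 1, upper = full)
  fit <- stats::step(start, scope = scope, direction = direction, k = k,
                     trace = 0)
  cf <- stats::coef(fit)
  list(compound = compound,
       factors = setdiff(names(cf), "(Intercept)"),
       coef = cf,
       r_squared = summary(fit)$r.squared,
       aic = stats::AIC(fit),
       model = fit)
}

#' Compound-by-factor correlation table
#'
#' Pearson r with two-sided t-test p-value per compound/factor pair;
#' significance stars at 0.05 (*) and 0.01 (**). Constant columns yield an
#' \code{NA} (flagged), never a zero.
#'
#' @param panel a \linkS4class{CompoundPanel}.
#' @param envTable data.frame of ecological-factor values per site.
#' @return data.frame \code{compound}, \code{factor}, \code{r}, \code{p},
#'   \code{stars}.
#' @export
correlationTable <- function(panel, envTable) {
  env <- as.data.frame(envTable)
  if (nrow(env) < 4L) stop("need at least 4 sites", call. = FALSE)
  rows <- list()
  for (cp in colnames(panel@contents)) for (f in colnames(env)) {
    y <- panel@contents[, cp]; x <- env[[f]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      r <- NA_real_; p <- NA_real_
    } else {
      ct <- stats::cor.test(x, y)
      r <- unname(ct$estimate); p <- ct$p.value
    }
    stars <- if (is.na(p)) "" else if (p < 0.01) "**"
             else if (p < 0.05) "*" else ""
    rows[[length(rows) + 1L]] <- data.frame(
      compound = cp, factor = f, r = r, p = p, stars = stars,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Predict a compound-content raster from a fitted quality model
#'
#' Cell-wise linear prediction \eqn{\beta \cdot x + intercept} over the
#' stack; negative predictions are floored at 0 and the flooring count
#' attached as attribute \code{flooredCells}.
#'
#' @param model a fit from \code{\link{stepwiseFit}} (or any list with
#'   \code{coef} named by factors plus \code{"(Intercept)"}).
#' @param stack an \linkS4class{EnvStack} carrying the selected factors.
#' @return a \linkS4class{RasterGrid} (mg/g).
#' @export
predictContentRaster <- function(model, stack) {
  cf <- model$coef
  fac <- setdiff(names(cf), "(Intercept)")
  miss <- setdiff(fac, layerNames(stack))
  if (length(miss))
    stop("missing layer(s): ", paste(miss, collapse = ", "), call. = FALSE)
  ref <- stack@layers[[1L]]
  mask <- validMask(stack)
  pred <- matrix(NA_real_, nrow(ref@values), ncol(ref@values))
  idx <- which(mask)
  acc <- rep(if ("(Intercept)" %in% names(cf)) cf[["(Intercept)"]] else 0,
             length(idx))
  for (f in fac) acc <- acc + cf[[f]] * getLayer(stack, f)@values[idx]
  floored <- sum(acc < 0)
  pred[idx] <- pmax(acc, 0)
  out <- rasterGrid(pred, name = paste0("content_", model$compound %||% "y"),
                    xll = ref@xll, yll = ref@yll, cellsize = ref@cellsize,
                    nodata = ref@nodata)
  attr(out, "flooredCells") <- floored
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Overlay content surfaces with suitability into a quality-zoning map
#'
#' Each content raster is min–max normalized over the masked region
#' (suitability at or above \code{maskThreshold}); the quality score is the
#' weighted mean of the normalized contents (unweighted by default), graded
#' by Jenks natural breaks. A content raster with a degenerate (constant)
#' range contributes the neutral score 0.5 by convention. Cells below the
#' masking threshold are nodata in both score and grade rasters.
#'
#' @param contentRasters named list of \linkS4class{RasterGrid} content
#'   surfaces on the suitability grid.
#' @param suitability \linkS4class{RasterGrid} of suitabilities.
#' @param maskThreshold suitability cut-off (default 0.2, i.e. above "no
#'   suitability").
#' @param kGrades number of quality grades (default 4).
#' @param weights optional named numeric weights per content raster.
#' @return a \linkS4class{QualityZoningMap}.
#' @export
overlayQualityZoning <- function(contentRasters, suitability,
                                 maskThreshold = 0.2, kGrades = 4L,
                                 weights = NULL) {
  if (!length(contentRasters))
    stop("need at least one content raster", call. = FALSE)
  mask <- binarizeSuitability(suitability, maskThreshold)
  for (cr in contentRasters) mask <- mask & !is.na(cr@values)
  idx <- which(mask)
  if (!length(idx))
    stop("masked region is empty at threshold ", maskThreshold,
         call. = FALSE)
  if (is.null(weights))
    weights <- stats::setNames(rep(1, length(contentRasters)),
                               names(contentRasters))
  w <- weights / sum(weights)
  score <- numeric(length(idx))
  degenerate <- character()
  for (i in seq_along(contentRasters)) {
    v <- contentRasters[[i]]@values[idx]
    rng <- range(v)
    norm <- if (rng[2L] > rng[1L]) (v - rng[1L]) / (rng[2L] - rng[1L])
      else { degenerate <- c(degenerate, names(contentRasters)[i])
             rep(0.5, length(v)) }
    score <- score + w[[i]] * norm
  }
  sv <- matrix(NA_real_, nrow(suitability@values), ncol(suitability@values))
  sv[idx] <- score
  scoreGrid <- rasterGrid(sv, name = "quality_score",
                          xll = suitability@xll, yll = suitability@yll,
                          cellsize = suitability@cellsize,
                          nodata = suitability@nodata)
  breaks <- if (length(unique(score)) >= kGrades)
    jenksBreaks(score, kGrades) else numeric(0)
  gv <- matrix(NA_real_, nrow(sv), ncol(sv))
  gv[idx] <- if (length(breaks)) rowSums(outer(score, breaks, ">="))
             else 0
  gradeGrid <- rasterGrid(gv, name = "quality_grade",
                          xll = suitability@xll, yll = suitability@yll,
                          cellsize = suitability@cellsize,
                          nodata = suitability@nodata)
  new("QualityZoningMap", score = scoreGrid, grades = gradeGrid,
      breaks = breaks,
      provenance = list(maskThreshold = maskThreshold, weights = w,
                        degenerate = degenerate,
                        compounds = names(contentRasters)))
}
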