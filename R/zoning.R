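#' Fisher–Jenks natural breaks
#'
#' Optimal 1-D classification into \code{k} classes minimizing the total
#' within-class sum of squared deviations, solved exactly by the Fisher
#' dynamic program over the sorted values. Returned are the \code{k - 1}
#' interior break values, each the midpoint between the last value of one
#' class and the first value of the next.
#'
#' @param values numeric vector (NAs dropped).
#' @param k number of classes (>= 2); needs at least \code{k} distinct
#'   values.
#' @param maxN if more than this many values, a deterministic
#'   evenly-spaced subsample of the sorted values is classified (the DP is
#'   O(k n²)).
#' @return numeric vector of \code{k - 1} strictly increasing breaks.
#' @examples
#' jenksBreaks(c(1, 1, 1, 9, 9, 9), 2) # single break at 5
#' @export
jenksBreaks <- function(values, k, maxN = 5000L) {
  x <- sort(values[!is.na(values)])
  if (k < 2L) stop("'k' must be at least 2", call. = FALSE)
  if (length(unique(x)) < k)
    stop("need at least k distinct values for k classes", call. = FALSE)
  if (length(x) > maxN)
    x <- x[unique(round(seq(1L, length(x), length.out = maxN)))]
  n <- length(x)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  # within-class SSD of x[i..j]
  ssd <- function(i, j) {
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }
  INF <- .Machine$double.xmax
  cost <- matrix(INF, k, n)      # cost[c, j]: best SSD for x[1..j] in c classes
  back <- matrix(0L, k, n)       # start index of the last class
  for (j in seq_len(n)) { cost[1L, j] <- ssd(1L, j); back[1L, j] <- 1L }
  for (c in 2:k) {
    for (j in c:n) {
      best <- INF; bi <- c
      for (i in c:j) {
        v <- cost[c - 1L, i - 1L] + ssd(i, j)
        if (v < best) { best <- v; bi <- i }
      }
      cost[c, j] <- best
      back[c, j] <- bi
    }
  }
  # recover class boundaries
  breaks <- numeric(k - 1L)
  j <- n
  for (c in k:2) {
    i <- back[c, j]
    breaks[c - 1L] <- (x[i - 1L] + x[i]) / 2
    j <- i - 1L
  }
  breaks
}

#' Classify a suitability raster into graded classes
#'
#' Default break values follow the printed four-grade scheme: no (0–0.2),
#' low (0.2–0.4), medium (0.4–0.6) and high (0.6–1) suitability. Intervals
#' are left-closed/right-open except the last, which includes 1, so a value
#' exactly on a break belongs to the upper class. Nodata cells are
#' preserved.
#'
#' @param suitability \linkS4class{RasterGrid} with values in [0, 1].
#' @param breaks strictly increasing interior breaks in [0, 1]; either the
#'   fixed default \code{c(0.2, 0.4, 0.6)} or output of
#'   \code{\link{jenksBreaks}}.
#' @param labels class labels, low code first.
#' @return a \linkS4class{SuitabilityClassMap} (codes 0..length(breaks)).
#' @export
classifySuitability <- function(suitability, breaks = c(0.2, 0.4, 0.6),
                                labels = c("no", "low", "medium", "high")) {
  v <- suitability@values
  fin <- v[!is.na(v)]
  if (length(fin) && (min(fin) < 0 || max(fin) > 1))
    stop("suitability values must lie in [0, 1]", call. = FALSE)
  if (length(labels) != length(breaks) + 1L)
    stop("need one label per class (breaks + 1)", call. = FALSE)
  codes <- matrix(NA_real_, nrow(v), ncol(v))
  ok <- !is.na(v)
  codes[ok] <- rowSums(outer(v[ok], breaks, ">="))
  cg <- rasterGrid(codes, name = "suitability_class",
                   xll = suitability@xll, yll = suitability@yll,
                   cellsize = suitability@cellsize,
                   nodata = suitability@nodata)
  cm <- new("SuitabilityClassMap", classes = cg, breaks = breaks,
            areasKm2 = stats::setNames(numeric(length(labels)), labels))
  cm@areasKm2 <- classAreas(cm, labels = labels)
  cm
}

#' Per-class areas in km²
#'
#' Sums latitude-corrected cell areas (\code{\link{cellAreaKm2}}) per class
#' code. Splitting a class into subclasses conserves total area; an empty
#' class reports 0.
#'
#' @param classMap a \linkS4class{SuitabilityClassMap}.
#' @param labels names for the codes, low first.
#' @return named numeric, km² per class.
#' @export
classAreas <- function(classMap,
                       labels = c("no", "low", "medium", "high")) {
  g <- classMap@classes
  A <- .areaMatrix(g)
  ncl <- length(classMap@breaks) + 1L
  if (length(labels) != ncl) labels <- paste0("class", 0:(ncl - 1L))
  out <- stats::setNames(numeric(ncl), labels)
  for (c in seq_len(ncl)) {
    sel <- !is.na(g@values) & g@values == (c - 1L)
    out[c] <- sum(A[sel])
  }
  out
}

#' Percent change in class areas between scenarios
#'
#' \eqn{(scenario - baseline)/baseline \times 100} per class; a class with
#' zero baseline area is reported as \code{NA} (undefined), never infinity.
#'
#' @param baseline,scenario named numeric km² per class (same class scheme).
#' @param digits decimals to round to in the report (default 2, matching the
#'   usual presentation).
#' @return data.frame \code{class}, \code{baseline_km2}, \code{scenario_km2},
#'   \code{percent_change}.
#' @examples
#' changeStatistics(c(high = 574879), c(high = 288333)) # -49.84 %
#' @export
changeStatistics <- function(baseline, scenario, digits = 2L) {
  if (!identical(names(baseline), names(scenario)))
    stop("baseline and scenario must use the same class scheme",
         call. = FALSE)
  pct <- ifelse(baseline == 0, NA_real_,
                (scenario - baseline) / baseline * 100)
  data.frame(class = names(baseline),
             baseline_km2 = as.numeric(baseline),
             scenario_km2 = as.numeric(scenario),
             percent_change = round(pct, digits),
             row.names = NULL)
}
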