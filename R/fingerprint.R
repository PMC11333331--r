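#' Construct a chromatogram
#'
#' @param time retention times in minutes, strictly increasing.
#' @param signal detector response, same length.
#' @param sampleId sample identifier.
#' @param meta acquisition metadata list (e.g. \code{wavelength_nm = 245},
#'   \code{column_temp_C = 38}, \code{flow_mL_min = 1},
#'   \code{injection_uL = 10}, gradient program).
#' @return a \linkS4class{Chromatogram}.
#' @export
chromatogram <- function(time, signal, sampleId = "sample",
                         meta = list()) {
  new("Chromatogram", sampleId = sampleId, time = as.numeric(time),
      signal = as.numeric(signal), meta = meta)
}

#' Read/write chromatogram CSV (time_min, signal)
#'
#' @param path CSV path.
#' @param sampleId identifier; defaults to the file name.
#' @export
readChromatogram <- function(path, sampleId = NULL) {
  if (is.null(sampleId)) sampleId <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path)
  chromatogram(df[[1L]], df[[2L]], sampleId = sampleId)
}

#' @rdname readChromatogram
#' @param chrom a \linkS4class{Chromatogram}.
#' @export
writeChromatogram <- function(chrom, path) {
  utils::write.csv(data.frame(time_min = chrom@time, signal = chrom@signal),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# trapezoidal integral
.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)

#' Detect chromatographic peaks
#'
#' Local maxima above a height threshold whose prominence (apex height above
#' the higher of the two flanking valleys) exceeds the prominence threshold.
#' Peak bounds sit at the flanking valleys; the area is the trapezoidal
#' integral of the signal minus the straight baseline drawn between the
#' bounds.
#'
#' @param chrom a \linkS4class{Chromatogram}.
#' @param minHeight minimum apex signal.
#' @param minProminence minimum apex height above the flanking valleys.
#' @return a peak table: data.frame \code{rt}, \code{height}, \code{area},
#'   \code{left}, \code{right} sorted by retention time, with the sample id
#'   as attribute \code{sampleId}.
#' @export
detectPeaks <- function(chrom, minHeight, minProminence) {
  if (minHeight <= 0 || minProminence <= 0)
    stop("thresholds must be positive", call. = FALSE)
  y <- chrom@signal
  x <- chrom@time
  n <- length(y)
  if (n < 3L) stop("signal too short for peak detection", call. = FALSE)
  apex <- which(diff(sign(diff(y))) < 0) + 1L
  apex <- apex[y[apex] >= minHeight]
  peaks <- list()
  for (a in apex) {
    l <- a
    while (l > 1L && y[l - 1L] <= y[l]) l <- l - 1L
    r <- a
    while (r < n && y[r + 1L] <= y[r]) r <- r + 1L
    prom <- y[a] - max(y[l], y[r])
    if (prom < minProminence) next
    seg <- l:r
    base <- y[l] + (y[r] - y[l]) * (x[seg] - x[l]) / (x[r] - x[l])
    area <- .trapz(x[seg], pmax(y[seg] - base, 0))
    if (area <= 0) next
    peaks[[length(peaks) + 1L]] <- data.frame(
      rt = x[a], height = y[a], area = area, left = x[l], right = x[r])
  }
  out <- if (length(peaks)) do.call(rbind, peaks)
    else data.frame(rt = numeric(), height = numeric(), area = numeric(),
                    left = numeric(), right = numeric())
  out <- out[order(out$rt), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sampleId") <- chrom@sampleId
  out
}

# greedy one-to-one matching of sample peaks to reference peaks by RT
# proximity; returns index into sample peaks per reference peak (NA if none)
.matchPeaks <- function(refRT, rt, tol) {
  cand <- expand.grid(i = seq_along(refRT), j = seq_along(rt))
  cand$d <- abs(refRT[cand$i] - rt[cand$j])
  cand <- cand[cand$d <= tol, , drop = FALSE]
  cand <- cand[order(cand$d), , drop = FALSE]
  m <- rep(NA_integer_, length(refRT))
  usedJ <- logical(length(rt))
  for (k in seq_len(nrow(cand))) {
    i <- cand$i[k]; j <- cand$j[k]
    if (is.na(m[i]) && !usedJ[j]) { m[i] <- j; usedJ[j] <- TRUE }
  }
  m
}

#' Align peak tables and extract the common-peak matrix
#'
#' Retention-time correction and matching: anchor peaks in each sample are
#' matched greedily (nearest within tolerance) to the reference sample's
#' peaks, a piecewise-linear time correction maps each sample onto the
#' reference scale, and corrected peaks within tolerance of a reference
#' peak form one column. Only columns occupied in every sample are kept —
#' the common peaks. Areas are never altered by the correction.
#'
#' @param peakTables list of peak tables from \code{\link{detectPeaks}},
#'   named by sample.
#' @param referenceSample name (or index) of the reference sample.
#' @param rtTolerance matching tolerance in minutes.
#' @param anchors optional retention times (on the reference scale) of the
#'   anchor peaks used for the piecewise-linear correction, typically the
#'   identified marker-compound peaks; defaults to all matched peaks.
#' @return a \linkS4class{CommonPeakMatrix}.
#' @export
alignPeakTables <- function(peakTables, referenceSample = 1L,
                            rtTolerance = 0.2, anchors = NULL) {
  if (length(peakTables) < 2L)
    stop("need at least 2 samples to align", call. = FALSE)
  if (is.null(names(peakTables)))
    names(peakTables) <- paste0("S", seq_along(peakTables))
  refName <- if (is.character(referenceSample)) referenceSample
    else names(peakTables)[referenceSample]
  ref <- peakTables[[refName]]
  refRT <- ref$rt
  nsamp <- length(peakTables)
  A <- matrix(NA_real_, nsamp, length(refRT),
              dimnames = list(names(peakTables), NULL))
  for (s in names(peakTables)) {
    pt <- peakTables[[s]]
    if (!nrow(pt))
      stop("sample '", s, "' has no matchable peaks", call. = FALSE)
    m0 <- .matchPeaks(refRT, pt$rt, rtTolerance)
    aRef <- refRT[!is.na(m0)]
    aSmp <- pt$rt[m0[!is.na(m0)]]
    if (!is.null(anchors)) {
      keep <- vapply(aRef, function(r) any(abs(anchors - r) <= rtTolerance),
                     logical(1))
      if (any(keep)) { aRef <- aRef[keep]; aSmp <- aSmp[keep] }
    }
    if (!length(aRef))
      stop("sample '", s, "' has no matchable anchor peaks within tolerance",
           call. = FALSE)
    corrected <- if (length(aRef) >= 2L) {
      o <- order(aSmp)
      stats::approx(aSmp[o], aRef[o], xout = pt$rt, rule = 2)$y
    } else pt$rt + (aRef - aSmp)      # single anchor: constant shift
    m <- .matchPeaks(refRT, corrected, rtTolerance)
    ok <- !is.na(m)
    A[s, ok] <- pt$area[m[ok]]
  }
  common <- colSums(is.na(A)) == 0L
  if (!any(common))
    stop("no peaks are common to all samples", call. = FALSE)
  areas <- A[, common, drop = FALSE]
  colnames(areas) <- paste0("P", seq_len(ncol(areas)))
  new("CommonPeakMatrix", areas = areas, peakRT = refRT[common],
      compoundMap = integer())
}

#' Assign identified compounds to common-peak columns
#'
#' @param matrix a \linkS4class{CommonPeakMatrix}.
#' @param compounds named numeric of reference retention times per compound
#'   (e.g. the five markers Ch.a, Rt, Hyp, Cyn, Isa A).
#' @param rtTolerance matching tolerance in minutes.
#' @return the matrix with \code{compoundMap} filled.
#' @export
identifyCompounds <- function(matrix, compounds, rtTolerance = 0.2) {
  m <- .matchPeaks(compounds, matrix@peakRT, rtTolerance)
  if (anyNA(m))
    stop("compound(s) not found among common peaks: ",
         paste(names(compounds)[is.na(m)], collapse = ", "), call. = FALSE)
  matrix@compoundMap <- stats::setNames(as.integer(m), names(compounds))
  validObject(matrix)
  matrix
}

#' Reference fingerprint of the common-peak matrix
#'
#' @param matrix a \linkS4class{CommonPeakMatrix}.
#' @param method \code{"median"} (default) or \code{"mean"} per column.
#' @return numeric area vector, one entry per common peak.
#' @export
referenceFingerprint <- function(matrix, method = c("median", "mean")) {
  method <- match.arg(method)
  apply(matrix@areas, 2L, if (method == "median") stats::median else mean)
}

#' Congruence (cosine) similarity between fingerprints
#'
#' The congruence coefficient \eqn{a \cdot b / (\|a\| \|b\|)} between two
#' peak-area vectors — scale-invariant, 1 for identical profiles. A
#' correlation-coefficient mode (Pearson r of the two vectors) is available
#' as the usual alternative.
#'
#' @param a,b equal-length nonzero area vectors.
#' @param method \code{"congruence"} (default) or \code{"correlation"}.
#' @return similarity value (in [0, 1] for nonnegative vectors under
#'   congruence).
#' @examples
#' congruenceSimilarity(c(1, 2, 2), c(2, 1, 2)) # 8/9
#' @export
congruenceSimilarity <- function(a, b,
                                 method = c("congruence", "correlation")) {
  method <- match.arg(method)
  if (length(a) != length(b))
    stop("vectors must have equal length", call. = FALSE)
  if (method == "correlation") return(stats::cor(a, b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("similarity undefined for a zero vector", call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Sample-by-sample similarity matrix
#'
#' Pairwise congruence similarities between all samples of a common-peak
#' matrix plus the reference fingerprint (appended as column/row \code{C}),
#' mirroring the usual fingerprint-report layout: symmetric, unit diagonal.
#'
#' @param matrix a \linkS4class{CommonPeakMatrix}.
#' @param reference optional reference fingerprint vector; default
#'   \code{\link{referenceFingerprint}} (median).
#' @param method forwarded to \code{\link{congruenceSimilarity}}.
#' @return numeric matrix with sample names plus \code{"C"}.
#' @export
similarityMatrix <- function(matrix, reference = NULL,
                             method = c("congruence", "correlation")) {
  method <- match.arg(method)
  if (is.null(reference)) reference <- referenceFingerprint(matrix)
  M <- rbind(matrix@areas, C = reference)
  n <- nrow(M)
  S <- diag(1, n)
  dimnames(S) <- list(rownames(M), rownames(M))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    S[i, j] <- S[j, i] <- congruenceSimilarity(M[i, ], M[j, ],
                                               method = method)
  S
}

#' Relative standard deviation in percent
#'
#' Sample (n-1) standard deviation over the mean, times 100 — the
#' method-validation statistic for precision, repeatability and stability
#' series.
#'
#' @param values numeric vector, length >= 2, nonzero mean.
#' @return RSD in percent.
#' @export
rsdPercent <- function(values) {
  if (length(values) < 2L)
    stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("RSD undefined for zero mean", call. = FALSE)
  stats::sd(values) / m * 100
}

#' One-point external-standard quantification
#'
#' Content (mg/g) per sample and compound:
#' \deqn{content = \frac{area_{sample}}{area_{std}} \cdot conc_{std}
#'       \cdot \frac{volume}{mass}}
#' using the extraction defaults of 1.0 g powder in 50 mL solvent.
#'
#' @param matrix a \linkS4class{CommonPeakMatrix} with its
#'   \code{compoundMap} filled (see \code{\link{identifyCompounds}}).
#' @param standards named list, per compound: \code{c(area, concentration)}
#'   with concentration in mg/mL.
#' @param sampleMassG sample mass in g.
#' @param extractVolumeML extract volume in mL.
#' @return matrix samples x compounds of contents in mg/g.
#' @export
quantifyCompounds <- function(matrix, standards, sampleMassG = 1.0,
                              extractVolumeML = 50) {
  cm <- matrix@compoundMap
  miss <- setdiff(names(standards), names(cm))
  if (length(miss))
    stop("compound(s) not mapped to a common peak: ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- vapply(names(standards), function(cp) {
    st <- standards[[cp]]
    matrix@areas[, cm[[cp]]] / st[[1]] * st[[2]] *
      extractVolumeML / sampleMassG
  }, numeric(nrow(matrix@areas)))
  if (is.null(dim(out)))
    out <- t(out)
  rownames(out) <- rownames(matrix@areas)
  out
}
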