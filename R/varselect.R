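#' Pairwise Pearson correlation of environmental variables
#'
#' Computes the Pearson correlation matrix over pairwise-complete rows of a
#' samples-by-variables table (e.g. values sampled from raster cells or
#' extracted at occurrence points). A constant variable has no defined
#' correlation; its entries are reported as \code{NA} with a warning, never
#' coerced to 0.
#'
#' @param samples data.frame or matrix, one column per variable.
#' @return list of class \code{CorrelationMatrix}: \code{names}, \code{r}
#'   (symmetric, unit diagonal), \code{n_used} (jointly valid rows per pair).
#' @export
pairwiseCorrelation <- function(samples) {
  x <- as.matrix(samples)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("v", seq_len(ncol(x)))
  p <- ncol(x)
  sds <- apply(x, 2L, stats::sd, na.rm = TRUE)
  const <- !is.na(sds) & sds == 0
  if (any(const))
    warning("constant variable(s) with undefined correlation: ",
            paste(colnames(x)[const], collapse = ", "), call. = FALSE)
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  diag(r) <- 1
  ok <- !is.na(x)
  nUsed <- crossprod(ok)
  if (any(nUsed[upper.tri(nUsed)] < 3L))
    warning("some pairs have fewer than 3 jointly valid rows", call. = FALSE)
  structure(list(names = colnames(x), r = r, n_used = nUsed),
            class = "CorrelationMatrix")
}

#' Screen collinear variables, retaining the higher-contribution member
#'
#' Greedy screening: iterate variables in descending contribution (ties
#' broken by name order) and keep a variable only if its absolute correlation
#' with every already-kept variable is below the threshold. Each dropped
#' variable is logged against the kept variable that excluded it.
#'
#' @param corr a \code{CorrelationMatrix} from \code{\link{pairwiseCorrelation}}.
#' @param contributions named numeric, percent contribution per variable
#'   (from a preliminary all-variable model fit).
#' @param threshold absolute-correlation cutoff in (0, 1]; default 0.8.
#' @return list: \code{retained} (character vector) and \code{dropLog}
#'   (data.frame \code{dropped}, \code{kept_by}, \code{r},
#'   \code{contribution}).
#' @export
selectUncorrelated <- function(corr, contributions, threshold = 0.8) {
  stopifnot(inherits(corr, "CorrelationMatrix"))
  if (!(threshold > 0 && threshold <= 1))
    stop("threshold must lie in (0, 1]", call. = FALSE)
  vars <- corr$names
  miss <- setdiff(vars, names(contributions))
  if (length(miss))
    stop("missing contribution for variable(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  contr <- contributions[vars]
  ord <- vars[order(-contr, vars)]
  kept <- character()
  log <- data.frame(dropped = character(), kept_by = character(),
                    r = numeric(), contribution = numeric(),
                    stringsAsFactors = FALSE)
  for (v in ord) {
    rv <- abs(corr$r[v, kept])
    hit <- which(!is.na(rv) & rv >= threshold)
    if (length(hit)) {
      by <- kept[hit[which.max(rv[hit])]]
      log <- rbind(log, data.frame(dropped = v, kept_by = by,
                                   r = corr$r[v, by],
                                   contribution = contr[[v]],
                                   stringsAsFactors = FALSE))
    } else {
      kept <- c(kept, v)
    }
  }
  list(retained = kept, dropLog = log)
}

#' Sample jointly valid cells from a stack into a variables table
#'
#' Used to feed \code{\link{pairwiseCorrelation}}: draws up to \code{n}
#' jointly valid cells (seeded, without replacement) and returns their layer
#' values.
#'
#' @param stack an \linkS4class{EnvStack}.
#' @param n maximum cells to sample.
#' @param seed integer seed.
#' @return data.frame, one column per layer.
#' @export
sampleCellValues <- function(stack, n = 10000L, seed = 1L) {
  m <- validMask(stack)
  idx <- which(m)
  if (!length(idx)) stop("stack has no jointly valid cells", call. = FALSE)
  if (length(idx) > n)
    idx <- sort(idx[.withSeed(seed, sample.int(length(idx), n))])
  out <- lapply(stack@layers, function(l) l@values[idx])
  as.data.frame(out)
}
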