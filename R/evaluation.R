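#' Area under the ROC curve (Mann–Whitney estimate)
#'
#' Pair-counting AUC: the fraction of (positive, negative) score pairs in
#' which the positive outscores the negative, ties counted one half.
#' Computed via midranks, which is exactly the exhaustive pair count.
#'
#' @param pos scores of positive (presence) cases.
#' @param neg scores of negative (background/absence) cases.
#' @return a value in [0, 1].
#' @examples
#' aucScore(c(0.9, 0.8), c(0.7, 0.85)) # 3 wins of 4 pairs = 0.75
#' @export
aucScore <- function(pos, neg) {
  if (!length(pos) || !length(neg))
    stop("both score sets must be non-empty", call. = FALSE)
  np <- length(pos)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(neg))
}

#' Per-variable percent contributions
#'
#' Training-gain increments accumulated during the fit are attributed to the
#' variables behind the updated features (product features split evenly
#' between their two variables) and normalized to sum to 100.
#'
#' @param model a \linkS4class{MaxentModel} with a gain trajectory.
#' @return named numeric, percent per variable (sums to 100).
#' @export
variableContributions <- function(model) {
  if (!length(model@gainTrajectory))
    stop("model carries no gain trajectory", call. = FALSE)
  vg <- pmax(model@varGain, 0)
  if (sum(vg) == 0) return(vg * 0)
  100 * vg / sum(vg)
}

#' Permutation importance of each variable
#'
#' For each variable, its values are permuted jointly across presence and
#' background rows, the training AUC is recomputed from the (unrefitted)
#' model, and the drop in AUC is normalized across variables to sum to 100.
#' One permutation per variable by default; more give steadier estimates.
#'
#' @param model a \linkS4class{MaxentModel} (must retain its training data).
#' @param seed integer seed.
#' @param reps permutations per variable.
#' @return named numeric, percent per variable (sums to 100).
#' @export
permutationImportance <- function(model, seed = 1L, reps = 1L) {
  P <- model@presenceX
  B <- model@backgroundX
  if (!nrow(P))
    stop("model does not retain training data", call. = FALSE)
  vars <- model@features$vars
  full <- aucScore(predictRaw(model, P), predictRaw(model, B))
  m <- nrow(P)
  drops <- stats::setNames(numeric(length(vars)), vars)
  for (vi in seq_along(vars)) {
    v <- vars[vi]
    d <- 0
    for (r in seq_len(reps)) {
      XP <- P; XB <- B
      comb <- c(XP[, v], XB[, v])
      perm <- .withSeed(.childSeed(seed, (vi - 1L) * reps + r),
                        sample(comb))
      XP[, v] <- perm[seq_len(m)]
      XB[, v] <- perm[-seq_len(m)]
      d <- d + (full - aucScore(predictRaw(model, XP),
                                predictRaw(model, XB)))
    }
    drops[v] <- max(d / reps, 0)
  }
  if (sum(drops) == 0) return(drops)
  100 * drops / sum(drops)
}

# regularized-gain-style training gain of a fitted model:
# mean log q over presences relative to a uniform background
.trainingGain <- function(model) {
  q <- predictRaw(model, model@presenceX)
  mean(log(pmax(q, 1e-300))) + log(model@nNorm)
}

#' Jackknife variable-importance gains
#'
#' Fits, for every variable, a model with only that variable and a model
#' with all the others, plus the full model, and reports each training gain
#' (mean presence log-probability relative to a uniform background). A
#' variable whose with-only gain is high carries much usable information; a
#' large drop in the without-gain marks information held by no other
#' variable.
#'
#' @param occ an \linkS4class{OccurrenceSet} (or a presence covariate
#'   matrix).
#' @param stack an \linkS4class{EnvStack}.
#' @param nBackground background points.
#' @param seed integer seed for the shared background sample.
#' @param config fit settings forwarded to \code{\link{fitMaxent}}.
#' @return list: \code{table} (data.frame variable, gain_only,
#'   gain_without), \code{gain_full}, \code{errors} (per-variable fit
#'   failures, fitting continues past them).
#' @export
jackknifeGains <- function(occ, stack, nBackground = 10000L, seed = 1L,
                           config = list()) {
  vars <- layerNames(stack)
  if (length(vars) < 2L)
    stop("jackknife needs at least 2 variables", call. = FALSE)
  if (is(occ, "OccurrenceSet")) {
    ev <- extractValues(stack, occPoints(occ), method = "nearest")
    X <- as.matrix(ev[!ev$incomplete, vars, drop = FALSE])
  } else X <- as.matrix(occ)
  bg <- sampleBackground(stack, n = nBackground, seed = seed)
  fitGain <- function(cols) {
    fit <- fitMaxent(X[, cols, drop = FALSE],
                     bg$X[, cols, drop = FALSE], config)
    .trainingGain(fit)
  }
  errors <- list()
  gFull <- fitGain(vars)
  gOnly <- gWithout <- stats::setNames(rep(NA_real_, length(vars)), vars)
  for (v in vars) {
    gOnly[v] <- tryCatch(fitGain(v), error = function(e) {
      errors[[v]] <<- conditionMessage(e); NA_real_ })
    gWithout[v] <- tryCatch(fitGain(setdiff(vars, v)), error = function(e) {
      errors[[v]] <<- conditionMessage(e); NA_real_ })
  }
  list(table = data.frame(variable = vars, gain_only = gOnly,
                          gain_without = gWithout, row.names = NULL),
       gain_full = gFull, errors = errors)
}

#' Marginal response curve of one variable
#'
#' Varies the target variable across its observed range while holding every
#' other variable at its background mean, and reports the logistic output —
#' the standard single-variable response plot. The first and last values at
#' which the curve exceeds \code{threshold} are returned as an attribute
#' (\code{NA} if never exceeded).
#'
#' @param model a \linkS4class{MaxentModel} retaining its background rows.
#' @param variable variable name.
#' @param nPoints grid points along the range.
#' @param threshold presence-probability threshold reported alongside the
#'   curve (default 0.55).
#' @return data.frame \code{value}, \code{p}, with attribute
#'   \code{thresholdRange = c(first, last)}.
#' @export
responseCurve <- function(model, variable, nPoints = 100L,
                          threshold = 0.55) {
  vars <- model@features$vars
  if (!variable %in% vars)
    stop("unknown variable '", variable, "'", call. = FALSE)
  if (!nrow(model@backgroundX))
    stop("model does not retain background data", call. = FALSE)
  rng <- model@features$range[, variable]
  xs <- seq(rng[1L], rng[2L], length.out = nPoints)
  mu <- colMeans(model@backgroundX[, vars, drop = FALSE])
  X <- matrix(rep(mu, each = nPoints), nPoints, length(vars),
              dimnames = list(NULL, vars))
  X[, variable] <- xs
  p <- predictLogistic(model, X)
  out <- data.frame(value = xs, p = p)
  above <- which(p > threshold)
  attr(out, "thresholdRange") <- if (length(above))
    c(xs[above[1L]], xs[above[length(above)]]) else c(NA_real_, NA_real_)
  out
}

#' Full evaluation report
#'
#' @param model a \linkS4class{MaxentModel}.
#' @param testX optional held-out presence covariate rows for test AUC.
#' @param seed seed for permutation importance.
#' @return list with \code{auc_train}, \code{auc_test}, \code{contributions},
#'   \code{permutation_importance}.
#' @export
evaluationReport <- function(model, testX = NULL, seed = 1L) {
  sBg <- predictRaw(model, model@backgroundX)
  rep <- list(
    auc_train = aucScore(predictRaw(model, model@presenceX), sBg),
    auc_test = if (!is.null(testX))
      aucScore(predictRaw(model, as.matrix(testX)), sBg) else NA_real_,
    contributions = variableContributions(model),
    permutation_importance = permutationImportance(model, seed = seed)
  )
  class(rep) <- "EvaluationReport"
  rep
}
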