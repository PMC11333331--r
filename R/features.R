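#' Build the MaxEnt feature expansion
#'
#' Expands raw covariates into the canonical MaxEnt feature classes — linear,
#' quadratic, pairwise product, and forward/reverse hinge on a fixed knot
#' grid — each scaled so that its values lie in [0, 1] on the training data.
#' Knots are placed strictly inside each variable's observed range.
#' Threshold features are deliberately omitted: hinge features subsume their
#' role.
#'
#' @param X numeric matrix of training covariates (presence + background),
#'   with column names.
#' @param classes subset of \code{c("linear", "quadratic", "product",
#'   "hinge")}.
#' @param nKnots hinge knots per variable (forward and reverse each get this
#'   many).
#' @return a feature set: list with \code{vars} (per-variable observed
#'   min/max) and \code{table} (one row per feature: \code{type},
#'   \code{var1}, \code{var2}, \code{knot}, \code{fmin}, \code{fmax}).
#' @export
buildFeatureSet <- function(X,
                            classes = c("linear", "quadratic", "product",
                                        "hinge"),
                            nKnots = 50L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("covariates must be named", call. = FALSE)
  classes <- match.arg(classes, several.ok = TRUE)
  if (any(!is.finite(X)))
    stop("non-finite covariate values in feature-building data",
         call. = FALSE)
  vmin <- apply(X, 2L, min)
  vmax <- apply(X, 2L, max)
  keep <- vmax > vmin
  if (!all(keep))
    warning("constant variable(s) excluded from features: ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
  vars <- colnames(X)[keep]
  if (!length(vars)) stop("no usable (non-constant) variables", call. = FALSE)
  rows <- list()
  add <- function(type, v1, v2 = NA_character_, knot = NA_real_,
                  fmin = 0, fmax = 1)
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, var1 = v1, var2 = v2, knot = knot,
      fmin = fmin, fmax = fmax, stringsAsFactors = FALSE)
  for (v in vars) {
    x <- X[, v]
    if ("linear" %in% classes)
      add("linear", v, fmin = vmin[v], fmax = vmax[v])
    if ("quadratic" %in% classes)
      add("quadratic", v, fmin = min(x^2), fmax = max(x^2))
    if ("hinge" %in% classes && nKnots > 0L) {
      knots <- vmin[v] + (vmax[v] - vmin[v]) *
        seq_len(nKnots) / (nKnots + 1)
      for (k in knots) {
        add("hinge_f", v, knot = k, fmin = k, fmax = vmax[v])
        add("hinge_r", v, knot = k, fmin = vmin[v], fmax = k)
      }
    }
  }
  if ("product" %in% classes && length(vars) >= 2L) {
    for (i in seq_len(length(vars) - 1L)) for (j in (i + 1L):length(vars)) {
      pr <- X[, vars[i]] * X[, vars[j]]
      add("product", vars[i], vars[j], fmin = min(pr), fmax = max(pr))
    }
  }
  tab <- do.call(rbind, rows)
  tab$fmax <- ifelse(tab$fmax > tab$fmin, tab$fmax, tab$fmin + 1)
  varRange <- rbind(min = vmin[vars], max = vmax[vars])
  list(vars = vars, range = varRange, table = tab)
}

#' Evaluate the feature matrix for covariate rows
#'
#' Values are guaranteed to lie in [0, 1] on the data the set was built from;
#' off-range rows extrapolate linearly (hinges saturate by construction).
#'
#' @param fs a feature set from \code{\link{buildFeatureSet}}.
#' @param X numeric matrix with (at least) the set's variables as columns.
#' @return numeric matrix, rows of \code{X} by features.
#' @export
featureMatrix <- function(fs, X) {
  X <- as.matrix(X)
  miss <- setdiff(fs$vars, colnames(X))
  if (length(miss))
    stop("missing variable(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab <- fs$table
  n <- nrow(X)
  F <- matrix(0, n, nrow(tab))
  for (j in seq_len(nrow(tab))) {
    t <- tab$type[j]
    x1 <- X[, tab$var1[j]]
    raw <- switch(t,
      linear = x1,
      quadratic = x1^2,
      product = x1 * X[, tab$var2[j]],
      hinge_f = pmax(0, x1 - tab$knot[j]),
      hinge_r = pmax(0, tab$knot[j] - x1)
    )
    den <- tab$fmax[j] - tab$fmin[j]
    F[, j] <- switch(t,
      hinge_f = pmin(raw / den, 1),
      hinge_r = pmin(raw / den, 1),
      (raw - tab$fmin[j]) / den
    )
  }
  F
}

# map each feature to its variable weight vector: a J x V matrix of shares
# (products split evenly between their two variables)
.featureVarShares <- function(fs) {
  tab <- fs$table
  V <- fs$vars
  S <- matrix(0, nrow(tab), length(V), dimnames = list(NULL, V))
  for (j in seq_len(nrow(tab))) {
    if (tab$type[j] == "product") {
      S[j, tab$var1[j]] <- 0.5
      S[j, tab$var2[j]] <- 0.5
    } else {
      S[j, tab$var1[j]] <- 1
    }
  }
  S
}

# canonical per-class regularization amounts, interpolated by presence count
.betaClass <- function(type, m) {
  if (type %in% c("hinge_f", "hinge_r")) return(0.5)
  # linear/quadratic/product class schedule
  stats::approx(x = c(10, 30, 100), y = c(1.0, 0.2, 0.05),
                xout = m, rule = 2)$y
}
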