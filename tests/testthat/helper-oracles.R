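# Independent oracles and tiny fixture builders used across the suite.

# exhaustive pair-counting AUC, ties counted one half
aucPairOracle <- function(pos, neg) {
  wins <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(wins)
}

# exhaustive Fisher-Jenks: minimal total within-class SSD over all ordered
# partitions of the sorted values into k non-empty classes
jenksBruteForceSSD <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  cuts <- utils::combn(n - 1L, k - 1L)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    b <- c(0L, cuts[, j], n)
    tot <- 0
    for (c in seq_len(k)) tot <- tot + ssd(x[(b[c] + 1L):b[c + 1L]])
    best <- min(best, tot)
  }
  best
}

# total within-class SSD of values classified by interior break values
classifiedSSD <- function(values, breaks) {
  x <- sort(values)
  cls <- rowSums(outer(x, breaks, ">="))
  sum(vapply(split(x, cls), function(v) sum((v - mean(v))^2), numeric(1)))
}

# independent trapezoid rule for integrals
.trapzOracle <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

# tiny aligned two-layer stack with known values
tinyStack <- function() {
  a <- rasterGrid(matrix(c(1, 3, 2, 4), 2, 2), name = "a",
                  xll = 0, yll = 0, cellsize = 1)
  b <- rasterGrid(matrix(c(10, 30, 20, 40), 2, 2), name = "b",
                  xll = 0, yll = 0, cellsize = 1)
  envStack(list(a, b))
}

# binary-covariate presence/background with a known moment condition
binaryFeatureData <- function(presMean = 0.8, bgMean = 0.5, n = 200L) {
  list(
    P = matrix(rep(c(0, 1), round(c(1 - presMean, presMean) * n)),
               ncol = 1, dimnames = list(NULL, "x")),
    B = matrix(rep(c(0, 1), round(c(1 - bgMean, bgMean) * n)),
               ncol = 1, dimnames = list(NULL, "x"))
  )
}

# the standard small synthetic scene used by recovery experiments
recoveryScene <- function(seed = 7L, nrows = 64L, ncols = 64L) {
  st <- makeEnvStack(k = 5, nrows = nrows, ncols = ncols, seed = seed,
                     names = c("bio4", "bio6", "bio12", "elev", "srad2"))
  occ <- simulateOccurrences(st, trueBeta = c(bio6 = 3, bio12 = 1.2),
                             intercept = -6, n = 298L, seed = 42L)
  list(stack = st, occ = occ)
}
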