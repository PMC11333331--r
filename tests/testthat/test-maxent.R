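test_that("background sampling is exhaustive, seeded and reproducible", {
  st <- tinyStack()
  expect_warning(bg <- sampleBackground(st, n = 10L, seed = 1),
                 "taking all")
  expect_equal(bg$n, 4L)
  expect_equal(sort(bg$X[, "a"]), 1:4 + 0)  # every cell exactly once
  big <- makeEnvStack(k = 1, nrows = 20, ncols = 20, seed = 3)
  b1 <- sampleBackground(big, n = 100L, seed = 9)
  b2 <- sampleBackground(big, n = 100L, seed = 9)
  expect_identical(b1$X, b2$X)
  b3 <- sampleBackground(big, n = 400L, seed = 9)
  expect_equal(nrow(unique(b3$points)), 400L)  # without replacement
})

test_that("no signal gives near-zero weights and a uniform distribution", {
  set.seed(4)
  x <- rnorm(300)
  P <- matrix(sample(x, 100), ncol = 1, dimnames = list(NULL, "x"))
  B <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  fit <- fitMaxent(P, B, list(classes = "linear", nKnots = 0))
  q <- predictRaw(fit, B)
  expect_lt(diff(range(q)) / mean(q), 0.5)
  expect_equal(sum(predictRaw(fit, rbind(B, P))), 1, tolerance = 1e-9)
})

test_that("a single-feature unregularized fit matches the brute-force oracle", {
  d <- binaryFeatureData()
  fit <- fitMaxent(d$P, d$B,
                   list(classes = "linear", nKnots = 0, regMultiplier = 0,
                        tol = 0, maxIter = 5000L, addSamples = FALSE))
  xb <- d$B[, 1]; xp <- d$P[, 1]
  oracle <- optimize(function(l) -(mean(l * xp) - log(mean(exp(l * xb)))),
                     c(-10, 10), tol = 1e-12)$minimum
  expect_equal(fit@lambda, oracle, tolerance = 1e-6)
  # moment condition: fitted expectation matches the presence mean
  q <- predictRaw(fit, d$B)
  expect_equal(sum(q * xb), mean(xp), tolerance = 1e-5)
})

test_that("background probabilities are normalized after every fit", {
  for (seed in 1:3) {
    set.seed(seed)
    P <- cbind(a = rnorm(40, 1), b = rnorm(40))
    B <- cbind(a = rnorm(300), b = rnorm(300))
    fit <- fitMaxent(P, B, list(nKnots = 8))
    expect_equal(sum(predictRaw(fit, rbind(B, P))), 1, tolerance = 1e-9)
    expect_true(all(diff(fit@gainTrajectory) > -1e-8))
  }
})

test_that("heavy regularization shrinks all weights and the gain to zero", {
  set.seed(2)
  P <- cbind(x = rnorm(50, 2))
  B <- cbind(x = rnorm(400))
  fit <- fitMaxent(P, B, list(nKnots = 5, regMultiplier = 1e6))
  expect_true(all(abs(fit@lambda) < 1e-8))
  expect_lt(abs(tail(fit@gainTrajectory, 1)), 1e-6)
})

test_that("the logistic transform follows the entropy closed form", {
  d <- binaryFeatureData()
  fit <- fitMaxent(d$P, d$B, list(classes = "linear", nKnots = 0))
  # uniform scores: q = 1/N, H = ln N  =>  p = 0.5
  uni <- fitMaxent(matrix(rep(c(0, 1), 50), ncol = 1,
                          dimnames = list(NULL, "x")),
                   matrix(rep(c(0, 1), 200), ncol = 1,
                          dimnames = list(NULL, "x")),
                   list(classes = "linear", nKnots = 0))
  pU <- predictLogistic(uni, uni@backgroundX)
  expect_equal(unname(pU), rep(0.5, length(pU)), tolerance = 1e-3)
  # hand evaluation of p = e^H q / (1 + e^H q)
  q <- predictRaw(fit, d$B)
  pHand <- exp(fit@entropyH) * q / (1 + exp(fit@entropyH) * q)
  expect_equal(predictLogistic(fit, d$B), pHand, tolerance = 1e-12)
  # strict monotonicity in q
  o <- order(q)
  expect_true(all(diff(predictLogistic(fit, d$B)[o])[diff(q[o]) > 0] > 0))
})

test_that("two cells with known q give the hand-computed logistic output", {
  q <- c(0.9, 0.1)
  H <- -sum(q * log(q))
  model <- new("MaxentModel",
               features = list(vars = "x",
                               range = matrix(c(0, 1), 2, 1,
                                              dimnames = list(c("min", "max"),
                                                              "x")),
                               table = data.frame(type = "linear",
                                                  var1 = "x", var2 = NA,
                                                  knot = NA, fmin = 0,
                                                  fmax = 1)),
               lambda = log(9), regBeta = 0, logZ = log(1 / 0.1),
               entropyH = H, gainTrajectory = 0,
               varGain = c(x = 1), presenceX = matrix(0, 0, 0),
               backgroundX = matrix(0, 0, 0), nNorm = 2, converged = TRUE)
  rows <- matrix(c(1, 0), ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(predictRaw(model, rows), q, tolerance = 1e-12)
  expect_equal(predictLogistic(model, rows),
               exp(H) * q / (1 + exp(H) * q), tolerance = 1e-12)
})

test_that("feature values stay within [0, 1] on the training data", {
  set.seed(11)
  X <- cbind(a = rnorm(200, 3, 5), b = runif(200, -2, 2))
  fs <- buildFeatureSet(X, nKnots = 12)
  F <- featureMatrix(fs, X)
  expect_true(all(F >= 0 & F <= 1))
  # knots strictly inside the observed range
  kn <- fs$table$knot[!is.na(fs$table$knot)]
  expect_true(all(kn > min(X[, "a"]) | kn > min(X[, "b"])))
  expect_true(all(fs$table$knot[fs$table$var1 == "a" &
                                  !is.na(fs$table$knot)] > min(X[, "a"])))
  expect_true(all(fs$table$knot[fs$table$var1 == "a" &
                                  !is.na(fs$table$knot)] < max(X[, "a"])))
})

test_that("bootstrap replicates are deterministic under a fixed seed", {
  sc <- recoveryScene(nrows = 32, ncols = 32)
  cfg <- list(nKnots = 5, maxIter = 100)
  e1 <- bootstrapEnsemble(sc$occ, sc$stack, reps = 2, seed = 3,
                          nBackground = 300, config = cfg)
  e2 <- bootstrapEnsemble(sc$occ, sc$stack, reps = 2, seed = 3,
                          nBackground = 300, config = cfg)
  expect_identical(gridValues(e1$meanRaster), gridValues(e2$meanRaster))
  expect_identical(e1$testAUC, e2$testAUC)
  expect_error(bootstrapEnsemble(sc$occ, sc$stack, reps = 0),
               "at least 1")
})

test_that("model serialization round-trips predictions", {
  d <- binaryFeatureData()
  fit <- fitMaxent(d$P, d$B, list(classes = "linear", nKnots = 0))
  f <- withr::local_tempfile(fileext = ".json")
  writeMaxentModel(fit, f)
  fit2 <- readMaxentModel(f)
  rows <- matrix(c(0, 1), ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(predictLogistic(fit2, rows), predictLogistic(fit, rows),
               tolerance = 1e-12)
})
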