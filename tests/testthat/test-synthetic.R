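test_that("random fields are reproducible, standardized and tunable in smoothness", {
  f1 <- gaussianField(100, 100, correlationLength = 8, seed = 5)
  f2 <- gaussianField(100, 100, correlationLength = 8, seed = 5)
  expect_identical(gridValues(f1), gridValues(f2))
  v <- as.vector(gridValues(f1))
  expect_equal(sd(v), 1, tolerance = 0.15)
  expect_equal(mean(v), 0, tolerance = 1e-9)
  # smooth field: strong lag-1 autocorrelation; tiny length: white noise
  lag1 <- function(g) {
    m <- gridValues(g)
    cor(as.vector(m[, -1]), as.vector(m[, -ncol(m)]))
  }
  expect_gt(lag1(f1), 0.8)
  white <- gaussianField(100, 100, correlationLength = 1e-3, seed = 5)
  expect_lt(abs(lag1(white)), 0.1)
  expect_error(gaussianField(4, 100), "at least 8")
})

test_that("stacks reproduce the requested cross-correlation structure", {
  cc <- diag(3)
  cc[1, 2] <- cc[2, 1] <- 0.9
  st <- makeEnvStack(crossCorr = cc, nrows = 200, ncols = 200, seed = 2)
  V <- vapply(st@layers, function(l) as.vector(gridValues(l)),
              numeric(200 * 200))
  emp <- cor(V)
  expect_equal(emp[1, 2], 0.9, tolerance = 0.05)
  expect_lt(abs(emp[1, 3]), 0.1)
  expect_error(makeEnvStack(crossCorr = matrix(c(1, 2, 2, 1), 2, 2)),
               "positive-definite")
  # k = 1 passthrough: one standardized layer
  st1 <- makeEnvStack(k = 1, nrows = 50, ncols = 50, seed = 4)
  expect_length(st1@layers, 1L)
})

test_that("occurrences concentrate where the suitability law is high", {
  st <- makeEnvStack(k = 2, nrows = 60, ncols = 60, seed = 3,
                     names = c("A", "B"))
  occ <- simulateOccurrences(st, c(A = 3), intercept = -2, n = 400,
                             seed = 8)
  ev <- extractValues(st, occ, method = "nearest")
  bgMean <- mean(gridValues(getLayer(st, "A")))
  bgSd <- sd(gridValues(getLayer(st, "A")))
  expect_gt(mean(ev$A), bgMean + 0.5 * bgSd)
  one <- simulateOccurrences(st, c(A = 1), n = 1, seed = 2)
  expect_equal(nrow(occPoints(one)), 1L)
  truth <- attr(occ, "truth")
  expect_equal(truth$trueBeta, c(A = 3))
  expect_s4_class(truth$trueSurface, "RasterGrid")
})

test_that("a flat suitability law yields spatially uniform occurrences", {
  st <- makeEnvStack(k = 1, nrows = 40, ncols = 40, seed = 6)
  occ <- simulateOccurrences(st, c(env1 = 0), intercept = 0, n = 1200,
                             seed = 9)
  pts <- occPoints(occ)
  # quadrant counts against the uniform expectation
  midLon <- 100 + 40 * 0.05 / 2
  midLat <- 20 + 40 * 0.05 / 2
  q <- table(pts[, 1] >= midLon, pts[, 2] >= midLat)
  expect_gt(chisq.test(as.vector(q))$p.value, 0.01)
})

test_that("chromatogram simulation integrates to the planted areas", {
  ch <- simulateChromatogram(data.frame(rt = 25, width = 0.2, area = 80),
                             noiseSd = 0, rate = 50)
  expect_equal(.trapzOracle(ch@time, ch@signal), 80, tolerance = 0.01)
  ch2 <- simulateChromatogram(data.frame(rt = 25, width = 0.2, area = 80),
                              noiseSd = 0.5, seed = 3)
  ch3 <- simulateChromatogram(data.frame(rt = 25, width = 0.2, area = 80),
                              noiseSd = 0.5, seed = 3)
  expect_identical(ch2@signal, ch3@signal)
  empty <- simulateChromatogram(data.frame(rt = numeric(),
                                           width = numeric(),
                                           area = numeric()),
                                noiseSd = 0, drift = 0)
  expect_equal(unique(empty@signal), 0)
  expect_error(simulateChromatogram(data.frame(rt = 99, width = 1,
                                               area = 1)), "duration")
})

test_that("content simulation follows the linear law and decouples at beta zero", {
  set.seed(12)
  env <- matrix(rnorm(100 * 2), 100, 2, dimnames = list(NULL, c("f", "g")))
  exact <- simulateContents(env, list(Hyp = c(f = 2)), intercepts = c(Hyp = 10),
                            noiseSd = 0, seed = 1)
  expect_equal(unname(exact@contents[, "Hyp"]),
               pmax(10 + 2 * env[, "f"], 0))
  null <- simulateContents(env, list(Rt = c(f = 0)), intercepts = c(Rt = 5),
                           noiseSd = 1, seed = 2)
  expect_lt(abs(cor(null@contents[, "Rt"], env[, "f"])), 0.2)
})

test_that("fingerprint scenes plant the requested shared-peak structure", {
  sc <- simulateFingerprintScene(nSamples = 4, nPeaks = 10, seed = 5)
  expect_length(sc$chromatograms, 4L)
  expect_length(sc$trueRT, 10L)
  expect_equal(dim(sc$trueAreas), c(4L, 10L))
  sc2 <- simulateFingerprintScene(nSamples = 4, nPeaks = 10, seed = 5)
  expect_identical(sc$chromatograms[[1]]@signal,
                   sc2$chromatograms[[1]]@signal)
})
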