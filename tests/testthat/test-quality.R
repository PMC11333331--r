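panelFrom <- function(contents, ids = NULL) {
  n <- nrow(contents)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  rownames(contents) <- ids
  new("CompoundPanel",
      sites = data.frame(id = ids, lon = seq_len(n) / 10, lat = 30),
      contents = contents)
}

test_that("panels pass contents through and enforce the site mapping", {
  ct <- matrix(1:6 + 0, 3, 2, dimnames = list(NULL, c("Hyp", "Ch.a")))
  sites <- data.frame(id = c("a", "b", "c"), lon = 1:3, lat = 30:32)
  rownames(ct) <- sites$id
  p <- buildPanel(sites, contents = ct)
  expect_s4_class(p, "CompoundPanel")
  # column order fixed to the marker-compound order
  expect_equal(colnames(p@contents), c("Ch.a", "Hyp"))
  expect_error(buildPanel(data.frame(id = "zzz", lon = 1, lat = 2),
                          contents = ct), "without contents")
})

test_that("noiseless stepwise regression recovers the exact generating model", {
  set.seed(41)
  env <- as.data.frame(matrix(rnorm(50 * 5), 50, 5,
                              dimnames = list(NULL, paste0("x", 1:5))))
  y <- 20 + 2 * env$x1
  p <- panelFrom(matrix(y, ncol = 1, dimnames = list(NULL, "Ch.a")))
  fit <- stepwiseFit(p, env, "Ch.a")
  expect_equal(fit$factors, "x1")
  expect_equal(unname(fit$coef["x1"]), 2, tolerance = 1e-8)
  expect_equal(unname(fit$coef["(Intercept)"]), 20, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("pure-noise responses almost always select the intercept-only model", {
  hits <- 0
  for (s in 1:10) {
    set.seed(700 + s)
    env <- as.data.frame(matrix(rnorm(200 * 5), 200, 5,
                                dimnames = list(NULL, paste0("x", 1:5))))
    y <- rnorm(200)
    p <- panelFrom(matrix(pmax(y + 5, 0), ncol = 1,
                          dimnames = list(NULL, "Rt")))
    fit <- stepwiseFit(p, env, "Rt", criterion = "BIC")
    hits <- hits + (length(fit$factors) == 0L)
  }
  expect_gte(hits, 9)
})

test_that("forward and backward selection agree on a well-separated signal", {
  set.seed(43)
  env <- as.data.frame(matrix(rnorm(80 * 4), 80, 4,
                              dimnames = list(NULL, paste0("x", 1:4))))
  y <- 20 + 3 * env$x2 + rnorm(80, 0, 0.1)
  p <- panelFrom(matrix(y, ncol = 1, dimnames = list(NULL, "Hyp")))
  fw <- stepwiseFit(p, env, "Hyp", direction = "forward")
  bw <- stepwiseFit(p, env, "Hyp", direction = "backward")
  expect_equal(sort(fw$factors), sort(bw$factors))
  expect_true("x2" %in% fw$factors)
  expect_equal(unname(fw$coef["x2"]), 3, tolerance = 0.05)
})

test_that("correlation tables match the textbook t-test and sign symmetry", {
  set.seed(44)
  env <- data.frame(f1 = c(1.2, 2.1, 2.9, 4.2, 5.1))
  y <- c(2.0, 3.9, 6.2, 8.1, 9.9)
  p <- panelFrom(matrix(y, ncol = 1, dimnames = list(NULL, "Cyn")))
  tb <- correlationTable(p, env)
  r <- cor(env$f1, y)
  tstat <- r * sqrt(3 / (1 - r^2))
  expect_equal(tb$r, r)
  expect_equal(tb$p, 2 * pt(-abs(tstat), df = 3), tolerance = 1e-12)
  # y = x gives r = 1; flipping the sign of the factor flips r
  p2 <- panelFrom(matrix(env$f1, ncol = 1, dimnames = list(NULL, "Rt")))
  expect_equal(correlationTable(p2, env)$r, 1)
  tbNeg <- correlationTable(p, data.frame(f1 = -env$f1))
  expect_equal(tbNeg$r, -tb$r)
  expect_equal(tb$stars, "**")
})

test_that("content rasters apply the linear model cell-wise with flooring", {
  st <- tinyStack()
  m0 <- list(compound = "Hyp", coef = c(`(Intercept)` = 2.5))
  r0 <- predictContentRaster(m0, st)
  expect_equal(unique(as.vector(gridValues(r0))), 2.5)
  m1 <- list(compound = "Hyp", coef = c(`(Intercept)` = 0, a = 1))
  r1 <- predictContentRaster(m1, st)
  expect_equal(gridValues(r1), gridValues(getLayer(st, "a")))
  mNeg <- list(compound = "Hyp", coef = c(`(Intercept)` = -1))
  rNeg <- predictContentRaster(mNeg, st)
  expect_equal(unique(as.vector(gridValues(rNeg))), 0)
  expect_equal(attr(rNeg, "flooredCells"), 4L)
  expect_error(predictContentRaster(
    list(coef = c(`(Intercept)` = 0, zz = 1)), st), "missing layer")
})

test_that("quality zoning normalizes, masks and grades as specified", {
  set.seed(45)
  suit <- rasterGrid(matrix(runif(100, 0, 1), 10, 10), yll = 20)
  c1 <- rasterGrid(matrix(runif(100, 1, 3), 10, 10), name = "Hyp",
                   yll = 20)
  qz <- overlayQualityZoning(list(Hyp = c1), suit, maskThreshold = 0.2)
  mask <- binarizeSuitability(suit, 0.2)
  # nodata pattern is exactly the complement of the mask
  expect_equal(is.na(gridValues(qz@score)), !mask)
  expect_equal(is.na(gridValues(qz@grades)), !mask)
  # single raster: grades equal the Jenks classes of that raster on the mask
  v <- c1@values[mask]
  norm <- (v - min(v)) / (max(v) - min(v))
  br <- jenksBreaks(norm, 4)
  expect_equal(gridValues(qz@grades)[mask], rowSums(outer(norm, br, ">=")))
  # affine rescaling of a content raster leaves the score unchanged
  c2 <- c1; c2@values <- 100 * c2@values + 7
  qz2 <- overlayQualityZoning(list(Hyp = c2), suit, maskThreshold = 0.2)
  expect_equal(gridValues(qz2@score), gridValues(qz@score),
               tolerance = 1e-12)
})

test_that("degenerate constant contents score the neutral 0.5", {
  suit <- rasterGrid(matrix(0.5, 4, 4), yll = 20)
  cst <- rasterGrid(matrix(3, 4, 4), name = "Hyp", yll = 20)
  qz <- overlayQualityZoning(list(Hyp = cst), suit)
  expect_equal(unique(as.vector(gridValues(qz@score))), 0.5)
  expect_equal(qz@provenance$degenerate, "Hyp")
  expect_error(overlayQualityZoning(list(Hyp = cst),
                                    rasterGrid(matrix(0.1, 4, 4), yll = 20)),
               "empty")
})
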