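test_that("peak detection recovers a noiseless Gaussian to 1% in area", {
  ch <- simulateChromatogram(data.frame(rt = 10, width = 0.15, area = 100),
                             noiseSd = 0, rate = 50)
  pk <- detectPeaks(ch, minHeight = 1, minProminence = 1)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$rt, 10, tolerance = 1 / 50 + 1e-9)
  expect_equal(pk$area, 100, tolerance = 0.01)
})

test_that("flat baselines yield no peaks and separated peaks stay ordered", {
  flat <- chromatogram(seq(0, 10, 0.1), rep(2, 101))
  expect_equal(nrow(detectPeaks(flat, 1, 0.5)), 0L)
  two <- simulateChromatogram(
    data.frame(rt = c(10, 20), width = 0.2, area = c(50, 80)),
    noiseSd = 0, rate = 50)
  pk <- detectPeaks(two, 1, 1)
  expect_equal(nrow(pk), 2L)
  expect_lt(pk$rt[1], pk$rt[2])
  expect_equal(pk$area, c(50, 80), tolerance = 0.01)
  expect_error(detectPeaks(two, -1, 1), "positive")
})

test_that("identical peak tables are fully common under identity correction", {
  ch <- simulateChromatogram(
    data.frame(rt = c(5, 10, 15), width = 0.15, area = c(40, 60, 30)),
    noiseSd = 0, rate = 50)
  pk <- detectPeaks(ch, 1, 1)
  cpm <- alignPeakTables(list(S1 = pk, S2 = pk, S3 = pk), 1L,
                         rtTolerance = 0.2)
  expect_equal(ncol(cpm@areas), 3L)
  expect_equal(unname(cpm@areas["S2", ]), pk$area, tolerance = 1e-9)
})

test_that("a uniform retention shift is fully corrected within tolerance", {
  spec <- data.frame(rt = c(5, 10, 15, 20), width = 0.15,
                     area = c(40, 60, 30, 50))
  ref <- detectPeaks(simulateChromatogram(spec, rate = 50), 1, 1)
  shifted <- spec; shifted$rt <- shifted$rt + 0.1
  smp <- detectPeaks(simulateChromatogram(shifted, rate = 50), 1, 1)
  cpm <- alignPeakTables(list(R = ref, S = smp), "R", rtTolerance = 0.2)
  expect_equal(ncol(cpm@areas), 4L)
  # areas are conserved by the correction (only times move)
  expect_equal(unname(cpm@areas["S", ]), smp$area, tolerance = 1e-9)
})

test_that("peaks absent from one sample are excluded from the common set", {
  full <- data.frame(rt = c(5, 10, 15), width = 0.15, area = 50)
  part <- data.frame(rt = c(5, 15), width = 0.15, area = 50)
  pkF <- detectPeaks(simulateChromatogram(full, rate = 50), 1, 1)
  pkP <- detectPeaks(simulateChromatogram(part, rate = 50), 1, 1)
  cpm <- alignPeakTables(list(A = pkF, B = pkP), "A", rtTolerance = 0.2)
  expect_equal(ncol(cpm@areas), 2L)
  expect_equal(cpm@peakRT, c(5, 15), tolerance = 0.05)
})

test_that("reference fingerprints are the column statistic", {
  areas <- rbind(S1 = c(1, 5), S2 = c(2, 6), S3 = c(100, 7))
  cpm <- new("CommonPeakMatrix", areas = areas, peakRT = c(5, 10))
  expect_equal(unname(referenceFingerprint(cpm, "median")), c(2, 6))
  expect_equal(unname(referenceFingerprint(cpm, "mean")),
               c(mean(c(1, 2, 100)), 6))
  one <- new("CommonPeakMatrix", areas = areas[1, , drop = FALSE],
             peakRT = c(5, 10))
  expect_equal(unname(referenceFingerprint(one)), unname(areas[1, ]))
})

test_that("congruence similarity is the cosine of the area vectors", {
  expect_equal(congruenceSimilarity(c(1, 2, 2), c(2, 1, 2)), 8 / 9)
  v <- c(3, 1, 4, 1, 5)
  expect_equal(congruenceSimilarity(v, v), 1.0)
  expect_equal(congruenceSimilarity(v, 3 * v), 1.0)  # scale invariance
  expect_error(congruenceSimilarity(v, rep(0, 5)), "zero vector")
  expect_error(congruenceSimilarity(v, 1:4), "equal length")
})

test_that("similarity matrices are symmetric with unit diagonal in [0, 1]", {
  set.seed(23)
  areas <- matrix(runif(5 * 7, 1, 100), 5, 7,
                  dimnames = list(paste0("S", 1:5), NULL))
  cpm <- new("CommonPeakMatrix", areas = areas, peakRT = 1:7 + 0)
  S <- similarityMatrix(cpm)
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 6))
  expect_true(all(S >= 0 & S <= 1 + 1e-12))
  expect_equal(rownames(S), c(paste0("S", 1:5), "C"))
})

test_that("RSD follows the sample-sd convention and is scale-free", {
  expect_equal(rsdPercent(rep(7, 6)), 0)
  expect_equal(rsdPercent(c(2, 4)), sqrt(2) / 3 * 100)
  expect_equal(rsdPercent(c(2, 4)), 47.14045, tolerance = 1e-6)
  set.seed(2)
  v <- runif(6, 10, 20)
  expect_equal(rsdPercent(v * 3.7), rsdPercent(v))
  expect_error(rsdPercent(3), "at least 2")
  expect_error(rsdPercent(c(-1, 1)), "zero mean")
})

test_that("one-point external-standard quantification scales as expected", {
  areas <- rbind(S1 = c(100, 50), S2 = c(200, 50))
  cpm <- new("CommonPeakMatrix", areas = areas, peakRT = c(5, 10),
             compoundMap = c(`Ch.a` = 1L, Rt = 2L))
  std <- list(`Ch.a` = c(100, 0.1), Rt = c(100, 0.1))
  q <- quantifyCompounds(cpm, std, sampleMassG = 1, extractVolumeML = 50)
  # area ratio 1 -> conc * volume / mass = 0.1 * 50 / 1 = 5 mg/g
  expect_equal(q["S1", "Ch.a"], 5)
  expect_equal(q["S2", "Ch.a"], 10)       # doubling area doubles content
  expect_equal(q["S1", "Rt"], 0.5 * 0.1 * 50 / 1)  # ratio 0.5 -> 2.5 mg/g
  expect_error(quantifyCompounds(cpm, list(Hyp = c(1, 1))), "not mapped")
})

test_that("marker compounds map onto common-peak columns by retention time", {
  areas <- rbind(S1 = c(10, 20, 30), S2 = c(11, 21, 31))
  cpm <- new("CommonPeakMatrix", areas = areas, peakRT = c(5, 10, 15))
  cpm2 <- identifyCompounds(cpm, c(`Ch.a` = 5.05, `Isa A` = 14.9),
                            rtTolerance = 0.2)
  expect_equal(cpm2@compoundMap, c(`Ch.a` = 1L, `Isa A` = 3L))
  expect_error(identifyCompounds(cpm, c(Rt = 40)), "not found")
})
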