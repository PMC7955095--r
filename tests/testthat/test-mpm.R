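# SHG/CARS collagen quantification: preprocessing, binarization, crystal
# correction, stack averaging and lipid summary.

test_that("every preprocessing stage matches its brute-force oracle bit-exactly", {
  for (seed in 1:3) {
    img <- randomImage16(48L, seed)
    expect_identical(meanFilter(img, 1L), oracleMeanFilter(img, 1L))
    expect_identical(contrastStretch(img, 0.4), oracleStretch(img, 0.4))
    expect_identical(subtractBackground(img, 8L), oracleTopHat(img, 8L))
    expect_identical(triangleThreshold(img), oracleTriangle(img))
  }
  # stretch with zero saturation too
  img <- randomImage16(48L, 9)
  expect_identical(contrastStretch(img, 0), oracleStretch(img, 0))
})

test_that("constant image passes through SHG preprocessing unchanged", {
  img <- matrix(7L, 32, 32)
  expect_identical(preprocessSHG(img), img)
})

test_that("two-level image with zero saturation stretches to the full range", {
  img <- matrix(1000L, 100, 10)
  img[1:10, 1] <- 60000L   # 1 % bright pixels
  out <- contrastStretch(img, 0)
  expect_identical(sort(unique(as.vector(out))), c(0L, 65535L))
})

test_that("a single bright pixel is spread by the 3x3 neighborhood mean", {
  img <- matrix(0L, 9, 9)
  img[5, 5] <- 65535L
  out <- meanFilter(img, 1L)
  expect_equal(out[5, 5], round(65535 / 9))
  expect_equal(out[4, 4], round(65535 / 9))
  expect_equal(out[3, 5], 0L)
})

test_that("SHG binarization threshold is strictly greater-than", {
  at <- matrix(20000L, 8, 8)
  expect_equal(sum(maskPixels(binarizeSHG(at))), 0)      # boundary excluded
  above <- matrix(20001L, 8, 8)
  expect_equal(areaPct(binarizeSHG(above)), 100)
  chk <- matrix(c(0L, 65535L), 8, 8)                     # checkerboard-ish
  expect_equal(areaPct(binarizeSHG(chk)), 50)
})

test_that("CARS background subtraction removes flat and ramp backgrounds", {
  flat <- matrix(5000L, 64, 64)
  expect_true(all(subtractBackground(flat, 10L) == 0L))
  expect_true(all(subtractBackground(matrix(0L, 64, 64), 10L) == 0L))
  # small bright disc on a linear ramp: disc retained, ramp removed
  ramp <- matrix(rep(seq(0L, 8000L, length.out = 64), each = 64), 64, 64)
  storage.mode(ramp) <- "integer"
  disc <- ramp
  for (i in 28:36) for (j in 28:36)
    if ((i - 32)^2 + (j - 32)^2 <= 9) disc[i, j] <- disc[i, j] + 30000L
  th <- subtractBackground(disc, 10L)
  peak <- max(th)
  expect_gt(peak, 0.95 * 30000)
  corners <- c(th[1, 1], th[1, 64], th[64, 1], th[64, 64])
  expect_true(all(corners <= 0.05 * peak))
  expect_error(subtractBackground(matrix(0L, 20, 20), 30L), "smaller")
})

test_that("triangle threshold separates a bimodal histogram and rejects constants", {
  set.seed(2)
  v <- c(rep(10L * 256L + 5L, 950), rep(200L * 256L + 5L, 50))
  img <- matrix(sample(v), 40, 25)
  thr <- triangleThreshold(img)
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  m <- maskPixels(binarizeCARS(img))
  expect_equal(sum(m), 50)
  # exactly two extreme values: bright class isolated
  img2 <- matrix(c(rep(0L, 60), rep(65535L, 4)), 8, 8)
  expect_equal(sum(maskPixels(binarizeCARS(img2))), 4)
  expect_error(triangleThreshold(matrix(5L, 8, 8)), "constant")
})

test_that("crystal correction obeys exact mask algebra", {
  full <- BinaryMask(matrix(TRUE, 10, 10))
  f <- crystalCorrectedFraction(full, full)
  expect_equal(unname(f["correctedPct"]), 0)
  expect_equal(unname(f["crystalPct"]), 100)
  shg <- BinaryMask(matrix(rep(c(TRUE, FALSE), c(10, 90)), 10, 10))
  cars <- BinaryMask(matrix(rep(c(FALSE, TRUE, FALSE), c(10, 20, 70)), 10, 10))
  f <- crystalCorrectedFraction(shg, cars)   # disjoint 10 % and 20 %
  expect_equal(unname(f["correctedPct"]), 10)
  expect_equal(unname(f["crystalPct"]), 0)
  expect_error(crystalCorrectedFraction(shg, BinaryMask(matrix(TRUE, 5, 5))),
               "geometries")
  # corrected + crystal = raw, and corrected = area(A & !B), for random pairs
  set.seed(4)
  for (k in 1:50) {
    a <- BinaryMask(randomMask(32, runif(1)))
    b <- BinaryMask(randomMask(32, runif(1)))
    f <- crystalCorrectedFraction(a, b)
    expect_identical(unname(f["correctedPct"] + f["crystalPct"]),
                     unname(f["rawShgPct"]))
    expect_identical(unname(f["correctedPct"]), areaPct(a & !b))
  }
})

test_that("binarization is idempotent on its own output", {
  img <- randomImage16(48L, 5)
  m <- maskPixels(binarizeSHG(preprocessSHG(img)))
  again <- maskPixels(binarizeSHG(matrix(as.integer(m) * 65535L,
                                         nrow(m), ncol(m))))
  expect_identical(again, m)
})

test_that("raising the SHG threshold never increases the corrected fraction", {
  ph <- generateMPMPhantom(sizePx = c(96, 96), nSlices = 1,
                           fiberDensity = 0.15, crystalCount = 1, seed = 6)
  pre <- preprocessSHG(pixels(ph$shg)[[1]])
  carsBin <- binarizeCARS(preprocessCARS(pixels(ph$cars)[[1]]), 0.28)
  fr <- sapply(c(5000, 15000, 20000, 30000, 50000), function(t)
    crystalCorrectedFraction(binarizeSHG(pre, t), carsBin)[["correctedPct"]])
  expect_true(all(diff(fr) <= 0))
})

test_that("stack averaging equals the single-slice value for identical slices", {
  ph <- generateMPMPhantom(sizePx = c(96, 96), nSlices = 1,
                           fiberDensity = 0.1, crystalCount = 1, seed = 8)
  shg3 <- ImageStack(rep(pixels(ph$shg), 3), pitchUm = 0.28, channel = "SHG")
  cars3 <- ImageStack(rep(pixels(ph$cars), 3), pitchUm = 0.28,
                      channel = "CARS")
  r1 <- collagenStack(ph$shg, ph$cars)
  r3 <- collagenStack(shg3, cars3)
  expect_equal(r3@meanPct, r1@meanPct)
  expect_equal(length(r3@perSlicePct), 3L)
  expect_equal(r3@meanPct, mean(r3@perSlicePct))
})

test_that("empty phantom stack quantifies to 0 % collagen", {
  ph <- generateMPMPhantom(sizePx = c(64, 64), nSlices = 2, fiberDensity = 0,
                           noiseGaussianSd = 0, noisePoissonScale = 0,
                           seed = 1)
  expect_equal(collagenStack(ph$shg, ph$cars)@meanPct, 0)
})

test_that("channel-tag mismatches are rejected", {
  ph <- generateMPMPhantom(sizePx = c(32, 32), nSlices = 1, fiberDensity = 0.1,
                           seed = 1)
  expect_error(collagenStack(ph$cars, ph$shg), "channel tags")
  expect_error(lipidSummary(ph$shg, ph$cars), "channel tags")
})

test_that("phantom collagen recovery lands near truth at default noise", {
  ph <- generateMPMPhantom(sizePx = c(128, 128), nSlices = 3,
                           fiberDensity = 0.10, crystalCount = 2, seed = 3)
  r <- collagenStack(ph$shg, ph$cars)
  expect_lt(abs(r@meanPct - ph$truth@collagenFractionPct), 2)
})

test_that("lipid summary counts planted droplets and separates crystals", {
  ph <- generateMPMPhantom(sizePx = c(128, 128), nSlices = 3,
                           fiberDensity = 0.05, crystalCount = 0,
                           dropletCount = 12, seed = 4)
  lip <- lipidSummary(ph$cars, ph$shg)
  expect_equal(lip@dropletCount, 12L)
  expect_equal(lip@crystalAreaPct, 0)
  expect_gt(lip@dropletAreaPct, 0)
  # with crystals present, both classes are reported
  ph2 <- generateMPMPhantom(sizePx = c(128, 128), nSlices = 2,
                            fiberDensity = 0.05, crystalCount = 2,
                            dropletCount = 4, seed = 2)
  lip2 <- lipidSummary(ph2$cars, ph2$shg)
  expect_equal(lip2@dropletCount, 4L)
  expect_gt(lip2@crystalAreaPct, 0)
})

test_that("empty phantom yields an all-zero lipid summary", {
  ph <- generateMPMPhantom(sizePx = c(64, 64), nSlices = 2, fiberDensity = 0,
                           noiseGaussianSd = 0, noisePoissonScale = 0,
                           seed = 1)
  lip <- lipidSummary(ph$cars, ph$shg)
  expect_equal(lip@dropletCount, 0L)
  expect_equal(lip@dropletAreaPct, 0)
  expect_equal(lip@crystalAreaPct, 0)
})

test_that("maximum intensity projection dominates slice-wise", {
  s1 <- matrix(0L, 8, 8); s2 <- matrix(65535L, 8, 8)
  st <- ImageStack(list(s1, s2, s1), channel = "CARS")
  expect_true(all(maxIntensityProjection(st) == 65535L))
})
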