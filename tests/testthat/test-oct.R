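# OCT morphometry: rescaling, refractive correction, composite slabs,
# region assignment, area and thickness measurement.

test_that("rescaling to the current pitch is the identity", {
  set.seed(1)
  v <- array(runif(8 * 8 * 8, 0, 65535), c(8, 8, 8))
  vol <- OCTVolume(v, pitchUm = c(2.255, 2.255, 2.255))
  out <- rescaleIsotropic(vol, 2.255)
  expect_equal(voxels(out), v)
  expect_true(out@isotropic)
})

test_that("rescaling preserves extent within one voxel and constants", {
  v <- array(0, c(11, 4, 4))       # 100 um extent at 10 um pitch on x
  vol <- OCTVolume(v, pitchUm = c(10, 10, 10))
  out <- rescaleIsotropic(vol, 2.255)
  nNew <- dim(voxels(out))[1]
  expect_equal((nNew - 1) * 2.255, 100, tolerance = 2.255 / 100)
  cvol <- OCTVolume(array(42, c(9, 9, 9)), pitchUm = c(5, 4, 3))
  expect_true(all(abs(voxels(rescaleIsotropic(cvol, 2.255)) - 42) < 1e-9))
})

test_that("optical-to-geometric correction divides the axial pitch by n", {
  v <- array(0, c(4, 4, 10))
  vol <- OCTVolume(v, pitchUm = c(2, 2, 2), refractiveIndex = 1.33)
  out <- opticalToGeometric(vol)
  expect_equal(pitchUm(out), c(2, 2, 2 / 1.33))
  # 133 um optical extent becomes 100 um geometric
  expect_equal(133 / 1.33, 100)
  expect_equal(10 * pitchUm(out)[3] * 1.33 / 1.33, 10 * 2 / 1.33)
  # n = 1 is the identity, and the correction is exactly invertible
  expect_equal(pitchUm(opticalToGeometric(vol, 1)), c(2, 2, 2))
  expect_equal(pitchUm(out)[3] * 1.33, 2)
  expect_error(opticalToGeometric(vol, 0.9), ">= 1")
})

test_that("composite cross-sections sum adjacent slices", {
  v <- array(0, c(4, 10, 4))
  for (k in 1:10) v[, k, ] <- k            # slice k along y has value k
  vol <- OCTVolume(v, pitchUm = c(1, 1, 1))
  one <- compositeCrossSection(vol, 5, window = 1)
  expect_true(all(one == 5))
  vol2 <- OCTVolume(array(7, c(4, 12, 4)), pitchUm = c(1, 1, 1))
  ten <- compositeCrossSection(vol2, 6, window = 10)
  expect_true(all(ten == 70))
  expect_error(compositeCrossSection(vol2, 2, window = 10), "exceeds")
})

test_that("slab summing improves speckle SNR", {
  snrs <- sapply(1:5, function(sd) {
    oc <- generateOCTPhantom(volumePx = c(60, 24, 100),
                             thicknessUm = c(80, 70, 60), curvatureUm = 15,
                             seed = sd)
    vol <- oc$volume
    band <- oc$truth@leafletMask$crossSection
    single <- voxels(vol)[, 12, ]
    comp <- compositeCrossSection(vol, 12, window = 10)
    snr <- function(img) mean(img[band]) / stats::sd(img[band])
    c(snr(single), snr(comp))
  })
  expect_true(all(snrs[2, ] >= snrs[1, ]))
})

test_that("area is pixel count times squared pitch, with empty-mask warning", {
  expect_equal(measureArea(BinaryMask(matrix(TRUE, 10, 10), 2.255)), 508.5,
               tolerance = 1e-4)
  expect_warning(a0 <- measureArea(BinaryMask(matrix(FALSE, 4, 4), 1)),
                 "empty")
  expect_equal(a0, 0)
})

test_that("region assignment partitions the mask tip-to-base", {
  m <- matrix(FALSE, 40, 300)
  m[10:20, ] <- TRUE                       # straight band along columns
  mask <- BinaryMask(m, 1)
  grid <- assignRegions(mask, tipPoint = c(15, 300), basePoint = c(15, 1))
  expect_equal(sort(unique(as.vector(grid@labels[m]))), 1:3)
  expect_true(all(grid@labels[!m] == 0L))
  counts <- table(grid@labels[m])
  expect_equal(max(counts) / min(counts), 1, tolerance = 0.05)
  # orientation: region 1 holds the tip, region 3 the base
  expect_equal(grid@labels[15, 299], 1L)
  expect_equal(grid@labels[15, 2], 3L)
  expect_error(assignRegions(mask, c(1, 1), c(1, 1)), "coincide")
})

test_that("thickness of an axis-aligned band is exact in every region", {
  m <- matrix(FALSE, 80, 300)
  m[11:60, ] <- TRUE                       # 50 px tall at 2 um
  mask <- BinaryMask(m, 2)
  grid <- assignRegions(mask, c(35, 300), c(35, 1))
  th <- measureThickness(mask, grid)
  expect_equal(unname(th), c(100, 100, 100))
  thMax <- measureThickness(mask, grid, mode = "max")
  expect_equal(unname(thMax), c(100, 100, 100))
})

test_that("thickness is stable under in-plane rotation of the band", {
  n <- 200
  m <- matrix(FALSE, n, n)
  th <- 30 * pi / 180
  u <- c(cos(th), sin(th))                # axis direction in (row, col)
  for (i in 1:n) for (j in 1:n) {
    d <- c(i - n / 2, j - n / 2)
    along <- d[1] * u[1] + d[2] * u[2]
    perp <- -d[1] * u[2] + d[2] * u[1]
    if (abs(perp) <= 20 && abs(along) <= 80) m[i, j] <- TRUE
  }
  mask <- BinaryMask(m, 1)
  tip <- c(n / 2 + 75 * u[1], n / 2 + 75 * u[2])
  base <- c(n / 2 - 75 * u[1], n / 2 - 75 * u[2])
  grid <- assignRegions(mask, tip, base)
  th3 <- measureThickness(mask, grid)
  expect_true(all(abs(th3 - 41) / 41 < 0.05))   # 41 px true chord
})

test_that("scale equivariance: doubling pitch doubles thickness, quadruples area", {
  m <- matrix(FALSE, 40, 120)
  m[5:24, ] <- TRUE
  m1 <- BinaryMask(m, 1); m2 <- BinaryMask(m, 2)
  g <- assignRegions(m1, c(14, 120), c(14, 1))
  expect_equal(measureArea(m2), 4 * measureArea(m1))
  expect_equal(unname(measureThickness(m2, g)),
               2 * unname(measureThickness(m1, g)))
})

test_that("full OCT chain recovers phantom thickness and area", {
  maxThErr <- areaErr <- c()
  for (sd in 1:3) {
    oc <- generateOCTPhantom(seed = sd)
    vol <- rescaleIsotropic(opticalToGeometric(oc$volume), 2.255)
    idx <- dim(voxels(vol))[2] %/% 2
    cs <- compositeCrossSection(vol, idx, 10)
    mask <- segmentCrossSection(cs, 2.255)
    sc <- c(pitchUm(oc$volume)[1],
            pitchUm(oc$volume)[3] / oc$volume@refractiveIndex) / 2.255
    tip <- (oc$truth@leafletMask$tip - 0.5) * sc + 0.5
    base <- (oc$truth@leafletMask$base - 0.5) * sc + 0.5
    res <- leafletMorphometry(mask, tip, base)
    maxThErr <- c(maxThErr,
                  max(abs(res@thicknessUm - oc$truth@thicknessProfileUm)))
    areaErr <- c(areaErr,
                 abs(res@areaUm2 - oc$truth@areaUm2) / oc$truth@areaUm2)
  }
  expect_true(all(maxThErr <= 2.255))
  expect_true(all(areaErr <= 0.03))
})

test_that("region with no mask pixels yields NaN thickness", {
  m <- matrix(FALSE, 40, 90)
  m[10:19, 1:30] <- TRUE                   # base third only
  mask <- BinaryMask(m, 1)
  labels <- matrix(0L, 40, 90)
  labels[10:19, 1:30] <- 3L                # externally supplied grid
  grid <- new("RegionGrid", labels = labels, axis = c(0, 1))
  th <- measureThickness(mask, grid)
  expect_true(is.nan(th[["region1"]]))
  expect_true(is.nan(th[["region2"]]))
  expect_equal(th[["region3"]], 10)
})
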