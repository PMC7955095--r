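# Synthetic-data generator: determinism, truth consistency, degenerate
# parameters, monotonicity, channel placement of droplets and crystals.

test_that("identical spec and seed give bit-identical phantoms", {
  a <- generateMPMPhantom(sizePx = c(64, 64), nSlices = 2, fiberDensity = 0.1,
                          crystalCount = 1, dropletCount = 2, seed = 7)
  b <- generateMPMPhantom(sizePx = c(64, 64), nSlices = 2, fiberDensity = 0.1,
                          crystalCount = 1, dropletCount = 2, seed = 7)
  expect_identical(pixels(a$shg), pixels(b$shg))
  expect_identical(pixels(a$cars), pixels(b$cars))
  d <- generateMPMPhantom(sizePx = c(64, 64), nSlices = 2, fiberDensity = 0.1,
                          crystalCount = 1, dropletCount = 2, seed = 8)
  expect_false(identical(pixels(a$shg), pixels(b$shg)) &&
               identical(pixels(d$shg), pixels(a$shg)))
})

test_that("empty phantom is constant background with zero truth fractions", {
  ph <- generateMPMPhantom(sizePx = c(32, 32), nSlices = 2, fiberDensity = 0,
                           noiseGaussianSd = 0, noisePoissonScale = 0,
                           background = 1000, seed = 1)
  for (s in 1:2) {
    expect_true(all(pixels(ph$shg)[[s]] == 1000L))
    expect_true(all(pixels(ph$cars)[[s]] == 1000L))
  }
  expect_equal(ph$truth@collagenFractionPct, 0)
  expect_equal(ph$truth@crystalFractionPct, 0)
})

test_that("truth fractions equal mask pixel counts exactly", {
  ph <- generateMPMPhantom(sizePx = c(96, 96), nSlices = 3, fiberDensity = 0.12,
                           crystalCount = 2, dropletCount = 3, seed = 2)
  expect_identical(ph$truth@collagenFractionPct,
                   100 * mean(sapply(ph$truth@fiberMasks, mean)))
  expect_identical(ph$truth@crystalFractionPct,
                   100 * mean(sapply(ph$truth@crystalMasks, mean)))
  expect_identical(ph$truth@dropletCount, 3L)
  # truth masks share the image geometry
  expect_identical(dim(ph$truth@fiberMasks[[1]]), dim(pixels(ph$shg)[[1]]))
})

test_that("near-degenerate kappa renders all fibers at the mean angle", {
  ph <- generateMPMPhantom(sizePx = c(64, 64), nSlices = 1, fiberDensity = 0.1,
                           kappa = 1e6, meanAngleDeg = 30, seed = 1)
  expect_true(all(abs(ph$truth@anglesDeg - 30) < 1))
})

test_that("kappa = 0 gives an axially uniform angle distribution", {
  ph <- generateMPMPhantom(sizePx = c(96, 96), nSlices = 4, fiberDensity = 0.2,
                           kappa = 0, seed = 3)
  a <- ph$truth@anglesDeg
  expect_gt(diff(range(a)), 120)  # spans most of the axial half-circle
  # doubled-angle circular resultant is small for uniform axial data
  R <- sqrt(mean(cos(2 * a * pi / 180))^2 + mean(sin(2 * a * pi / 180))^2)
  expect_lt(R, 0.25)
})

test_that("circular mean of rendered angles converges to meanAngle as kappa grows", {
  err <- sapply(c(1, 10, 1000), function(k) {
    ph <- generateMPMPhantom(sizePx = c(96, 96), nSlices = 2,
                             fiberDensity = 0.15, kappa = k,
                             meanAngleDeg = 20, seed = 5)
    a2 <- 2 * ph$truth@anglesDeg * pi / 180
    m <- atan2(mean(sin(a2)), mean(cos(a2))) * 90 / pi
    abs(((m - 20 + 90) %% 180) - 90)
  })
  expect_true(all(diff(err) <= 0))
  expect_lt(err[3], 1)
})

test_that("raising fiberDensity never decreases the truth collagen fraction", {
  fr <- sapply(c(0.02, 0.05, 0.1, 0.2, 0.35), function(d)
    generateMPMPhantom(sizePx = c(64, 64), nSlices = 2, fiberDensity = d,
                       seed = 11)$truth@collagenFractionPct)
  expect_true(all(diff(fr) >= 0))
})

test_that("unreachable fiber density errors after bounded attempts", {
  # a large droplet excludes fibers from ~40 % of the field, so a 70 %
  # fiber fraction can never be reached
  expect_error(
    generateMPMPhantom(sizePx = c(32, 32), nSlices = 1, fiberDensity = 0.7,
                       fiberLengthPx = 8, fiberWidthPx = 2,
                       dropletCount = 1, dropletRadiusPx = 12, seed = 1),
    "unreachable")
})

test_that("droplets are CARS-only and crystals appear in both channels", {
  ph <- generateMPMPhantom(sizePx = c(96, 96), nSlices = 1, fiberDensity = 0,
                           crystalCount = 2, dropletCount = 3,
                           noiseGaussianSd = 0, noisePoissonScale = 0,
                           background = 0, seed = 4)
  shg <- pixels(ph$shg)[[1]]; cars <- pixels(ph$cars)[[1]]
  dro <- ph$truth@dropletMasks[[1]]; cry <- ph$truth@crystalMasks[[1]]
  expect_true(all(shg[dro] == 0))          # droplets dark in SHG
  expect_true(all(cars[dro] > 0))          # bright in CARS
  expect_true(all(shg[cry] > 0))           # crystals bright in both
  expect_true(all(cars[cry] > 0))
  # crystal truth masks are identical across channels by construction
  expect_identical(which(cry), which(ph$truth@crystalMasks[[1]]))
})

test_that("OCT phantom band spans thickness x n of optical axial path", {
  oc <- generateOCTPhantom(volumePx = c(60, 8, 120), pitchUm = c(4, 4, 2),
                           thicknessUm = c(100, 100, 100), curvatureUm = 0,
                           speckleContrast = 0, refractiveIndex = 1.33,
                           seed = 1)
  band <- oc$truth@leafletMask$crossSection
  # optical span of the band at any leaflet column
  col <- band[30, ]
  spanOptical <- sum(col) * 2           # z pitch 2 um optical
  expect_equal(spanOptical, 133, tolerance = 0.016)  # one voxel slack
  expect_equal(unname(oc$truth@thicknessProfileUm),
               c(100, 100, 100))        # truth stores geometric thickness
})

test_that("zero speckle gives a piecewise-constant volume and truth passes through", {
  oc <- generateOCTPhantom(thicknessUm = c(137, 90, 80), speckleContrast = 0,
                           seed = 2)
  expect_identical(sort(unique(as.vector(voxels(oc$volume)))),
                   c(3000, 30000))
  expect_equal(oc$truth@thicknessProfileUm,
               c(region1 = 137, region2 = 90, region3 = 80))
})

test_that("band thicker than the volume errors", {
  expect_error(generateOCTPhantom(volumePx = c(40, 8, 30),
                                  pitchUm = c(4, 4, 2),
                                  thicknessUm = c(100, 100, 100), seed = 1),
               "thicker")
})

test_that("histology phantom truth fraction tracks the request and zero is blank", {
  hp <- generateHistoPhantom(sizePx = c(128, 128), collagenFractionPct = 50,
                             seed = 1)
  expect_equal(hp$truth@collagenFractionPct, 50, tolerance = 0.01)
  expect_identical(hp$truth@collagenFractionPct,
                   100 * mean(hp$truth@leafletMask$positive))
  h0 <- generateHistoPhantom(sizePx = c(64, 64), collagenFractionPct = 0,
                             seed = 1)
  d <- colorDeconvolve(h0$rgb)
  expect_lt(max(d$psr_red), 0.05)       # no red-stain OD anywhere
})

test_that("OCT phantom determinism holds", {
  a <- generateOCTPhantom(seed = 5)
  b <- generateOCTPhantom(seed = 5)
  expect_identical(voxels(a$volume), voxels(b$volume))
})
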