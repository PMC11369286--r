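test_that("relative distance follows the d_PT/(d_PT+d_CV) definition", {
  lm <- LandmarkSet(x = c(0, 100), y = c(0, 0), class = c("PT", "CV"))
  fld <- relativeDistanceMap(lm, matrix(TRUE, 1, 101))
  r <- relDistance(fld)
  expect_equal(r[1, 26], 0.25)        # x = 25: 25/(25+75)
  expect_equal(r[1, 1], 0)            # at the PT
  expect_equal(r[1, 101], 1)          # at the CV
  # two PTs, one CV, off-axis pixel: nearest-PT distance sqrt(50)
  lm2 <- LandmarkSet(x = c(0, 0, 10), y = c(0, 10, 5),
                     class = c("PT", "PT", "CV"))
  fld2 <- relativeDistanceMap(lm2, matrix(TRUE, 11, 11))
  expect_equal(relDistance(fld2)[6, 6], sqrt(50) / (sqrt(50) + 5))
})

test_that("landmark validation rejects degenerate inputs", {
  expect_error(LandmarkSet(0, 0, "CV"), "PT")
  expect_error(LandmarkSet(c(1, 1), c(2, 2), c("CV", "PT")), "identical")
  lm <- LandmarkSet(c(0, 5), c(0, 0), c("PT", "CV"))
  expect_error(relativeDistanceMap(lm, matrix(FALSE, 4, 4)), "tissue")
})

test_that("vectorized field equals the exhaustive per-pixel oracle bit-for-bit", {
  set.seed(42)
  for (rep in 1:3) {
    n <- sample(3:6, 1)
    lm <- LandmarkSet(x = runif(n + 2, 0, 127), y = runif(n + 2, 0, 127),
                      class = c("CV", "PT", sample(c("CV", "PT"), n, TRUE)))
    tissue <- matrix(TRUE, 128, 128)
    fld <- relativeDistanceMap(lm, tissue)
    oracle <- bruteZonationField(lm, tissue)
    expect_identical(fld@dPT, oracle$dPT)
    expect_identical(fld@dCV, oracle$dCV)
    expect_identical(relDistance(fld), oracle$r)
    expect_identical(fld@lobule, oracle$lobule)
  }
})

test_that("region landmarks measure distance to the nearest mask pixel", {
  # CV given as a 3x3 block; PT stays a point
  lm <- LandmarkSet(x = c(0, 30), y = c(0, 0), class = c("PT", "CV"))
  tissue <- matrix(TRUE, 32, 32)
  cvMask <- matrix(FALSE, 32, 32)
  cvMask[15:17, 29:31] <- TRUE   # x in 28..30, y in 14..16
  fld <- relativeDistanceMap(lm, tissue, cvMask = cvMask)
  expect_equal(relDistance(fld)[16, 30], 1)        # inside the region
  # dCV at (x=20, y=15) is the gap to the region's near face, x = 28
  expect_equal(fld@dCV[16, 21], 8)
  expect_true(all(fld@lobule[fld@tissue] == 1))    # one CV component
})

test_that("r is non-decreasing along a PT-to-CV segment and scale invariant", {
  lm <- LandmarkSet(x = c(5, 90), y = c(5, 90), class = c("PT", "CV"))
  tissue <- matrix(TRUE, 96, 96)
  r <- relDistance(relativeDistanceMap(lm, tissue))
  diag_r <- r[cbind(6:91, 6:91)]   # pixels along the straight segment
  expect_true(all(diff(diag_r) >= 0))
  # scale all coordinates x2: r unchanged at corresponding points
  lm2 <- LandmarkSet(x = c(10, 180), y = c(10, 180), class = c("PT", "CV"))
  r2 <- relDistance(relativeDistanceMap(lm2, matrix(TRUE, 192, 192)))
  expect_equal(r2[cbind(2 * (5:90) + 1, 2 * (5:90) + 1)],
               r[cbind(6:91, 6:91)])
})

test_that("zonated positivity bins as specified and conserves tissue pixels", {
  sim <- simulateLobuleImage(96, 96, nCV = 2, nPT = 5, pattern = "pericentral",
                             r0 = 0.8, noise = 0, seed = 3)
  prof <- zonatedPositivity(sim$field, sim$stain, B = 10)
  frac <- positiveFraction(prof)
  expect_equal(frac[1:8], rep(0, 8))      # bins covering [0, 0.8)
  expect_true(all(frac[9:10] > 0))        # bins covering [0.8, 1]
  # brute-force recount with the same binning rule
  r <- relDistance(sim$field)[sim$tissue]
  idx <- pmin(floor(r * 10) + 1, 10)
  expect_equal(prof@tissueCount, as.numeric(tabulate(idx, 10)))
  for (B in c(2, 7, 20))
    expect_equal(sum(zonatedPositivity(sim$field, sim$stain, B)@tissueCount),
                 sum(sim$tissue))
  # degenerate stains
  expect_equal(positiveFraction(zonatedPositivity(sim$field, sim$tissue, 10)),
               rep(1, 10))
  empty <- sim$stain & FALSE
  expect_equal(positiveFraction(zonatedPositivity(sim$field, empty, 10)),
               rep(0, 10))
  # a stain pixel outside a partial tissue mask is a mask inconsistency
  partTissue <- matrix(TRUE, 20, 20); partTissue[1:5, ] <- FALSE
  lmp <- LandmarkSet(c(0, 15), c(10, 10), c("PT", "CV"))
  fldp <- relativeDistanceMap(lmp, partTissue)
  badStain <- matrix(FALSE, 20, 20); badStain[1, 1] <- TRUE
  expect_error(zonatedPositivity(fldp, badStain, 10), "mask inconsistency")
})

test_that("profile centroid summarizes zonal position", {
  edges <- seq(0, 1, length.out = 11)
  lastOnly <- new("ZonationProfile", edges = edges,
                  tissueCount = rep(10, 10),
                  positiveCount = c(rep(0, 9), 5),
                  fraction = c(rep(0, 9), 0.5))
  expect_equal(profileCentroid(lastOnly), 0.95)
  uniform <- new("ZonationProfile", edges = edges,
                 tissueCount = rep(10, 10), positiveCount = rep(3, 10),
                 fraction = rep(0.3, 10))
  expect_equal(profileCentroid(uniform), 0.5)
  none <- new("ZonationProfile", edges = edges, tissueCount = rep(10, 10),
              positiveCount = rep(0, 10), fraction = rep(0, 10))
  expect_error(profileCentroid(none), "zero positive")
  # pericentral sits farther along the axis than panlobular
  peri <- simulateLobuleImage(64, 64, 2, 4, pattern = "pericentral",
                              r0 = 0.8, noise = 0, seed = 5)
  pan <- simulateLobuleImage(64, 64, 2, 4, pattern = "panlobular",
                             noise = 0, seed = 5)
  cPeri <- profileCentroid(zonatedPositivity(peri$field, peri$stain))
  cPan <- profileCentroid(zonatedPositivity(pan$field, pan$stain))
  expect_gt(cPeri, cPan)
})
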