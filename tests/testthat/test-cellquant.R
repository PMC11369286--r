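test_that("nucleus segmentation recovers disk counts and splits fused pairs", {
  cell <- simulateCellImage(nCells = 50, radius = 4, size = 160, seed = 11)
  lab <- segmentNuclei(cell$nucleiImage, sigma = 1, minArea = 10)
  expect_equal(max(lab), 50)
  expect_equal(sort(unique(lab[lab > 0])), 1:50)   # contiguous labels
  expect_equal(max(segmentNuclei(matrix(0, 32, 32))), 0)
  # two disks fused by a thin neck -> watershed yields 2 labels
  m <- diskMatrix(64, 25, 32, 8)
  m <- diskMatrix(64, 39, 32, 8, base = m)
  expect_equal(max(segmentNuclei(m, sigma = 0, threshold = 0.5,
                                 minArea = 10)), 2)
})

test_that("cytoplasm rings are disjoint from nuclei, each other and exclusions", {
  m <- diskMatrix(64, 20, 32, 5)
  m <- diskMatrix(64, 33, 32, 5, base = m)
  nuc <- segmentNuclei(m, sigma = 0, threshold = 0.5, minArea = 10)
  expect_equal(max(nuc), 2)
  rings <- cytoplasmRings(nuc, radius = 4)
  expect_false(any(nuc > 0 & rings > 0))
  expect_true(all(tabulate(rings[rings > 0], 2) > 0))
  # adjacent nuclei: contested pixels resolve to one owner (disjoint rings)
  expect_true(all(rings %in% 0:2))
  # a fully excluded nucleus is flagged
  one <- diskMatrix(32, 16, 16, 4)
  nuc1 <- segmentNuclei(one, sigma = 0, threshold = 0.5, minArea = 10)
  expect_warning(r2 <- cytoplasmRings(nuc1, 3, excluded = matrix(TRUE, 32, 32)),
                 "no cytoplasm")
  expect_equal(attr(r2, "emptyCytoplasm"), 1L)
  expect_error(cytoplasmRings(nuc1, radius = 0), "radius")
})

test_that("specimen quantification matches fixture truth", {
  cell <- simulateCellImage(nCells = 20, gpx4PositiveFraction = 0.25,
                            nTunelFoci = 3, nHneAggregates = 2,
                            ironPositive = TRUE, seed = 6)
  nuc <- segmentNuclei(cell$nucleiImage, sigma = 1, minArea = 10)
  expect_equal(max(nuc), 20)
  cyto <- cytoplasmRings(nuc, 4)
  row <- quantifySpecimen(cellMap(nuc, cyto),
                          cell[c("tunel", "hne", "gpx4", "acsl4", "iron")],
                          pixelSize = 0.5)
  expect_equal(row$gpx4, 5 / 20)
  areaMm2 <- 128^2 * (0.5 / 1000)^2
  expect_equal(row$tunel, 3 / areaMm2)
  expect_equal(row$hne, 2 / areaMm2)
  expect_equal(as.character(row$iron), "positive")
  # all-zero marker images: zero densities, iron negative
  zero <- matrix(0, 128, 128)
  row0 <- quantifySpecimen(cellMap(nuc, cyto),
                           list(tunel = zero, hne = zero, iron = zero),
                           pixelSize = 0.5)
  expect_equal(row0$tunel, 0)
  expect_equal(row0$hne, 0)
  expect_equal(as.character(row0$iron), "negative")
  expect_error(quantifySpecimen(cellMap(nuc, cyto),
                                list(tunel = matrix(0, 10, 10))), "shape")
})

test_that("marker rows are invariant to nucleus relabeling", {
  cell <- simulateCellImage(nCells = 12, seed = 2)
  nuc <- segmentNuclei(cell$nucleiImage, sigma = 1, minArea = 10)
  cyto <- cytoplasmRings(nuc, 3)
  perm <- sample(max(nuc))
  remap <- function(lab) {
    out <- lab
    out[lab > 0] <- perm[lab[lab > 0]]
    out
  }
  imgs <- cell[c("tunel", "hne", "gpx4", "acsl4", "iron")]
  r1 <- quantifySpecimen(cellMap(nuc, cyto), imgs)
  r2 <- quantifySpecimen(cellMap(remap(nuc), remap(cyto)), imgs)
  expect_equal(r1, r2)
})

test_that("thresholds and pixel size behave monotonically", {
  cell <- simulateCellImage(nCells = 16, gpx4PositiveFraction = 0.5, seed = 8)
  nuc <- segmentNuclei(cell$nucleiImage, sigma = 1, minArea = 10)
  cm <- cellMap(nuc, cytoplasmRings(nuc, 3))
  fr <- vapply(c(0.15, 0.5, 0.95), function(th)
    quantifySpecimen(cm, list(gpx4 = cell$gpx4),
                     thresholds = list(gpx4 = th))$gpx4, numeric(1))
  expect_true(all(diff(fr) <= 0))   # raising the cutoff never adds positives
  # halving pixel size quadruples per-mm2 densities
  imgs <- list(tunel = cell$tunel)
  d1 <- quantifySpecimen(cm, imgs, pixelSize = 0.5)$tunel
  d2 <- quantifySpecimen(cm, imgs, pixelSize = 0.25)$tunel
  expect_equal(d2, 4 * d1)
})
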