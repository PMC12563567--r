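roiFull <- function(n = 40L) {
  new("CellROI", cellId = 1L, cellMask = matrix(TRUE, n, n),
      nucleusMask = rbind(matrix(TRUE, 1, n), matrix(FALSE, n - 1L, n)),
      cloneStatus = TRUE, tissueEdge = FALSE, nucleusInPlane = TRUE)
}

structuresFromMask <- function(mask, roi) {
  labelStructures(mask, roi = roi, minSizePx = 1L)
}

test_that("overlap fractions hit 0 and 1 on disjoint and identical sets", {
  roi <- roiFull()
  mA <- matrix(FALSE, 40, 40); mA[5:8, 5:8] <- TRUE; mA[20:23, 5:8] <- TRUE
  mB <- matrix(FALSE, 40, 40); mB[5:8, 30:33] <- TRUE
  a <- structuresFromMask(mA, roi)
  b <- structuresFromMask(mB, roi)
  ov <- structureOverlap(a, b)
  expect_equal(ov$doublePositiveA, 0L)
  expect_equal(ov$overlapFraction, 0)
  ovSame <- structureOverlap(a, structuresFromMask(mA, roi))
  expect_equal(ovSame$overlapFraction, 1)
  expect_equal(ovSame$doublePositiveA, 2L)
  expect_error(structureOverlap(a, structuresFromMask(matrix(FALSE, 10, 10),
                                                      roiFull(10L))),
               "shape")
})

test_that("min shared pixels gates what counts as overlap", {
  roi <- roiFull()
  mA <- matrix(FALSE, 40, 40); mA[10:13, 10:13] <- TRUE
  mB <- matrix(FALSE, 40, 40); mB[13, 13] <- TRUE; mB[13, 14] <- TRUE
  a <- structuresFromMask(mA, roi)
  b <- structuresFromMask(mB, roi)
  expect_equal(structureOverlap(a, b, minSharedPx = 1L)$doublePositiveA, 1L)
  expect_equal(structureOverlap(a, b, minSharedPx = 2L)$doublePositiveA, 0L)
})

test_that("removing overlaps deletes exactly the double positives", {
  roi <- roiFull()
  mA <- matrix(FALSE, 40, 40); mA[5:8, 5:8] <- TRUE; mA[20:23, 5:8] <- TRUE
  a <- structuresFromMask(mA, roi)
  # identical sets -> both empty
  both <- removeOverlapping(a, structuresFromMask(mA, roi))
  expect_equal(nrow(structureTable(both$a)), 0L)
  expect_equal(nrow(structureTable(both$b)), 0L)
  # disjoint sets -> identity
  mB <- matrix(FALSE, 40, 40); mB[30:33, 30:33] <- TRUE
  b <- structuresFromMask(mB, roi)
  kept <- removeOverlapping(a, b)
  expect_equal(nrow(structureTable(kept$a)), 2L)
  expect_equal(nrow(structureTable(kept$b)), 1L)
})

test_that("overlap counts and removal agree with generator ground truth", {
  spec <- sceneSpec(fieldSize = c(400L, 400L), pixelSize = 0.1, seed = 5L,
                    nucleusRatio = 0.3)
  sim <- generateCulturedCell(spec, 0.6,
    punctaSpec("puncta-A", "uniform", nSpots = 50L, radiusMeanUm = 0.25),
    punctaSpec("puncta-B", "uniform", nSpots = 50L, radiusMeanUm = 0.25))
  roi <- sim$roi
  a <- labelStructures(thresholdChannel(sim$scene, "puncta-A", roi,
                                        threshold = 30),
                       sim$scene, roi, "puncta-A")
  b <- labelStructures(thresholdChannel(sim$scene, "puncta-B", roi,
                                        threshold = 30),
                       sim$scene, roi, "puncta-B")
  ov <- structureOverlap(a, b)
  truthPairs <- sum(!is.na(sim$truth$pair_id) &
                      sim$truth$channel == "puncta-A")
  expect_equal(ov$doublePositiveA, truthPairs)
  expect_equal(ov$doublePositiveB, truthPairs)
  # removal cross-check: removed per channel equals the double-positive count
  pruned <- removeOverlapping(a, b)
  expect_equal(nrow(structureTable(a)) - nrow(structureTable(pruned$a)),
               ov$doublePositiveA)
  expect_equal(structureOverlap(pruned$a, pruned$b)$doublePositiveA, 0L)
})

test_that("pixel Pearson hits its exact anchors and is symmetric", {
  roi <- roiFull()
  set.seed(42)
  x <- matrix(runif(1600, 0, 100), 40, 40)
  scene <- new("TissueScene",
               channels = list(a = x, b = 200 - x, c = x),
               pixelSize = 0.2, metadata = list())
  expect_equal(pixelPearson(scene, roi, c("a", "c"))$R, 1)
  expect_equal(pixelPearson(scene, roi, c("a", "b"))$R, -1)
  pAB <- pixelPearson(scene, roi, c("a", "b"))
  pBA <- pixelPearson(scene, roi, c("b", "a"))
  expect_equal(pAB$R, pBA$R)
  # zero variance -> flagged undefined
  sceneFlat <- new("TissueScene",
                   channels = list(a = x, flat = matrix(3, 40, 40)),
                   pixelSize = 0.2, metadata = list())
  pf <- pixelPearson(sceneFlat, roi, c("a", "flat"))
  expect_false(pf$defined)
  expect_true(is.na(pf$R))
})

test_that("independent noise decorrelates at 10^4 pixels", {
  n <- 101L
  roi <- new("CellROI", cellId = 1L, cellMask = matrix(TRUE, n, n),
             nucleusMask = rbind(matrix(TRUE, 1, n),
                                 matrix(FALSE, n - 1L, n)),
             cloneStatus = TRUE, tissueEdge = FALSE, nucleusInPlane = TRUE)
  set.seed(11)
  scene <- new("TissueScene",
               channels = list(a = matrix(rnorm(n * n), n, n),
                               b = matrix(rnorm(n * n), n, n)),
               pixelSize = 0.2, metadata = list())
  p <- pixelPearson(scene, roi, c("a", "b"))
  expect_gte(p$n, 1e4)
  expect_lt(abs(p$R), 0.05)
  # matches an independent correlation computation
  cyto <- cytoplasmMask(roi)
  expect_equal(p$R, cor(scene@channels$a[cyto], scene@channels$b[cyto]))
})

test_that("per-cell Pearson averages over cells", {
  sim <- generateScene(sceneSpec(fieldSize = c(224L, 224L), nCells = 4L,
                                 cloneFraction = 1, seed = 19L),
                       list(punctaSpec("puncta-A", "uniform", nSpots = 15L),
                            punctaSpec("puncta-B", "uniform", nSpots = 15L)))
  avg <- averagePearson(sim$scene, sim$rois, c("puncta-A", "puncta-B"))
  expect_equal(nrow(avg$perCell), 4L)
  expect_equal(avg$meanR, mean(avg$perCell$R))
})
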