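test_that("disk cell split radius matches the analytic annulus geometry", {
  roi <- diskCellROI(211, 211, cellRadius = 100, nucleusRadius = 20)
  part <- equalAreaPartition(roi)
  # continuum: equal-area radius sqrt((R^2 + r^2) / 2)
  expected <- sqrt((100^2 + 20^2) / 2)
  idx <- which(perinuclearMask(part), arr.ind = TRUE)
  center <- c(106, 106)
  splitR <- sqrt(max((idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2))
  expect_lt(abs(splitR - expected), 1)
  expect_lte(part@areaDifference, 1L)
})

test_that("domain areas differ by at most one pixel on arbitrary cells", {
  for (seed in c(11L, 12L, 13L)) {
    sim <- smallRandomCells(seed, nCells = 3L)
    for (roi in sim$rois) {
      part <- equalAreaPartition(roi)
      expect_lte(abs(sum(perinuclearMask(part)) - sum(peripheralMask(part))),
                 1L)
      # domains tile the cytoplasm exactly
      expect_identical(perinuclearMask(part) | peripheralMask(part),
                       cellMask(roi) & !nucleusMask(roi))
      expect_false(any(perinuclearMask(part) & peripheralMask(part)))
      # ordering: every perinuclear pixel at most as far as every
      # peripheral pixel (up to ties at the split distance)
      nuc <- which(nucleusMask(roi), arr.ind = TRUE)
      dist2 <- function(mask) {
        px <- which(mask, arr.ind = TRUE)
        vapply(seq_len(nrow(px)), function(i) {
          min((nuc[, 1] - px[i, 1])^2 + (nuc[, 2] - px[i, 2])^2)
        }, numeric(1))
      }
      expect_lte(max(dist2(perinuclearMask(part))),
                 min(dist2(peripheralMask(part))) + 1e-9 +
                   0)  # ties share the boundary distance
    }
  }
})

test_that("partition is reproducible across repeated runs", {
  sim <- smallRandomCells(21L)
  roi <- sim$rois[[1]]
  p1 <- equalAreaPartition(roi)
  p2 <- equalAreaPartition(roi)
  expect_identical(perinuclearMask(p1), perinuclearMask(p2))
  expect_identical(peripheralMask(p1), peripheralMask(p2))
})

test_that("index hits its anchors on domain-confined and uniform signal", {
  roi <- diskCellROI(151, 151, 70, 15)
  part <- equalAreaPartition(roi)
  expect_identical(indexValue(distributionIndex(part, perinuclearMask(part))),
                   1)
  expect_identical(indexValue(distributionIndex(part, peripheralMask(part))),
                   -1)
  full <- distributionIndex(part, cytoplasmMask(roi))
  expect_lte(abs(indexValue(full)), 1 / full@ATotal)
})

test_that("signal outside the cytoplasm is clipped before scoring", {
  roi <- diskCellROI(101, 101, 45, 12)
  part <- equalAreaPartition(roi)
  everywhere <- matrix(TRUE, 101, 101)   # covers nucleus and background too
  res <- distributionIndex(part, everywhere)
  expect_equal(res@ATotal, sum(cytoplasmMask(roi)))
  expect_equal(res@APeri + res@APeriph, res@ATotal)
})

test_that("zero signal is flagged undefined, not an error", {
  roi <- diskCellROI(101, 101, 45, 12)
  part <- equalAreaPartition(roi)
  res <- distributionIndex(part, matrix(FALSE, 101, 101))
  expect_false(res@defined)
  expect_true(is.na(indexValue(res)))
})

test_that("an empty nucleus makes the partition fail loudly", {
  roi <- diskCellROI(101, 101, 45, 12)
  roi@nucleusMask[] <- FALSE
  expect_error(equalAreaPartition(roi), "nucleus")
})

test_that("swapping the domains negates the index (antisymmetry)", {
  sim <- smallRandomCells(31L)
  roi <- sim$rois[[1]]
  part <- equalAreaPartition(roi)
  sig <- thresholdChannel(sim$scene, "puncta-A", roi, threshold = 30)
  swapped <- new("DomainPartition", cellId = part@cellId,
                 perinuclear = peripheralMask(part),
                 peripheral = perinuclearMask(part),
                 splitDistance = splitDistance(part),
                 areaDifference = part@areaDifference)
  d <- indexValue(distributionIndex(part, sig))
  expect_equal(indexValue(distributionIndex(swapped, sig)), -d)
})

test_that("moving signal from peripheral to perinuclear increases D", {
  roi <- diskCellROI(121, 121, 55, 12)
  part <- equalAreaPartition(roi)
  sig <- matrix(FALSE, 121, 121)
  periIdx <- which(perinuclearMask(part))
  periphIdx <- which(peripheralMask(part))
  sig[periIdx[1:40]] <- TRUE
  sig[periphIdx[1:60]] <- TRUE
  d0 <- indexValue(distributionIndex(part, sig))
  sig[periphIdx[60]] <- FALSE
  sig[periIdx[41]] <- TRUE
  d1 <- indexValue(distributionIndex(part, sig))
  expect_gt(d1, d0)
})

test_that("a perinuclear placement bias of f recovers D near 2f - 1", {
  # single large cell, many small spots, known placement fraction
  spec <- sceneSpec(fieldSize = c(301L, 301L), pixelSize = 0.1,
                    nCells = 1L, cloneFraction = 1, seed = 99L,
                    noiseSd = 1)
  sim <- generateScene(spec,
    list(punctaSpec("puncta-A", "perinuclear", f = 0.75, nSpots = 250L,
                    radiusMeanUm = 0.1, radiusSdUm = 0.02)))
  roi <- sim$rois[[1]]
  part <- equalAreaPartition(roi)
  sig <- thresholdChannel(sim$scene, "puncta-A", roi, threshold = 30)
  d <- indexValue(distributionIndex(part, sig))
  expect_lt(abs(d - 0.5), 0.1)
  # verify by independent pixel counting on the same mask
  expect_identical(d, bruteForceIndex(roi, sig))
})

test_that("pipeline index equals the brute-force oracle bit-exactly", {
  for (seed in c(41L, 42L)) {
    sim <- smallRandomCells(seed, nCells = 2L)
    for (roi in sim$rois) {
      part <- equalAreaPartition(roi)
      sig <- thresholdChannel(sim$scene, "puncta-A", roi, threshold = 30)
      expect_identical(indexValue(distributionIndex(part, sig)),
                       bruteForceIndex(roi, sig))
    }
  }
})

test_that("localization categories follow the decision rules", {
  # tight cluster far from the nucleus -> ectopic_focus
  spec <- sceneSpec(fieldSize = c(301L, 301L), pixelSize = 0.2,
                    nCells = 1L, cloneFraction = 1, seed = 5L, noiseSd = 1)
  sim <- generateScene(spec,
    list(punctaSpec("puncta-A", "ectopic_focus", nSpots = 40L,
                    focusOffsetUm = 12, focusSpreadUm = 1)))
  roi <- sim$rois[[1]]
  part <- equalAreaPartition(roi)
  sig <- thresholdChannel(sim$scene, "puncta-A", roi, threshold = 30)
  res <- distributionIndex(part, sig)
  ss <- labelStructures(sig, sim$scene, roi, "puncta-A")
  call <- classifyLocalization(res, ss, roi, pixelSizeUm = 0.2,
                               localizationThresholds(offsetUm = 5,
                                                      linkRadiusUm = 3))
  expect_identical(call$category, "ectopic_focus")
  expect_gt(call$clusterDistanceUm, 5)

  # high index, no distant cluster -> perinuclear
  simP <- generateScene(sceneSpec(fieldSize = c(301L, 301L), pixelSize = 0.2,
                                  nCells = 1L, cloneFraction = 1, seed = 6L,
                                  noiseSd = 1),
    list(punctaSpec("puncta-A", "perinuclear", nSpots = 40L)))
  roiP <- simP$rois[[1]]
  partP <- equalAreaPartition(roiP)
  sigP <- thresholdChannel(simP$scene, "puncta-A", roiP, threshold = 30)
  resP <- distributionIndex(partP, sigP)
  ssP <- labelStructures(sigP, simP$scene, roiP, "puncta-A")
  callP <- classifyLocalization(resP, ssP, roiP, pixelSizeUm = 0.2,
                                localizationThresholds(offsetUm = 5,
                                                       linkRadiusUm = 3))
  expect_identical(callP$category, "perinuclear")
})

test_that("cohort table has one row per eligible clone cell", {
  sim <- generateScene(
    sceneSpec(fieldSize = c(256L, 256L), nCells = 6L, cloneFraction = 0.5,
              seed = 8L),
    list(punctaSpec("puncta-A", "perinuclear", nSpots = 25L)))
  tab <- cohortIndexTable(sim$scene, sim$rois, "puncta-A", threshold = 30)
  nClone <- sum(vapply(sim$rois, cloneStatus, logical(1)))
  expect_equal(nrow(tab), nClone)
  expect_true(all(tab$D >= -1 & tab$D <= 1))
  # per-cell values match single-cell calls
  roi <- Filter(cloneStatus, sim$rois)[[1]]
  d <- indexValue(distributionIndex(
    equalAreaPartition(roi),
    thresholdChannel(sim$scene, "puncta-A", roi, threshold = 30)))
  expect_identical(tab$D[tab$cell_id == cellId(roi)], d)
  # no eligible cells -> error
  noClone <- lapply(sim$rois, function(r) { r@cloneStatus <- FALSE; r })
  expect_error(cohortIndexTable(sim$scene, noClone, "puncta-A"),
               "no eligible")
})
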