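# Independent brute-force recomputation of the distribution index: exact
# integer squared distances computed by direct minimisation over every
# nucleus pixel, half-area split by an explicit sort with raster tie-break,
# and integer pixel counting. Shares no code with equalAreaPartition() /
# distributionIndex() beyond base R.
bruteForceIndex <- function(roi, signalMask) {
  nuc <- which(nucleusMask(roi), arr.ind = TRUE)
  cyto <- which(cellMask(roi) & !nucleusMask(roi), arr.ind = TRUE)
  d2 <- vapply(seq_len(nrow(cyto)), function(i) {
    min((nuc[, 1] - cyto[i, 1])^2 + (nuc[, 2] - cyto[i, 2])^2)
  }, numeric(1))
  ord <- order(d2, cyto[, 1], cyto[, 2])
  n <- nrow(cyto)
  target <- as.integer(ceiling(n / 2))
  nr <- nrow(signalMask)
  lin <- function(rc) (rc[, 2] - 1L) * nr + rc[, 1]
  sig <- signalMask != 0
  periLin <- lin(cyto[ord[seq_len(target)], , drop = FALSE])
  allLin <- lin(cyto)
  aPeri <- sum(sig[periLin])
  aTotal <- sum(sig[allLin])
  if (aTotal == 0L) return(NA_real_)
  (aPeri - (aTotal - aPeri)) / aTotal
}

# Small random mosaic cells (kept small so the O(n_cyto * n_nucleus)
# oracle stays cheap).
smallRandomCells <- function(seed, nCells = 2L, field = 96L) {
  sim <- generateScene(
    sceneSpec(fieldSize = c(field, field), pixelSize = 0.2,
              nCells = nCells, cloneFraction = 1, seed = seed,
              noiseSd = 1),
    list(punctaSpec("puncta-A", "uniform", nSpots = 15L,
                    radiusMeanUm = 0.25)))
  sim
}
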