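test_that("degenerate specs reproduce the base geometry exactly", {
  sp <- ensembleSpec(12, 2, 5, noiseSd = 0, seed = 3)
  out <- generateEnsemble(sp)
  base <- as.vector(t(idealChainCoords(12)))
  for (t in seq_len(nFrames(out$ensemble)))
    expect_equal(unname(frameCoords(out$ensemble)[t, ]), base)
})

test_that("two-well coordinate honours occupancy extremes and stationarity", {
  dirs <- randomModes(12, 1, region = c(3, 9), seed = 2)
  mk <- function(occ, nf = 200, seed = 1) {
    generateEnsemble(ensembleSpec(
      12, 1, nf,
      twoWell = list(direction = dirs[, 1], centerI = 0, centerII = 4,
                     occupancyII = occ, dwell = 10),
      noiseSd = 0, seed = seed))
  }
  expect_true(all(mk(0)$truth$stateSeq == 0L))
  expect_true(all(mk(1)$truth$stateSeq == 1L))
  # occupancyII = 0: every frame identical (constant at center I)
  e0 <- mk(0)$ensemble
  expect_equal(max(abs(sweep(frameCoords(e0), 2, frameCoords(e0)[1, ]))), 0)
  # empirical fraction within 3 chain SDs of the planted occupancy
  o <- mk(0.30, nf = 6000, seed = 11)
  frac <- mean(o$truth$stateSeq)
  expect_lt(abs(frac - 0.30), 3 * chainFractionSd(0.30, 10, 6000))
})

test_that("generator output is byte-identical under identical spec and seed", {
  sw <- randomModes(15, 1, seed = 4)
  sp <- function() ensembleSpec(15, 3, 40,
                                modes = list(list(direction = sw[, 1], sd = 1)),
                                noiseSd = 0.2, seed = 99)
  a <- generateEnsemble(sp()); b <- generateEnsemble(sp())
  expect_identical(frameCoords(a$ensemble), frameCoords(b$ensemble))
  expect_identical(a$truth, b$truth)
})

test_that("spec validation rejects bad modes, occupancies and frame counts", {
  v <- randomModes(10, 2, seed = 1)
  expect_error(ensembleSpec(10, 1, 10, modes = list(
    list(direction = v[, 1], sd = 1),
    list(direction = v[, 1], sd = 1))), "orthonormal")
  expect_error(ensembleSpec(10, 1, 10, twoWell = list(
    direction = v[, 2], centerI = 0, centerII = 2, occupancyII = 1.2)),
    "occupancyII")
  expect_error(ensembleSpec(10, 1, 1), "nFramesPerReplicate")
  expect_error(ensembleSpec(10, 1, 10, noiseSd = -0.1), "noiseSd")
})

test_that("planted per-residue RMSF is reached by a noise-only ensemble", {
  sp <- ensembleSpec(30, 1, 10000, noiseSd = 0.4, seed = 21)
  out <- generateEnsemble(sp)
  expect_equal(out$truth$rmsf, rep(0.4 * sqrt(3), 30))
  xyz <- frameCoords(out$ensemble)
  emp <- sqrt(colSums(matrix(colMeans(
    sweep(xyz, 2, colMeans(xyz))^2), nrow = 3)))
  expect_lt(max(abs(emp - 0.4 * sqrt(3)) / (0.4 * sqrt(3))), 0.05)
})

test_that("energy series has the requested moments and determinism", {
  expect_equal(generateEnergySeries(-250, 0, 5), rep(-250, 5))
  x <- generateEnergySeries(-250, 10, 1e5, autocorr = 0, seed = 7)
  expect_lt(abs(mean(x) + 250), 4 * 10 / sqrt(1e5))
  expect_identical(x, generateEnergySeries(-250, 10, 1e5, autocorr = 0, seed = 7))
  expect_error(generateEnergySeries(0, -1, 10), "sd")
})

test_that("melting-curve generator peaks at the planted midpoint", {
  cv <- generateMeltingCurve(62.8, steepness = 0.5,
                             baselines = list(low = 0, high = 1), noiseSd = 0)
  expect_lt(abs(fitTm(cv) - 62.8), 0.1)
  cv2 <- generateMeltingCurve(67.8, steepness = 0.5,
                              baselines = list(low = 0, high = 1), noiseSd = 0)
  expect_equal(as.numeric(fitTm(cv2)) - as.numeric(fitTm(cv)), 5,
               tolerance = 1e-3)
  expect_error(generateMeltingCurve(10), "tRange")
})

test_that("planted score tables put WT at the reference centroid", {
  g <- generateScoreTable(12, 6, plantedGroups = 3, effectSize = 5, seed = 2,
                          nucleotide = c("GDP", "GTP"))
  sc <- scoreData(g$table)
  wtRows <- sc[sc$variant == "WT", metricNames(g$table)]
  expect_true(all(wtRows == 0))
  expect_length(g$truth$labels, 12)
  # WT classifies wt-like on every metric by construction
  M <- buildMetaclassMatrix(g$table,
                            classifierConfig(threeWay = metricNames(g$table)))
  expect_true(all(M["WT", ] == 0))
})
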