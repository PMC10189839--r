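mkEns <- function(xyz, nRes, reps = rep(1L, nrow(xyz))) {
  trajectoryEnsemble(xyz, caAtomTable(nRes), "toy", "GDP",
                     replicate = reps, superposed = TRUE)
}

test_that("RMSF handles degenerate and analytic two-point cases", {
  base <- as.vector(t(idealChainCoords(5)))
  const <- mkEns(rbind(base, base, base), 5)
  expect_equal(computeRMSF(const)$rmsf, rep(0, 5))
  # residue 2 alternating +/- d along x: RMSF = d there, 0 elsewhere
  d <- 0.7
  up <- base; up[4] <- up[4] + d
  dn <- base; dn[4] <- dn[4] - d
  alt <- mkEns(rbind(up, dn, up, dn), 5)
  r <- computeRMSF(alt)$rmsf
  expect_equal(r[2], d)
  expect_equal(r[-2], rep(0, 4))
  # single-frame replicate -> error
  expect_error(computeRMSF(mkEns(matrix(base, nrow = 1), 5)), "fewer than 2")
})

test_that("RMSF is invariant to frame order and replicate-aggregated", {
  sp <- ensembleSpec(8, 2, 50, noiseSd = 0.3, seed = 5)
  ens <- generateEnsemble(sp)$ensemble
  ens@superposed <- TRUE
  r1 <- computeRMSF(ens)
  # permute frames within each replicate
  perm <- unlist(lapply(split(seq_len(nFrames(ens)), replicateIndex(ens)),
                        sample))
  ens2 <- trajectoryEnsemble(frameCoords(ens)[perm, ], atomTable(ens),
                             "toy", "GDP",
                             replicate = replicateIndex(ens)[perm],
                             superposed = TRUE)
  expect_equal(computeRMSF(ens2)$rmsf, r1$rmsf)
  per <- attr(r1, "perReplicate")
  expect_equal(rowMeans(per), r1$rmsf, ignore_attr = TRUE)
})

test_that("SSR matches brute force, is symmetric and classified by threshold", {
  expect_equal(rmsfSSR(1:10, 1:10), 0)
  L <- 169
  expect_equal(rmsfSSR(rep(2, L), rep(1, L)), L)
  set.seed(3)
  a <- runif(169); b <- runif(169)
  brute <- 0
  for (i in seq_along(a)) brute <- brute + (a[i] - b[i])^2
  expect_lt(abs(rmsfSSR(a, b) - brute), 1e-10)
  expect_equal(rmsfSSR(a, b), rmsfSSR(b, a))
  expect_error(rmsfSSR(a, b[-1]), "lengths differ")
  expect_equal(ssrClassify(1.2, 1.0), "similar")
  expect_equal(ssrClassify(1.6, 1.0), "deviated")
})

test_that("RMSD to reference is zero for self and rigid copies", {
  sp <- ensembleSpec(10, 1, 30, noiseSd = 0.2, seed = 8)
  ens <- generateEnsemble(sp)$ensemble
  ref <- caCoordsByResno(ens)   # first frame
  ser <- computeRMSDToReference(ens, ref, nSamples = 10)
  expect_equal(ser$rmsd[1], 0, tolerance = 1e-9)
  set.seed(2)
  R <- randomRotation()
  rot <- frameCoords(ens)
  for (t in seq_len(nrow(rot)))
    rot[t, ] <- as.vector(t(matrix(rot[t, ], ncol = 3, byrow = TRUE) %*% R + 3))
  rotEns <- trajectoryEnsemble(rot, atomTable(ens), "r", "GDP")
  ser0 <- computeRMSDToReference(ens, ref, nSamples = 5)
  serR <- computeRMSDToReference(rotEns, ref, nSamples = 5)
  expect_equal(serR$rmsd, ser0$rmsd, tolerance = 1e-6)
})

test_that("displacement outside the fitting region gives the analytic RMSD", {
  n <- 10; d <- 1.25
  base <- as.vector(t(idealChainCoords(n)))
  disp <- base
  movedRes <- 6:10
  disp[atomXyzCols(movedRes)[seq(3, 15, by = 3)]] <-
    disp[atomXyzCols(movedRes)[seq(3, 15, by = 3)]] + d  # +d along z
  ens <- mkEns(rbind(disp, disp), n)
  rmap <- regionMap(fixed = c(1, 5), moved = c(6, 10),
                    alignmentExclusions = "moved")
  ref <- caCoordsByResno(mkEns(matrix(base, nrow = 1), n))
  ser <- computeRMSDToReference(ens, ref, map = rmap, nSamples = 2,
                                selection = movedRes)
  expect_equal(ser$rmsd, rep(d, 2), tolerance = 1e-9)
})

test_that("inflating fluctuations does not decrease mean RMSD to a reference", {
  base <- idealChainCoords(10)
  ref <- base; rownames(ref) <- 1:10
  means <- vapply(c(0.2, 0.4), function(s) {
    sp <- ensembleSpec(10, 1, 400, noiseSd = s, seed = 31)
    ens <- generateEnsemble(sp)$ensemble
    mean(computeRMSDToReference(ens, ref, nSamples = 100)$rmsd)
  }, numeric(1))
  expect_gt(means[2], means[1])
})
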