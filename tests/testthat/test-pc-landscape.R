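planted1D <- function(n = 12, nf = 500, sdMode = 2, seed = 5, noise = 0) {
  v <- randomModes(n, 2, seed = seed)
  list(dir = v,
       ens = generateEnsemble(ensembleSpec(
         n, 1, nf, modes = list(list(direction = v[, 1], sd = sdMode)),
         noiseSd = noise, seed = seed))$ensemble)
}

test_that("PCA recovers a single planted direction with full variance", {
  p <- planted1D()
  m <- fitPCA(p$ens)
  expect_gt(abs(sum(m@loadings[, 1] * p$dir[, 1])), 0.999)
  expect_equal(m@varFrac[1], 1, tolerance = 1e-9)
})

test_that("two orthogonal modes give the analytic 4:1 variance split", {
  v <- randomModes(15, 2, seed = 7)
  ens <- generateEnsemble(ensembleSpec(
    15, 1, 10000,
    modes = list(list(direction = v[, 1], sd = 2),
                 list(direction = v[, 2], sd = 1)),
    noiseSd = 0, seed = 3))$ensemble
  m <- fitPCA(ens)
  expect_equal(m@varFrac[1], 0.8, tolerance = 0.02)
  expect_equal(m@varFrac[2], 0.2, tolerance = 0.02)
})

test_that("total variance is conserved and projections roundtrip", {
  sp <- ensembleSpec(10, 1, 300, noiseSd = 0.5, seed = 13)
  ens <- generateEnsemble(sp)$ensemble
  m <- fitPCA(ens)
  X <- frameCoords(ens, select = caIndices(ens))
  expect_equal(sum(m@sdev^2), sum(apply(X, 2, var)), tolerance = 1e-6)
  # project the model mean -> zeros; mean + component 1 -> (1, 0, ...)
  expect_equal(max(abs(projectFrames(matrix(m@center, 1), m))), 0)
  one <- matrix(m@center + m@loadings[, 1], 1)
  pr <- projectFrames(one, m)
  expect_equal(unname(pr[1, 1]), 1, tolerance = 1e-9)
  expect_lt(max(abs(pr[1, -1])), 1e-9)
  # reconstruct-then-project is the identity on the projected subspace
  P <- projectFrames(ens, m)[, 1:3, drop = FALSE]
  back <- projectFrames(reconstructFrames(P, m), m)[, 1:3]
  expect_lt(max(abs(back - P)), 1e-8)
  expect_error(projectFrames(matrix(0, 1, 7), m), "dimension mismatch")
})

test_that("PCA on top-3 reconstructed data spans the same subspace", {
  sp <- ensembleSpec(8, 1, 400, noiseSd = 0.4, seed = 17)
  ens <- generateEnsemble(sp)$ensemble
  m <- fitPCA(ens)
  P3 <- projectFrames(ens, m)[, 1:3]
  rec <- reconstructFrames(P3, m)
  m2 <- fitPCA(trajectoryEnsemble(rec, caAtomTable(8), "r", "GDP"),
               nComponents = 3)
  # principal angles between the top-3 subspaces
  sv <- svd(crossprod(m@loadings[, 1:3], m2@loadings[, 1:3]))$d
  expect_lt(max(abs(sv - 1)), 1e-6)
})

test_that("FEL normalization, undefined bins and count-scale invariance", {
  # one point per bin centre -> uniform occupancy -> F identically 0
  g <- expand.grid(x = seq(0.5, 9.5), y = seq(0.5, 9.5))
  fel <- buildFEL(as.matrix(g), nBins = 10,
                  xBreaks = seq(0, 10), yBreaks = seq(0, 10))
  expect_true(all(fel@free == 0))
  # all frames in one bin
  one <- matrix(rep(c(0.1, 0.1), 50), ncol = 2, byrow = TRUE)
  fel1 <- buildFEL(one, nBins = 5)
  expect_equal(sum(fel1@counts > 0), 1)
  expect_equal(fel1@free[fel1@counts > 0], 0)
  expect_true(all(is.na(fel1@free[fel1@counts == 0])))
  # tripling every count leaves F unchanged
  set.seed(2)
  pts <- matrix(rnorm(2000), ncol = 2)
  f1 <- buildFEL(pts, nBins = 20, xBreaks = seq(-4, 4, length.out = 21),
                 yBreaks = seq(-4, 4, length.out = 21))
  f3 <- buildFEL(rbind(pts, pts, pts), nBins = 20,
                 xBreaks = seq(-4, 4, length.out = 21),
                 yBreaks = seq(-4, 4, length.out = 21))
  expect_equal(f1@free, f3@free, tolerance = 1e-12)
  expect_equal(f1@kT, 0.0019872 * 300)
})

test_that("well detection finds the density minimum between modes", {
  set.seed(8)
  x <- c(rnorm(3000, -5), rnorm(3000, 5))
  dw <- detectWells(x)
  expect_false(dw$unimodal)
  expect_lt(abs(dw$boundary), 0.5)
  expect_true(detectWells(rnorm(2000))$unimodal)
  xa <- c(rnorm(5400, -5), rnorm(600, 5))
  dwa <- detectWells(xa)
  expect_false(dwa$unimodal)
  expect_gt(dwa$boundary, -4); expect_lt(dwa$boundary, 4)
  expect_error(detectWells(rnorm(50)), "100 samples")
})

test_that("occupancy ratio hits the 0 and 1 extremes and adds over replicates", {
  expect_equal(wellRatio(occupancyRatio(rep(-1, 10), 0, "above")), 0)
  expect_equal(wellRatio(occupancyRatio(rep(1, 10), 0, "above")), 1)
  expect_error(occupancyRatio(rnorm(10), NA, "above"), "unimodal")
  set.seed(5)
  x <- rnorm(300)
  reps <- rep(1:3, each = 100)
  ws <- occupancyRatio(x, 0.3, "above", replicate = reps)
  repRatio <- ws@countII / (ws@countI + ws@countII)
  pooled <- sum((ws@countI + ws@countII) * repRatio) /
    sum(ws@countI + ws@countII)
  expect_equal(wellRatio(ws), pooled)
})

test_that("PC standard scores are exact for constructed shifts", {
  set.seed(9)
  wt <- matrix(rnorm(3000), ncol = 3)
  expect_equal(unname(pcStandardScore(wt, wt)), c(0, 0, 0))
  mut <- wt
  mut[, 1] <- mut[, 1] + 2 * sd(wt[, 1])
  expect_equal(unname(pcStandardScore(mut, wt)), c(2, 0, 0), tolerance = 1e-9)
  degenerate <- wt; degenerate[, 2] <- 1
  expect_error(pcStandardScore(wt, degenerate), "WT SD")
})
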