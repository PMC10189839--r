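test_that("monitor distances follow the representative-point rules", {
  # two CA-only residues at a 3-4-5 configuration -> 5.0 A
  atoms <- caAtomTable(2)
  xyz <- matrix(c(0, 0, 0, 3, 4, 0), nrow = 1)
  ens <- trajectoryEnsemble(xyz, atoms, "t", "GDP")
  ms <- monitorSet("a_b", 1, 2, rule = "ca")
  expect_equal(as.numeric(computeMonitors(ens, ms)[1, 1]), 5)
  # glycine end falls back to CA; other end uses side-chain centroid
  at <- data.frame(
    eleno = 1:6,
    elety = c("N", "CA", "C", "CA", "CB", "CG"),
    resid = c("GLY", "GLY", "GLY", "GLN", "GLN", "GLN"),
    chain = "A", resno = c(1, 1, 1, 2, 2, 2), element = "",
    stringsAsFactors = FALSE)
  co <- matrix(c(9, 9, 9,  0, 0, 0,  8, 8, 8,   # GLY: CA at origin
                 5, 0, 0,  1, 2, 0,  3, 4, 0),  # GLN side chain CB+CG
               nrow = 1)
  ens2 <- trajectoryEnsemble(co, at, "t", "GDP")
  sc <- computeMonitors(ens2, monitorSet("g_q", 1, 2))
  expect_equal(as.numeric(sc[1, 1]), sqrt(2^2 + 3^2))  # centroid (2,3,0)
  expect_error(computeMonitors(ens2, monitorSet("bad", 1, 9)), "missing")
})

test_that("the shipped KRAS monitor set has exactly the ten pairs", {
  km <- krasMonitors()
  expect_equal(nrow(km), 10)
  expect_setequal(km$name, c("Q61_D92", "E62_H95", "A11_Q61", "G12_Q61",
                             "I36_A59", "Y32_Y40", "Y32_A59", "G12_T35",
                             "Q61_T35", "S17_T35"))
  ens <- generateEnsemble(ensembleSpec(100, 1, 4, noiseSd = 0.1,
                                       seed = 3))$ensemble
  expect_equal(ncol(computeMonitors(ens, km)), 10)
})

test_that("monitor distances are invariant to global rigid motion", {
  ens <- generateEnsemble(ensembleSpec(20, 1, 10, noiseSd = 0.3,
                                       seed = 12))$ensemble
  ms <- monitorSet(c("a", "b"), c(2, 5), c(11, 17), rule = "ca")
  d0 <- computeMonitors(ens, ms)
  set.seed(1)
  R <- randomRotation()
  moved <- frameCoords(ens)
  for (t in seq_len(nrow(moved)))
    moved[t, ] <- as.vector(t(matrix(moved[t, ], ncol = 3, byrow = TRUE) %*% R - 7))
  ens2 <- trajectoryEnsemble(moved, atomTable(ens), "t", "GDP")
  expect_equal(unclass(computeMonitors(ens2, ms))[, ],
               unclass(d0)[, ], tolerance = 1e-9)
})

test_that("sigma scores standardize monitor medians against WT", {
  set.seed(7)
  wt <- matrix(rnorm(4000, mean = 8), ncol = 2,
               dimnames = list(NULL, c("m1", "m2")))
  class(wt) <- c("MonitorSeries", class(wt))
  expect_equal(unname(monitorSigmaScore(wt, wt)), c(0, 0))
  mut <- wt
  mut[, 1] <- wt[, 1] + 1.0 * sd(wt[, 1])  # shifts the median by exactly 1 SD
  s <- monitorSigmaScore(mut, wt)
  expect_equal(unname(s[1]), 1, tolerance = 1e-9)
  const <- wt; const[, 2] <- 5
  expect_error(monitorSigmaScore(wt, const), "spread is zero")
})

test_that("monitor-PC correlations are exact for constructed series", {
  set.seed(3)
  proj <- matrix(rnorm(600), ncol = 3)
  mon <- cbind(mon1 = proj[, 1] + 10, mon2 = -proj[, 2] + 12)
  cc <- monitorPCCorrelation(mon, proj)
  expect_equal(cc["mon1", "PC1"], 1)
  expect_equal(cc["mon2", "PC2"], -1)
  expect_true(all(abs(cc) <= 1 + 1e-12, na.rm = TRUE))
  monC <- cbind(mon1 = rep(4, 200))
  expect_warning(out <- monitorPCCorrelation(monC, proj), "constant")
  expect_true(all(is.na(out)))
})

test_that("a planted mode stretching a monitored pair correlates with its PC", {
  n <- 20
  # the planted mode stretches the pair along its separation axis
  # (z on the ideal chain), so the monitored distance tracks the mode
  dir <- rep(0, 3 * n)
  dir[atomXyzCols(5)[3]] <- 1 / sqrt(2)   # residue 5 moves +z
  dir[atomXyzCols(15)[3]] <- -1 / sqrt(2) # residue 15 moves -z
  ens <- generateEnsemble(ensembleSpec(
    n, 1, 2000, modes = list(list(direction = dir, sd = 1.5)),
    noiseSd = 0.05, seed = 4))$ensemble
  m <- fitPCA(ens)
  pr <- projectFrames(ens, m)
  mon <- computeMonitors(ens, monitorSet("pair", 5, 15, rule = "ca"))
  cc <- monitorPCCorrelation(unclass(mon), pr)
  expect_gt(abs(cc["pair", "PC1"]), 0.9)
})

test_that("nonbonded energy reproduces hand-computed values", {
  # beyond r_off: exactly zero
  ens <- twoAtomEnsemble(c(12, 13))
  e <- computeInteractionEnergy(ens, twoAtomParams(qP = 1, qL = 1,
                                                   epsP = 0.3, epsL = 0.3),
                                proteinSel = 1L, ligandSel = 2L)
  expect_equal(e$e_int, c(0, 0))
  # LJ minimum: r = Rmin_ij inside r_on, eps_ij = 0.2 -> E = -0.2
  ensLJ <- twoAtomEnsemble(4)   # Rmin_ij = 2 + 2 = 4
  params <- twoAtomParams(rminHalfP = 2, rminHalfL = 2, epsP = 0.2, epsL = 0.2)
  eLJ <- computeInteractionEnergy(ensLJ, params, 1L, 2L)
  expect_equal(eLJ$e_lj, -0.2, tolerance = 1e-12)
  expect_equal(eLJ$e_coul, 0)
  # Coulomb: unit charges at 3.320716 A -> 332.0716 / 3.320716 = 100
  ensC <- twoAtomEnsemble(3.320716)
  eC <- computeInteractionEnergy(ensC, twoAtomParams(qP = 1, qL = 1), 1L, 2L)
  expect_equal(eC$e_coul, 100, tolerance = 1e-9)
  expect_equal(eC$e_int, eC$e_coul + eC$e_lj)
})

test_that("switching is continuous at both radii and selections validated", {
  d <- 1e-9
  expect_lt(abs(switchingFunction(10 + d) - 1), 1e-8)
  expect_lt(abs(switchingFunction(12 - d)), 1e-8)
  ens <- twoAtomEnsemble(c(10 - d, 10 + d, 12 - d, 12 + d))
  e <- computeInteractionEnergy(ens, twoAtomParams(qP = 1, qL = 1), 1L, 2L)
  expect_lt(abs(e$e_int[1] - e$e_int[2]), 1e-8)
  expect_lt(abs(e$e_int[3] - e$e_int[4]), 1e-8)
  expect_error(computeInteractionEnergy(ens, twoAtomParams(), 1L, 1L),
               "overlap")
  badParams <- nonbondedParams("XX", "YY", 0, 1, 0)
  expect_error(computeInteractionEnergy(ens, badParams, 1L, 2L),
               "missing nonbonded parameters.*P1")
})

test_that("energy is additive over disjoint ligand selections", {
  atoms <- data.frame(eleno = 1:3, elety = c("P1", "L1", "L2"),
                      resid = c("PRO", "LIG", "LIG"), chain = "A",
                      resno = 1:3, element = "", stringsAsFactors = FALSE)
  xyz <- matrix(c(0, 0, 0, 4, 0, 0, 0, 6, 0), nrow = 1)
  ens <- trajectoryEnsemble(xyz, atoms, "t", "GDP")
  params <- nonbondedParams(c("P1", "L1", "L2"), c("PRO", "LIG", "LIG"),
                            charge = c(0.5, -0.4, 0.8),
                            rminHalf = c(1.8, 1.9, 2.0),
                            epsilon = c(0.1, 0.12, 0.2))
  eBoth <- computeInteractionEnergy(ens, params, 1L, c(2L, 3L))
  e1 <- computeInteractionEnergy(ens, params, 1L, 2L)
  e2 <- computeInteractionEnergy(ens, params, 1L, 3L)
  expect_equal(eBoth$e_int, e1$e_int + e2$e_int, tolerance = 1e-12)
})

test_that("energy series CSV ingestion validates and summarizes", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeEnergySeries(rep(-300, 50), f)
  e <- ingestEnergySeries(f)
  expect_equal(attr(e, "summary")[["mean"]], -300)
  expect_equal(attr(e, "summary")[["sd"]], 0)
  # roundtrip
  x <- generateEnergySeries(-250, 10, 1e5, seed = 13)
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeEnergySeries(x, f2)
  e2 <- ingestEnergySeries(f2)
  expect_equal(e2$e_int, x)
  expect_lt(abs(attr(e2, "summary")[["mean"]] + 250), 0.2)
  # bad line is named
  writeLines(c("frame,energy", "1,-3.5", "2,oops"), f)
  expect_error(ingestEnergySeries(f), "line 3")
})
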