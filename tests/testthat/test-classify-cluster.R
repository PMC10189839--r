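test_that("three-way classification uses inclusive 1-sigma boundaries", {
  expect_equal(threeWayClassify(5, 5, 2), "wt-like")
  expect_equal(threeWayClassify(7, 5, 2), "high")    # z = 1 exactly
  expect_equal(threeWayClassify(5 - 2 * 2.3, 5, 2), "low")
  expect_error(threeWayClassify(1, 0, 0), "wtSd")
  # scale equivariance: affine map of metric and WT stats preserves labels
  set.seed(2)
  v <- rnorm(50); m <- 0.3; s <- 1.7
  a <- 4.2; b <- -11
  expect_identical(threeWayClassify(v, m, s),
                   threeWayClassify(a * v + b, a * m + b, a * s))
})

test_that("the energy scheme yields exactly nine labelled groups", {
  expect_equal(energyNineGroup(0.2, 0.5)$label, "GDP Neutral GTP Neutral")
  expect_equal(energyNineGroup(0.3, 2.8)$label, "GDP Neutral GTP Unstable")
  expect_equal(energyNineGroup(-1.5, -1)$label, "GDP Stable GTP Stable")
  zs <- c(-2, 0, 2)
  labs <- outer(zs, zs, function(g, t) energyNineGroup(g, t)$label)
  expect_equal(length(unique(as.vector(labs))), 9)
  expect_setequal(as.vector(labs), energyGroupLabels())
})

test_that("RMSD two-way combinations label both states", {
  expect_equal(rmsdTwoWay(0, 0)$label, "GTP Closed GDP Closed")
  expect_equal(rmsdTwoWay(2, 2)$label, "GTP Deviated GDP Deviated")
  expect_equal(rmsdTwoWay(2, 0)$label, "GTP Closed GDP Deviated")
  expect_equal(rmsdTwoWay(-1, 0.5)$label, "GTP Closed GDP Deviated")
})

mkTable <- function(values, wtSd = 1, states = c("GDP", "GTP")) {
  # values: named list metric -> variants x states matrix (WT row first)
  metrics <- names(values)
  nv <- nrow(values[[1]])
  variants <- c("WT", sprintf("V%d", seq_len(nv - 1)))
  rows <- list()
  for (si in seq_along(states)) {
    df <- data.frame(variant = variants, nucleotide = states[si],
                     stringsAsFactors = FALSE)
    for (m in metrics) df[[m]] <- values[[m]][, si]
    rows[[si]] <- df
  }
  wt <- expand.grid(metric = metrics, nucleotide = states,
                    stringsAsFactors = FALSE)
  wt$mean <- 0; wt$sd <- wtSd; wt$median <- 0
  scoreTable(do.call(rbind, rows), wt)
}

test_that("meta-class matrix matches elementwise classification", {
  # all variants identical to WT -> every column zero
  z <- matrix(0, nrow = 4, ncol = 2)
  tab0 <- mkTable(list(m1 = z, m2 = z))
  M0 <- buildMetaclassMatrix(tab0, classifierConfig(threeWay = c("m1", "m2")))
  expect_true(all(M0 == 0))
  # a single +2 sigma excursion lights exactly one Above column
  z1 <- z; z1[3, 2] <- 2
  M1 <- buildMetaclassMatrix(mkTable(list(m1 = z1, m2 = z)),
                             classifierConfig(threeWay = c("m1", "m2")))
  expect_equal(sum(M1), 1)
  expect_equal(M1["V2", "m1 Above GTP"], 1L)
  # random tables vs brute-force elementwise oracle
  set.seed(42)
  for (i in 1:40) {
    vals <- list(m1 = matrix(rnorm(10), 5), m2 = matrix(rnorm(10), 5),
                 eint = matrix(rnorm(10), 5), rmsd_a = matrix(rnorm(10), 5))
    vals$m1[1, ] <- 0; vals$m2[1, ] <- 0; vals$eint[1, ] <- 0; vals$rmsd_a[1, ] <- 0
    tab <- mkTable(vals)
    M <- buildMetaclassMatrix(tab)   # default config by name prefixes
    sc <- scoreData(tab)
    for (v in unique(sc$variant)) {
      for (m in c("m1", "m2")) {
        for (st in c("GDP", "GTP")) {
          zv <- sc[[m]][sc$variant == v & sc$nucleotide == st]
          expect_identical(M[v, sprintf("%s Above %s", m, st)],
                           as.integer(zv >= 1))
          expect_identical(M[v, sprintf("%s Below %s", m, st)],
                           as.integer(zv <= -1))
        }
      }
      zg <- sc$eint[sc$variant == v & sc$nucleotide == "GDP"]
      zt <- sc$eint[sc$variant == v & sc$nucleotide == "GTP"]
      lab <- energyNineGroup(zg, zt)$label
      expect_identical(M[v, paste("eint", lab)], 1L)
      rg <- sc$rmsd_a[sc$variant == v & sc$nucleotide == "GDP"]
      rt <- sc$rmsd_a[sc$variant == v & sc$nucleotide == "GTP"]
      expect_identical(M[v, paste("rmsd_a", rmsdTwoWay(rg, rt)$label)], 1L)
    }
  }
})

test_that("k-means grouping handles degenerate k and is deterministic", {
  g <- generateScoreTable(12, 5, plantedGroups = 2, effectSize = 4, seed = 3)
  km1 <- kmeansGroups(g$table, "GTP", k = 1, seed = 1)
  expect_equal(length(unique(km1$assignments)), 1)
  km <- kmeansGroups(g$table, "GTP", k = 2, seed = 5)
  km2 <- kmeansGroups(g$table, "GTP", k = 2, seed = 5)
  expect_identical(km$assignments, km2$assignments)
  expect_error(kmeansGroups(g$table, "GTP", k = 99), "exceed")
  # duplicated rows, k = number of distinct rows -> zero inertia
  sc <- data.frame(variant = c("WT", "A", "B", "C"), nucleotide = "GTP",
                   m1 = c(0, 0, 3, 3), m2 = c(0, 0, -2, -2))
  wt <- data.frame(metric = c("m1", "m2"), nucleotide = "GTP",
                   mean = 0, sd = 1, median = 0)
  kmd <- kmeansGroups(scoreTable(sc, wt), "GTP", k = 2, seed = 1)
  expect_equal(kmd$totWithinSS, 0)
})

test_that("group signatures rank by occupancy and retain planted blocks", {
  M <- matrix(0L, nrow = 9, ncol = 6,
              dimnames = list(sprintf("V%d", 1:9),
                              sprintf("mc%d", 1:6)))
  groups <- setNames(rep(1:3, each = 3), rownames(M))
  # block structure: group g fully occupies columns 2g-1 and 2g
  for (g in 1:3) M[groups == g, c(2 * g - 1, 2 * g)] <- 1L
  sig <- groupSignatures(groups, M, topN = 2)
  expect_setequal(sig$retained, colnames(M))
  s1 <- sig$signatures[["1"]]
  expect_equal(s1$occupancy[1:2], c(1, 1))
  expect_setequal(s1$metaclass[1:2], c("mc1", "mc2"))
  # an all-zero meta-class is never retained while nonzero ones exist
  M2 <- cbind(M, dead = 0L)
  sig2 <- groupSignatures(groups, M2, topN = 2)
  expect_false("dead" %in% sig2$retained)
  expect_error(groupSignatures(setNames(integer(0), character(0)), M), "share")
})

test_that("cross-correlation has unit diagonal and detects independence", {
  set.seed(31)
  n <- 200
  sc <- data.frame(variant = c("WT", sprintf("V%d", 1:(n - 1))),
                   nucleotide = "GTP",
                   m1 = rnorm(n), m2 = rnorm(n))
  sc$m3 <- -sc$m1
  wt <- data.frame(metric = c("m1", "m2", "m3"), nucleotide = "GTP",
                   mean = 0, sd = 1, median = 0)
  cc <- crossCorrelation(scoreTable(sc, wt), "GTP")
  expect_equal(diag(cc), c(m1 = 1, m2 = 1, m3 = 1))
  expect_equal(cc["m1", "m3"], -1)
  expect_lt(abs(cc["m1", "m2"]), 0.2)
  expect_equal(cc, t(cc))
})

test_that("PCA embedding preserves rank-2 geometry and separates clusters", {
  set.seed(12)
  n <- 40
  basis <- qr.Q(qr(matrix(rnorm(12), 6)))[, 1:2]
  low <- matrix(rnorm(2 * n), ncol = 2)
  sc <- data.frame(variant = c("WT", sprintf("V%d", 1:(n - 1))),
                   nucleotide = "GTP", stringsAsFactors = FALSE)
  m <- low %*% t(basis)
  for (j in 1:6) sc[[paste0("m", j)]] <- m[, j]
  wt <- data.frame(metric = paste0("m", 1:6), nucleotide = "GTP",
                   mean = 0, sd = 1, median = 0)
  emb <- embed2D(scoreTable(sc, wt), method = "pca", seed = 1)
  expect_equal(nrow(emb), n)
  d0 <- dist(m); d2 <- dist(cbind(emb$dim1, emb$dim2))
  expect_lt(max(abs(d0 - d2)), 1e-6)
  # planted separated clusters keep a clean silhouette in the embedding
  g <- generateScoreTable(30, 6, plantedGroups = 2, effectSize = 8, seed = 5)
  emb2 <- embed2D(g$table, seed = 2)
  nonWt <- emb2$variant != "WT"
  sil <- meanSilhouette(cbind(emb2$dim1, emb2$dim2)[nonWt, ],
                        g$truth$labels)
  expect_gt(sil, 0.5)
})
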