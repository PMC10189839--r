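#' @include AllClasses.R
NULL

#' Generate a per-frame interaction-energy series
#'
#' AR(1) series with the stated stationary mean and SD:
#' `x_t = mean + phi (x_{t-1} - mean) + eps_t`, with innovation variance
#' `sd^2 (1 - phi^2)` so the stationary SD is exactly `sd`.
#'
#' @param mean stationary mean (kcal/mol).
#' @param sd stationary SD (kcal/mol), `>= 0`.
#' @param n series length, `>= 1`.
#' @param autocorr lag-1 autocorrelation `phi` in \[0, 1).
#' @param seed integer seed.
#' @return Numeric vector of length `n`.
#' @export
generateEnergySeries <- function(mean, sd, n, autocorr = 0, seed = 1L) {
  if (sd < 0) stop("sd must be >= 0")
  if (n < 1) stop("n must be >= 1")
  if (autocorr < 0 || autocorr >= 1) stop("autocorr must lie in [0, 1)")
  set.seed(seed)
  if (sd == 0) return(rep(mean, n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, mean, sd)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - autocorr^2))
    for (t in 2:n) x[t] <- mean + autocorr * (x[t - 1] - mean) + innov[t - 1]
  }
  x
}

#' Generate a synthetic thermal-unfolding curve
#'
#' Logistic transition between a low and a high baseline with midpoint
#' `tm`, plus Gaussian noise, sampled on a regular temperature grid.
#' With flat baselines and zero noise the first derivative of the curve
#' peaks exactly at `tm`.
#'
#' @param tm melting midpoint (deg C), within `tRange`.
#' @param steepness logistic steepness (1/deg C), `> 0`.
#' @param baselines list with `low`, `high` (ratio units) and optional
#'   `slopeLow`, `slopeHigh` (ratio per deg C, default 0).
#' @param noiseSd Gaussian noise SD on the ratio.
#' @param tRange length-2 temperature range (deg C), default 20-95.
#' @param step grid spacing (deg C), default 0.5.
#' @param seed integer seed.
#' @return `data.frame` with columns `temperature_C`, `ratio_350_330`.
#' @examples
#' cv <- generateMeltingCurve(62.8, steepness = 0.5, noiseSd = 0)
#' fitTm(cv)
#' @export
generateMeltingCurve <- function(tm, steepness = 0.5,
                                 baselines = list(low = 0.8, high = 1.1),
                                 noiseSd = 0, tRange = c(20, 95),
                                 step = 0.5, seed = 1L) {
  if (tm < tRange[1] || tm > tRange[2]) stop("tm must lie within tRange")
  if (steepness <= 0) stop("steepness must be > 0")
  set.seed(seed)
  tt <- seq(tRange[1], tRange[2], by = step)
  sl <- if (is.null(baselines$slopeLow)) 0 else baselines$slopeLow
  sh <- if (is.null(baselines$slopeHigh)) 0 else baselines$slopeHigh
  pre <- baselines$low + sl * (tt - tm)
  post <- baselines$high + sh * (tt - tm)
  frac <- 1 / (1 + exp(-steepness * (tt - tm)))
  ratio <- pre + (post - pre) * frac + stats::rnorm(length(tt), 0, noiseSd)
  data.frame(temperature_C = tt, ratio_350_330 = ratio)
}

#' Generate a score table with planted variant groups
#'
#' Variants are drawn around group-specific metric centroids separated
#' by `effectSize` WT-SD units (WT SD is 1 for every metric); the
#' designated WT row sits exactly at the global reference centroid
#' (the origin). Group centroid directions are mutually orthonormal, so
#' centroids are `effectSize` apart from the origin along independent
#' axes in metric space.
#'
#' @param nVariants number of non-WT variants.
#' @param nMetrics number of metric columns.
#' @param plantedGroups number of planted groups, `>= 1`.
#' @param effectSize centroid separation in WT-SD units.
#' @param seed integer seed.
#' @param nucleotide states to generate rows for (same group structure,
#'   independent noise per state).
#' @return A list with elements
#'   \describe{
#'     \item{table}{a [ScoreTable-class] with WT reference statistics
#'       mean 0 / SD 1 / median 0 per metric.}
#'     \item{truth}{planted group label per variant (WT is `NA`), and
#'       the group centroids.}
#'   }
#' @export
generateScoreTable <- function(nVariants, nMetrics, plantedGroups = 1L,
                               effectSize = 0, seed = 1L,
                               nucleotide = "GTP") {
  if (plantedGroups < 1) stop("plantedGroups must be >= 1")
  if (plantedGroups > nMetrics)
    stop("plantedGroups must not exceed nMetrics (orthonormal centroids)")
  set.seed(seed)
  dirs <- qr.Q(qr(matrix(stats::rnorm(nMetrics * plantedGroups), nMetrics)))
  centroids <- effectSize * t(dirs[, seq_len(plantedGroups), drop = FALSE])
  labels <- rep_len(seq_len(plantedGroups), nVariants)
  metricNames <- sprintf("metric_%02d", seq_len(nMetrics))
  rows <- list()
  for (st in nucleotide) {
    vals <- centroids[labels, , drop = FALSE] +
      matrix(stats::rnorm(nVariants * nMetrics), nVariants)
    m <- rbind(rep(0, nMetrics), vals)   # WT row exactly at the reference
    df <- data.frame(variant = c("WT", sprintf("V%03d", seq_len(nVariants))),
                     nucleotide = st, stringsAsFactors = FALSE)
    df[metricNames] <- as.data.frame(m)
    rows[[st]] <- df
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  wt <- expand.grid(metric = metricNames, nucleotide = nucleotide,
                    stringsAsFactors = FALSE)
  wt$mean <- 0; wt$sd <- 1; wt$median <- 0
  list(table = scoreTable(scores, wt),
       truth = list(labels = labels, centroids = centroids))
}
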