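#' @include score-table.R
NULL

#' Three-way WT-standardized classification
#'
#' `z = (value - wtMean) / wtSd`; `z >= 1` is `"high"`, `z <= -1` is
#' `"low"`, otherwise `"wt-like"` (boundaries inclusive to high/low).
#' The 1-sigma threshold is configurable.
#'
#' @param value metric value(s).
#' @param wtMean,wtSd wild-type reference mean and SD, `wtSd > 0`.
#' @param threshold sigma threshold, default 1.
#' @return Character vector over `value` with levels
#'   `"low"`, `"wt-like"`, `"high"`.
#' @export
threeWayClassify <- function(value, wtMean, wtSd, threshold = 1) {
  if (any(!is.finite(wtSd) | wtSd <= 0)) stop("wtSd must be > 0")
  z <- (value - wtMean) / wtSd
  ifelse(z >= threshold, "high", ifelse(z <= -threshold, "low", "wt-like"))
}

#' Nine-group interaction-energy classification
#'
#' Classifies a variant's nucleotide interaction energy in two
#' dimensions (GDP and GTP z-scores against the WT mean energy, where
#' more-negative energy is more favorable): per dimension, `z <= -1` is
#' `"Stable"`, `|z| < 1` is `"Neutral"`, `z >= 1` is `"Unstable"`. The
#' label set of the pair has exactly 9 members.
#'
#' @param gdpZ,gtpZ z-scores of mean interaction energy vs WT per
#'   state.
#' @param threshold sigma threshold, default 1.
#' @return `data.frame` with columns `gdp`, `gtp`, `label`
#'   (e.g. `"GDP Neutral GTP Unstable"`).
#' @export
energyNineGroup <- function(gdpZ, gtpZ, threshold = 1) {
  cat1 <- function(z) ifelse(z <= -threshold, "Stable",
                      ifelse(z >= threshold, "Unstable", "Neutral"))
  g <- cat1(gdpZ); t <- cat1(gtpZ)
  data.frame(gdp = g, gtp = t,
             label = sprintf("GDP %s GTP %s", g, t),
             stringsAsFactors = FALSE)
}

#' All nine energy-group labels
#'
#' @return Character vector of the 9 possible labels of
#'   [energyNineGroup()].
#' @export
energyGroupLabels <- function() {
  cats <- c("Stable", "Neutral", "Unstable")
  as.vector(outer(cats, cats,
                  function(g, t) sprintf("GDP %s GTP %s", g, t)))
}

#' Two-way RMSD classification per nucleotide state
#'
#' RMSD summaries against a binding-competent reference conformation
#' are split into WT-like (`"Closed"`, `|z| < 1`) or `"Deviated"`
#' (`|z| >= 1`) per state, and combined into labels like
#' `"GTP Closed GDP Deviated"`.
#'
#' @param gdpZ,gtpZ z-scores of the variant's RMSD summary vs WT per
#'   state.
#' @param threshold sigma threshold, default 1.
#' @return `data.frame` with columns `gdp`, `gtp`, `label`.
#' @export
rmsdTwoWay <- function(gdpZ, gtpZ, threshold = 1) {
  cat1 <- function(z) ifelse(abs(z) < threshold, "Closed", "Deviated")
  g <- cat1(gdpZ); t <- cat1(gtpZ)
  data.frame(gdp = g, gtp = t,
             label = sprintf("GTP %s GDP %s", t, g),
             stringsAsFactors = FALSE)
}

#' Classifier configuration for the meta-class matrix
#'
#' @param threeWay metric names classified three-way (low / wt-like /
#'   high) per state.
#' @param energy optional metric name carrying mean interaction energy
#'   (classified with the 9-group scheme across GDP and GTP).
#' @param rmsd optional character vector of RMSD metric names (one per
#'   reference conformation), each classified two-way per state and
#'   combined.
#' @param threshold sigma threshold, default 1.
#' @return List of class `"ClassifierConfig"`.
#' @export
classifierConfig <- function(threeWay = character(), energy = NULL,
                             rmsd = character(), threshold = 1) {
  structure(list(threeWay = threeWay, energy = energy, rmsd = rmsd,
                 threshold = threshold),
            class = "ClassifierConfig")
}

#' Default classifier configuration for a ScoreTable
#'
#' Metrics named like `rmsd_*` become two-way RMSD combinations,
#' `eint*` the 9-group energy scheme, everything else three-way.
#'
#' @param x a [ScoreTable-class].
#' @return A `"ClassifierConfig"`.
#' @export
defaultClassifierConfig <- function(x) {
  mn <- metricNames(x)
  rmsd <- grep("^rmsd", mn, value = TRUE)
  energy <- grep("^eint", mn, value = TRUE)
  classifierConfig(
    threeWay = setdiff(mn, c(rmsd, energy)),
    energy = if (length(energy)) energy[1] else NULL,
    rmsd = rmsd)
}

.zFor <- function(x, metric, st) {
  sc <- x@scores[x@scores$nucleotide == st, , drop = FALSE]
  w <- wtStat(x, metric, st)
  if (!is.finite(w$sd) || w$sd <= 0)
    stop(sprintf("WT SD is zero for metric '%s' (%s)", metric, st))
  stats::setNames((sc[[metric]] - w$mean) / w$sd, sc$variant)
}

#' Build the binary variant x meta-class matrix
#'
#' One binary column per (three-way metric, state, non-wt-like
#' category) — named like `"metric_01 Above GTP"` / `"metric_01 Below
#' GDP"` — plus the 9 energy-group columns and the four two-way RMSD
#' combination columns per RMSD reference. The column count is
#' emergent from the configuration, not hard-coded.
#'
#' @param x a [ScoreTable-class] containing both states needed by the
#'   configured energy/RMSD schemes.
#' @param config a `"ClassifierConfig"`; default from
#'   [defaultClassifierConfig()].
#' @return Binary integer matrix, rows = variants, columns =
#'   meta-classes; column names unique.
#' @export
buildMetaclassMatrix <- function(x, config = defaultClassifierConfig(x)) {
  states <- unique(x@scores$nucleotide)
  variants <- unique(x@scores$variant)
  cols <- list()
  for (m in config$threeWay) {
    # classify only in states where WT statistics exist for this metric
    mStates <- intersect(states, x@wt$nucleotide[x@wt$metric == m])
    if (!length(mStates)) stop(sprintf("metric '%s' has no WT statistics", m))
    for (st in mStates) {
      z <- .zFor(x, m, st)
      lab <- threeWayClassify(z, 0, 1, config$threshold)
      lab <- lab[match(variants, names(z))]
      cols[[sprintf("%s Above %s", m, st)]] <- as.integer(lab == "high")
      cols[[sprintf("%s Below %s", m, st)]] <- as.integer(lab == "low")
    }
  }
  if (!is.null(config$energy)) {
    if (!all(c("GDP", "GTP") %in% states))
      stop("energy nine-group scheme needs both GDP and GTP rows")
    zg <- .zFor(x, config$energy, "GDP")[variants]
    zt <- .zFor(x, config$energy, "GTP")[variants]
    nine <- energyNineGroup(zg, zt, config$threshold)
    for (lab in energyGroupLabels())
      cols[[sprintf("%s %s", config$energy, lab)]] <- as.integer(nine$label == lab)
  }
  for (m in config$rmsd) {
    if (!all(c("GDP", "GTP") %in% states))
      stop("RMSD two-way combinations need both GDP and GTP rows")
    zg <- .zFor(x, m, "GDP")[variants]
    zt <- .zFor(x, m, "GTP")[variants]
    two <- rmsdTwoWay(zg, zt, config$threshold)
    for (lab in unique(c("GTP Closed GDP Closed", "GTP Closed GDP Deviated",
                         "GTP Deviated GDP Closed", "GTP Deviated GDP Deviated")))
      cols[[sprintf("%s %s", m, lab)]] <- as.integer(two$label == lab)
  }
  out <- do.call(cbind, cols)
  rownames(out) <- variants
  out
}
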