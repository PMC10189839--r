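#' @include trajectory-ensemble.R
NULL

#' Define a set of residue-pair distance monitors
#'
#' Each monitor is a literature-derived residue pair whose distance
#' tracks a biophysical hallmark of switch-regulated GTPase activity
#' (switch opening, inter-switch coordination, nucleotide/Mg
#' coordination). The representative point of a residue is the centroid
#' of its side-chain heavy atoms under the default rule (`"sidechain"`,
#' falling back to CA for glycine or CA-only models); `"ca"` uses the
#' CA atom directly; a named atom pair may be given as
#' `"atom:ND2-OD1"`-style overrides via the `atomA`/`atomB` columns.
#'
#' @param name monitor names.
#' @param resA,resB 1-based residue indices, `resA != resB`.
#' @param rule per-monitor rule, `"sidechain"` (default) or `"ca"`.
#' @param theme biophysical theme label.
#' @param atomA,atomB optional atom-name overrides per end.
#' @return `data.frame` of class `"MonitorSet"`.
#' @seealso [krasMonitors()], [computeMonitors()]
#' @export
monitorSet <- function(name, resA, resB, rule = "sidechain", theme = "",
                       atomA = NA_character_, atomB = NA_character_) {
  if (any(resA == resB)) stop("monitor residues must differ")
  out <- data.frame(name = name, resA = as.integer(resA), resB = as.integer(resB),
                    rule = rep_len(rule, length(name)),
                    theme = rep_len(theme, length(name)),
                    atomA = rep_len(atomA, length(name)),
                    atomB = rep_len(atomB, length(name)),
                    stringsAsFactors = FALSE)
  class(out) <- c("MonitorSet", "data.frame")
  out
}

#' The ten default KRAS distance monitors
#'
#' The ten literature-derived residue pairs shipped with the package
#' (also available as `extdata/kras_monitors.csv`): Q61-D92, E62-H95,
#' A11-Q61, G12-Q61, I36-A59, Y32-Y40, Y32-A59, G12-T35, Q61-T35 and
#' S17-T35, grouped into four biophysical themes (switch2-helix
#' coupling, p-loop to switch2 opening, switch1-switch2 coordination,
#' nucleotide/Mg coordination).
#'
#' @return A `"MonitorSet"` with 10 rows.
#' @export
krasMonitors <- function() {
  p <- system.file("extdata", "kras_monitors.csv", package = "SwitchScore",
                   mustWork = TRUE)
  df <- utils::read.csv(p, stringsAsFactors = FALSE)
  monitorSet(df$name, df$resA, df$resB, df$rule, df$theme)
}

.BACKBONE <- c("N", "CA", "C", "O", "OXT", "H", "HA", "HN", "H1", "H2", "H3")

# representative point of one residue in every frame: frames x 3
.residuePoint <- function(ensemble, resno, rule, atomName = NA) {
  at <- atomTable(ensemble)
  rows <- which(at$resno == resno)
  if (!length(rows)) stop(sprintf("residue %d not present", resno))
  if (!is.na(atomName)) {
    rows <- rows[at$elety[rows] == atomName]
    if (!length(rows)) stop(sprintf("atom %s of residue %d not present", atomName, resno))
  } else if (rule == "ca") {
    rows <- rows[at$elety[rows] == "CA"]
  } else {
    # side-chain heavy atoms; CA fallback for glycine / CA-only models
    sc <- rows[!(at$elety[rows] %in% .BACKBONE) &
                 !grepl("^H", at$elety[rows])]
    rows <- if (length(sc)) sc else rows[at$elety[rows] == "CA"]
  }
  if (!length(rows)) stop(sprintf("no representative atoms for residue %d", resno))
  xyz <- frameCoords(ensemble)
  pts <- array(0, dim = c(nFrames(ensemble), 3))
  for (a in rows) pts <- pts + xyz[, atomXyzCols(a), drop = FALSE]
  pts / length(rows)
}

#' Per-frame monitor distances of an ensemble
#'
#' For each monitor, the Euclidean distance per frame between the two
#' residues' representative points under the monitor's atom rule.
#'
#' @param ensemble a [TrajectoryEnsemble-class].
#' @param monitors a `"MonitorSet"`, e.g. [krasMonitors()].
#' @return Numeric matrix frames x monitors (Angstrom), of class
#'   `"MonitorSeries"`, with the monitor table in `attr(, "monitors")`
#'   and per-monitor medians in `attr(, "medians")`.
#' @export
computeMonitors <- function(ensemble, monitors) {
  resno <- atomTable(ensemble)$resno
  out <- matrix(NA_real_, nrow = nFrames(ensemble), ncol = nrow(monitors),
                dimnames = list(NULL, monitors$name))
  for (i in seq_len(nrow(monitors))) {
    m <- monitors[i, ]
    if (!all(c(m$resA, m$resB) %in% resno))
      stop(sprintf("monitor '%s': residue %d or %d missing", m$name, m$resA, m$resB))
    a <- .residuePoint(ensemble, m$resA, m$rule, m$atomA)
    b <- .residuePoint(ensemble, m$resB, m$rule, m$atomB)
    out[, i] <- sqrt(rowSums((a - b)^2))
  }
  attr(out, "monitors") <- monitors
  attr(out, "medians") <- apply(out, 2, stats::median)
  class(out) <- c("MonitorSeries", class(out))
  out
}

#' Sigma-from-WT-median score of monitor distances
#'
#' Per monitor, the number of wild-type standard deviations separating
#' the mutant's median distance from the wild-type median:
#' `score = (median_mut - median_WT) / SD_WT`, where `SD_WT` is the SD
#' of the pooled wild-type per-frame distribution.
#'
#' @param mutantSeries,wtSeries `"MonitorSeries"` matrices sharing
#'   monitor columns.
#' @return Named numeric vector, one score per monitor.
#' @export
monitorSigmaScore <- function(mutantSeries, wtSeries) {
  stopifnot(identical(colnames(mutantSeries), colnames(wtSeries)))
  vapply(colnames(mutantSeries), function(j) {
    s <- stats::sd(wtSeries[, j])
    if (!is.finite(s) || s <= 0)
      stop(sprintf("WT spread is zero for monitor '%s'", j))
    (stats::median(mutantSeries[, j]) - stats::median(wtSeries[, j])) / s
  }, numeric(1))
}

#' Correlations between monitor distances and PC projections
#'
#' Pearson correlation of each monitor's per-frame distance against
#' each of the leading PC projections, on frame-aligned series.
#' Constant series yield `NA` with a warning.
#'
#' @param monitorSeries frames x monitors matrix.
#' @param projections frames x >=k PC projection matrix of the same
#'   frames.
#' @param k number of leading components, default 3.
#' @return monitors x k correlation matrix.
#' @export
monitorPCCorrelation <- function(monitorSeries, projections, k = 3L) {
  if (nrow(monitorSeries) != nrow(projections))
    stop("monitor series and projections must have aligned frame counts")
  k <- min(k, ncol(projections))
  out <- matrix(NA_real_, ncol(monitorSeries), k,
                dimnames = list(colnames(monitorSeries), paste0("PC", seq_len(k))))
  for (j in seq_len(ncol(monitorSeries))) {
    if (stats::sd(monitorSeries[, j]) == 0) {
      warning(sprintf("monitor '%s' is constant; correlation undefined",
                      colnames(monitorSeries)[j]))
      next
    }
    for (p in seq_len(k)) {
      if (stats::sd(projections[, p]) == 0) next
      out[j, p] <- stats::cor(monitorSeries[, j], projections[, p])
    }
  }
  out
}
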