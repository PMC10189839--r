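#' @include superpose.R
NULL

#' RMSD of evenly sampled frames against a reference conformation
#'
#' Selects `nSamples` frames at an even stride across each replicate
#' (first frame included), superposes each onto the reference using the
#' CA atoms outside the alignment-excluded regions, and computes the
#' RMSD over the configured selection (all shared CA atoms by default;
#' a residue subset, e.g. the switches, may be supplied).
#'
#' @param ensemble a [TrajectoryEnsemble-class].
#' @param reference reference structure: `"ProteinStructure"`,
#'   `TrajectoryEnsemble` (first frame), or CA matrix with residue
#'   rownames.
#' @param map optional [RegionMap-class] for alignment exclusions.
#' @param nSamples frames sampled per replicate, default 100.
#' @param selection optional integer vector of residue numbers to
#'   measure RMSD over (default: all shared CA).
#' @param referenceName label stored with the series.
#' @return `data.frame` of class `"RMSDSeries"` with columns
#'   `replicate`, `frame`, `rmsd` (Angstrom); summary statistics in
#'   `attr(, "summary")` and the label in `attr(, "reference")`.
#' @export
computeRMSDToReference <- function(ensemble, reference, map = NULL,
                                   nSamples = 100L, selection = NULL,
                                   referenceName = "reference") {
  refCa <- if (is.matrix(reference)) reference else caCoordsByResno(reference)
  ensCa <- caCoordsByResno(ensemble)
  shared <- intersect(as.integer(rownames(ensCa)), as.integer(rownames(refCa)))
  if (length(shared) == 0L) stop("no shared CA atoms with the reference")
  fitRes <- .fitResnos(as.integer(rownames(ensCa)),
                       as.integer(rownames(refCa)), map)
  if (length(fitRes) < 3L) stop("fewer than 3 fitting atoms after exclusions")
  measRes <- if (is.null(selection)) sort(shared)
             else sort(intersect(shared, selection))
  if (length(measRes) == 0L) stop("empty RMSD selection")

  at <- atomTable(ensemble); caIdx <- caIndices(ensemble)
  ensFitCols <- atomXyzCols(caIdx[match(fitRes, at$resno[caIdx])])
  ensMeasCols <- atomXyzCols(caIdx[match(measRes, at$resno[caIdx])])
  refResno <- as.integer(rownames(refCa))
  refFit <- refCa[match(fitRes, refResno), , drop = FALSE]
  refMeas <- refCa[match(measRes, refResno), , drop = FALSE]

  xyz <- frameCoords(ensemble)
  repIdx <- replicateIndex(ensemble)
  out <- list()
  for (r in sort(unique(repIdx))) {
    rows <- which(repIdx == r)
    nf <- length(rows)
    sel <- if (nSamples >= nf) rows else {
      stride <- nf %/% nSamples
      rows[seq.int(1L, by = stride, length.out = nSamples)]
    }
    rv <- vapply(sel, function(t) {
      tr <- kabschTransform(.frameTo3col(xyz[t, ensFitCols]), refFit)
      coordRmsd(applyTransform(tr, .frameTo3col(xyz[t, ensMeasCols])), refMeas)
    }, numeric(1))
    out[[as.character(r)]] <- data.frame(replicate = r, frame = sel, rmsd = rv)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "reference") <- referenceName
  attr(res, "summary") <- c(mean = mean(res$rmsd),
                            median = stats::median(res$rmsd),
                            sd = stats::sd(res$rmsd))
  class(res) <- c("RMSDSeries", "data.frame")
  res
}

#' Summary statistics of an RMSD series
#'
#' @param series an `"RMSDSeries"` from [computeRMSDToReference()].
#' @return Named numeric vector `mean`, `median`, `sd`.
#' @export
rmsdSummary <- function(series) attr(series, "summary")
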