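#' @include trajectory-ensemble.R
NULL

#' Per-residue mobility (RMSF) of a superposed ensemble
#'
#' Per replicate, `RMSF_i = sqrt(mean_t ||r_i(t) - <r_i>||^2)` over CA
#' atoms; the profile is then aggregated across replicates
#' (arithmetic mean by default, median available).
#'
#' @param ensemble a superposed [TrajectoryEnsemble-class].
#' @param aggregate `"mean"` (default) or `"median"` across replicates.
#' @return `data.frame` of class `"RMSFProfile"` with columns
#'   `residue`, `rmsf` (Angstrom); the per-replicate profile matrix is
#'   kept in `attr(, "perReplicate")` (residues x replicates).
#' @export
computeRMSF <- function(ensemble, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (!ensemble@superposed)
    warning("ensemble is not flagged as superposed; RMSF assumes aligned frames")
  caIdx <- caIndices(ensemble)
  resno <- atomTable(ensemble)$resno[caIdx]
  reps <- sort(unique(replicateIndex(ensemble)))
  per <- matrix(NA_real_, nrow = length(caIdx), ncol = length(reps),
                dimnames = list(resno, reps))
  xyz <- frameCoords(ensemble, select = caIdx)
  for (k in seq_along(reps)) {
    rows <- replicateIndex(ensemble) == reps[k]
    if (sum(rows) < 2L)
      stop("RMSF undefined: a replicate has fewer than 2 frames")
    block <- xyz[rows, , drop = FALSE]
    dev2 <- sweep(block, 2, colMeans(block))^2
    percoord <- colMeans(dev2)                       # mean over frames
    per[, k] <- sqrt(colSums(matrix(percoord, nrow = 3)))  # sum x,y,z
  }
  prof <- apply(per, 1, if (aggregate == "mean") mean else stats::median)
  out <- data.frame(residue = resno, rmsf = as.numeric(prof))
  attr(out, "perReplicate") <- per
  class(out) <- c("RMSFProfile", "data.frame")
  out
}

#' Sum of squared residuals between two RMSF profiles
#'
#' `SSR = sum_residues (RMSF_a - RMSF_b)^2` (Angstrom^2). Symmetric,
#' non-negative, zero iff the profiles are equal.
#'
#' @param profile,reference numeric vectors or `"RMSFProfile"` objects
#'   of equal length. `reference` would typically be the across-variant
#'   mean profile, or the WT profile.
#' @return Numeric scalar (Angstrom^2).
#' @export
rmsfSSR <- function(profile, reference) {
  a <- if (is.data.frame(profile)) profile$rmsf else as.numeric(profile)
  b <- if (is.data.frame(reference)) reference$rmsf else as.numeric(reference)
  if (length(a) != length(b)) stop("profile lengths differ")
  sum((a - b)^2)
}

#' Classify SSR deviation from the wild type
#'
#' Compares `|SSR_mut - SSR_wt|` against a threshold (default
#' 0.5 Angstrom^2): within the threshold the variant's flexibility
#' profile is called `"similar"`, otherwise `"deviated"`.
#'
#' @param ssrMut,ssrWt SSR values of mutant and wild type against the
#'   same reference profile.
#' @param threshold deviation threshold (Angstrom^2), default 0.5.
#' @return `"similar"` or `"deviated"`.
#' @export
ssrClassify <- function(ssrMut, ssrWt, threshold = 0.5) {
  if (abs(ssrMut - ssrWt) < threshold) "similar" else "deviated"
}

#' Across-variant mean RMSF profile
#'
#' @param profiles list of `"RMSFProfile"` objects on the same residue
#'   range.
#' @return Numeric vector, the elementwise mean profile.
#' @export
meanRMSFProfile <- function(profiles) {
  m <- vapply(profiles, function(p) p$rmsf, numeric(nrow(profiles[[1]])))
  rowMeans(m)
}
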