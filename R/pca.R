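#' @include AllClasses.R trajectory-ensemble.R
NULL

# pooled, strided CA coordinate matrix from one or more ensembles
.pooledCa <- function(ensembles, stride = 1L) {
  if (methods::is(ensembles, "TrajectoryEnsemble")) ensembles <- list(ensembles)
  nca <- vapply(ensembles, function(e) length(caIndices(e)), integer(1))
  if (length(unique(nca)) != 1L)
    stop("all ensembles must have the same number of CA atoms")
  do.call(rbind, lapply(ensembles, function(e) {
    m <- frameCoords(e, select = caIndices(e))
    m[seq.int(1L, nrow(m), by = stride), , drop = FALSE]
  }))
}

#' Principal components of pooled C-alpha coordinates
#'
#' Eigendecomposition of the covariance of flattened CA Cartesian
#' coordinates over the pooled (optionally strided) frames of one or
#' more superposed ensembles. Deterministic up to component sign; the
#' sign is fixed so each component's largest-magnitude loading is
#' positive. Variance fractions are taken against the total coordinate
#' variance (trace of the covariance), so they sum to at most 1 even
#' for a truncated basis.
#'
#' @param ensembles a [TrajectoryEnsemble-class] or list of them, all
#'   superposed to the same reference with equal CA counts. Typically
#'   fit separately per nucleotide state; a pooled fit across states is
#'   obtained by passing both states' ensembles.
#' @param stride subsampling stride over frames, default 1.
#' @param nComponents number of components to keep (default: all).
#' @param scope label stored in the model, e.g. `"GDP"` or `"pooled"`.
#' @return A [PCModel-class].
#' @export
fitPCA <- function(ensembles, stride = 1L, nComponents = NULL, scope = "pooled") {
  X <- .pooledCa(ensembles, stride)
  totVar <- sum(apply(X, 2, stats::var))
  if (totVar <= 0) stop("zero coordinate variance; cannot fit PCA")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- if (is.null(nComponents)) length(pc$sdev) else min(nComponents, length(pc$sdev))
  L <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  methods::new("PCModel",
    center = pc$center, loadings = L, sdev = pc$sdev[seq_len(k)],
    varFrac = pc$sdev[seq_len(k)]^2 / totVar,
    nFramesFit = nrow(X), scope = scope)
}

setMethod("show", "PCModel", function(object) {
  k <- min(3L, length(object@varFrac))
  cat(sprintf(
    "PCModel (%s): %d components over %d coordinates, %d frames\n  top-%d variance fractions: %s (sum %.1f%%)\n",
    object@scope, ncol(object@loadings), nrow(object@loadings),
    object@nFramesFit, k,
    paste(sprintf("%.3f", object@varFrac[seq_len(k)]), collapse = ", "),
    100 * sum(object@varFrac[seq_len(k)])))
})

#' Project frames onto a PC model
#'
#' `projection = t(loadings) (frame - center)`; frame order preserved.
#'
#' @param x a [TrajectoryEnsemble-class] (CA coordinates used) or a
#'   frames x 3N coordinate matrix.
#' @param model a [PCModel-class].
#' @param pcs which components to return (default: all in the model).
#' @return Numeric matrix, frames x length(pcs).
#' @export
projectFrames <- function(x, model, pcs = NULL) {
  X <- if (methods::is(x, "TrajectoryEnsemble"))
    frameCoords(x, select = caIndices(x)) else as.matrix(x)
  if (ncol(X) != length(model@center))
    stop(sprintf("dimension mismatch: frames have %d coordinates, model %d",
                 ncol(X), length(model@center)))
  P <- sweep(X, 2, model@center) %*% model@loadings
  if (!is.null(pcs)) P <- P[, pcs, drop = FALSE]
  P
}

#' Reconstruct frames from PC projections
#'
#' @param projections frames x k matrix of PC coordinates.
#' @param model a [PCModel-class].
#' @return frames x 3N coordinate matrix.
#' @export
reconstructFrames <- function(projections, model) {
  k <- ncol(projections)
  sweep(projections %*% t(model@loadings[, seq_len(k), drop = FALSE]),
        2, model@center, `+`)
}

#' WT-standardized PC scores of a variant
#'
#' For each of the top `k` components,
#' `z = (mean_mut - mean_WT) / SD_WT`, i.e. the number of wild-type
#' standard deviations separating the variant's mean projection from
#' the wild-type mean. WT scores are 0 by construction.
#'
#' @param variantProjections,wtProjections frames x >=k projection
#'   matrices from [projectFrames()] (pooled frames).
#' @param k number of leading components to score, default 3.
#' @return Named numeric vector `PC1..PCk`.
#' @export
pcStandardScore <- function(variantProjections, wtProjections, k = 3L) {
  k <- min(k, ncol(variantProjections), ncol(wtProjections))
  z <- vapply(seq_len(k), function(j) {
    s <- stats::sd(wtProjections[, j])
    if (!is.finite(s) || s <= 0) stop("WT SD is zero along a component")
    (mean(variantProjections[, j]) - mean(wtProjections[, j])) / s
  }, numeric(1))
  names(z) <- paste0("PC", seq_len(k))
  z
}
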