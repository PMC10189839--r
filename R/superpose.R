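#' @include trajectory-ensemble.R io.R
NULL

#' Least-squares rigid-body transform (Kabsch)
#'
#' Optimal rotation + translation mapping the moving points onto the
#' fixed points in the least-squares sense, via SVD of the covariance
#' matrix with the usual determinant correction against reflections.
#'
#' @param moving,fixed n x 3 coordinate matrices, `n >= 3`.
#' @return List with `rotation` (3 x 3, applied as `X %*% rotation`),
#'   `centerMoving`, `centerFixed`; `apply(transform, X)` maps any
#'   m x 3 matrix.
#' @export
kabschTransform <- function(moving, fixed) {
  if (nrow(moving) < 3L) stop("need at least 3 fitting atoms")
  stopifnot(identical(dim(moving), dim(fixed)))
  cm <- colMeans(moving); cf <- colMeans(fixed)
  H <- crossprod(sweep(moving, 2, cm), sweep(fixed, 2, cf))
  s <- svd(H)
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rotation = R, centerMoving = cm, centerFixed = cf)
}

#' Apply a Kabsch transform to coordinates
#'
#' @param transform result of [kabschTransform()].
#' @param coords m x 3 matrix.
#' @return Transformed m x 3 matrix.
#' @export
applyTransform <- function(transform, coords) {
  sweep(sweep(coords, 2, transform$centerMoving) %*% transform$rotation,
        2, transform$centerFixed, `+`)
}

#' RMSD between two coordinate sets (no fitting)
#'
#' @param a,b n x 3 matrices.
#' @return Numeric scalar (Angstrom).
#' @export
coordRmsd <- function(a, b) {
  sqrt(mean(rowSums((a - b)^2)))
}

.frameTo3col <- function(v) matrix(v, ncol = 3, byrow = TRUE)

# resolve fitting residues: CA residues shared with reference, outside
# the alignment-excluded regions
.fitResnos <- function(ensResno, refResno, map) {
  shared <- intersect(ensResno, refResno)
  if (!is.null(map)) shared <- setdiff(shared, alignmentExcludedResidues(map))
  sort(shared)
}

#' Superpose every frame of an ensemble onto a reference
#'
#' Each frame is rigid-body transformed by the least-squares (Kabsch)
#' fit computed on the CA atoms outside the alignment-excluded regions
#' of `map` (typically the mobile switch loops); the transform is then
#' applied to all atoms of the frame. Mapping between ensemble and
#' reference is gap-aware, by residue number.
#'
#' @param ensemble a [TrajectoryEnsemble-class].
#' @param reference reference CA coordinates: a `"ProteinStructure"`,
#'   another `TrajectoryEnsemble` (first frame), or an n x 3 matrix
#'   with residue-number rownames. Defaults to the ensemble's own first
#'   frame.
#' @param map optional [RegionMap-class] supplying alignment
#'   exclusions.
#' @return The ensemble with transformed coordinates and
#'   `superposed = TRUE`.
#' @export
superposeEnsemble <- function(ensemble, reference = NULL, map = NULL) {
  refCa <- if (is.null(reference)) caCoordsByResno(ensemble)
           else if (is.matrix(reference)) reference
           else caCoordsByResno(reference)
  ensCa <- caCoordsByResno(ensemble)
  fitRes <- .fitResnos(as.integer(rownames(ensCa)),
                       as.integer(rownames(refCa)), map)
  if (length(fitRes) < 3L)
    stop("fewer than 3 fitting atoms after exclusions")
  caIdx <- caIndices(ensemble)
  at <- atomTable(ensemble)
  ensFitAtoms <- caIdx[match(fitRes, at$resno[caIdx])]
  refFit <- refCa[match(fitRes, as.integer(rownames(refCa))), , drop = FALSE]
  xyz <- frameCoords(ensemble)
  out <- xyz
  fitCols <- atomXyzCols(ensFitAtoms)
  for (t in seq_len(nrow(xyz))) {
    tr <- kabschTransform(.frameTo3col(xyz[t, fitCols]), refFit)
    out[t, ] <- as.vector(t(applyTransform(tr, .frameTo3col(xyz[t, ]))))
  }
  setCoords(ensemble, out, superposed = TRUE)
}
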