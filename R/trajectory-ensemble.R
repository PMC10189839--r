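#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a TrajectoryEnsemble
#'
#' Low-level constructor. Most users will get ensembles from
#' [generateEnsemble()] or [loadEnsemble()].
#'
#' @param xyz numeric matrix, frames x (3 * atoms), bio3d xyz ordering.
#' @param atoms `data.frame` with columns `eleno`, `elety`, `resid`,
#'   `chain`, `resno`, `element` (missing optional columns are filled).
#' @param variantId character(1) variant label.
#' @param nucleotide character(1), `"GDP"` or `"GTP"`.
#' @param replicate integer vector of per-frame replicate indices;
#'   defaults to a single replicate.
#' @param superposed logical(1).
#' @param provenance character vector of source descriptions.
#' @return A [TrajectoryEnsemble-class] object.
#' @examples
#' xyz <- matrix(rnorm(2 * 9), nrow = 2)
#' ens <- trajectoryEnsemble(xyz, caAtomTable(3), "WT", "GDP")
#' nFrames(ens)
#' @export
trajectoryEnsemble <- function(xyz, atoms, variantId, nucleotide,
                               replicate = rep(1L, nrow(xyz)),
                               superposed = FALSE, provenance = character()) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  for (col in c("chain", "element")) {
    if (is.null(atoms[[col]]))
      atoms[[col]] <- if (col == "chain") "A" else ""
  }
  methods::new("TrajectoryEnsemble",
    variantId = as.character(variantId), nucleotide = as.character(nucleotide),
    xyz = xyz, atoms = atoms, replicate = as.integer(replicate),
    superposed = superposed, provenance = provenance)
}

#' Atom table for a C-alpha-only model
#'
#' @param n number of residues.
#' @param resid residue names, recycled to length `n`.
#' @return A `data.frame` usable as the `atoms` slot of a
#'   [TrajectoryEnsemble-class] with one CA atom per residue.
#' @export
caAtomTable <- function(n, resid = "ALA") {
  data.frame(
    eleno = seq_len(n), elety = "CA", resid = rep_len(resid, n),
    chain = "A", resno = seq_len(n), element = "C",
    stringsAsFactors = FALSE)
}

#' @describeIn TrajectoryEnsemble number of frames
#' @param x,object a `TrajectoryEnsemble`
#' @export
setMethod("nFrames", "TrajectoryEnsemble", function(x) nrow(x@xyz))

#' @describeIn TrajectoryEnsemble number of atoms
#' @export
setMethod("nAtoms", "TrajectoryEnsemble", function(x) nrow(x@atoms))

#' @describeIn TrajectoryEnsemble number of replicates
#' @export
setMethod("nReplicates", "TrajectoryEnsemble", function(x) length(unique(x@replicate)))

#' @describeIn TrajectoryEnsemble variant label
#' @export
setMethod("variantId", "TrajectoryEnsemble", function(x) x@variantId)

#' @describeIn TrajectoryEnsemble nucleotide state
#' @export
setMethod("nucleotideState", "TrajectoryEnsemble", function(x) x@nucleotide)

#' @describeIn TrajectoryEnsemble atom metadata
#' @export
setMethod("atomTable", "TrajectoryEnsemble", function(x) x@atoms)

#' @describeIn TrajectoryEnsemble replicate index per frame
#' @export
setMethod("replicateIndex", "TrajectoryEnsemble", function(x) x@replicate)

#' @describeIn TrajectoryEnsemble C-alpha atom indices
#' @export
setMethod("caIndices", "TrajectoryEnsemble", function(x) which(x@atoms$elety == "CA"))

#' @describeIn TrajectoryEnsemble frame coordinates; `select` is an
#'   optional atom index vector
#' @param select optional integer vector of atom indices.
#' @export
setMethod("frameCoords", "TrajectoryEnsemble", function(x, select = NULL) {
  if (is.null(select)) return(x@xyz)
  x@xyz[, atomXyzCols(select), drop = FALSE]
})

#' Map atom indices to xyz column indices
#'
#' @param idx integer atom indices.
#' @return Integer vector of columns into a frames x 3N xyz matrix.
#' @keywords internal
atomXyzCols <- function(idx) {
  as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
}

setMethod("show", "TrajectoryEnsemble", function(object) {
  cat(sprintf(
    "TrajectoryEnsemble: %s [%s]\n  %d atoms (%d CA), %d frames in %d replicate(s)%s\n",
    object@variantId, object@nucleotide, nAtoms(object),
    length(caIndices(object)), nFrames(object), nReplicates(object),
    if (object@superposed) ", superposed" else ""))
})

#' Replace the coordinates of an ensemble
#'
#' @param ensemble a [TrajectoryEnsemble-class].
#' @param xyz replacement coordinate matrix of identical dimensions.
#' @param superposed new value for the superposed flag.
#' @return The modified ensemble.
#' @keywords internal
setCoords <- function(ensemble, xyz, superposed = ensemble@superposed) {
  stopifnot(identical(dim(xyz), dim(ensemble@xyz)))
  ensemble@xyz <- xyz
  ensemble@superposed <- superposed
  methods::validObject(ensemble)
  ensemble
}
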