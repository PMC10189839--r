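#' @include AllClasses.R
NULL

#' Number of frames in an ensemble
#'
#' @param x A [TrajectoryEnsemble-class] object.
#' @return Integer scalar.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of atoms in an ensemble
#'
#' @param x A [TrajectoryEnsemble-class] object.
#' @return Integer scalar.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Number of replicates in an ensemble
#'
#' @param x A [TrajectoryEnsemble-class] object.
#' @return Integer scalar.
#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))

#' Variant identifier
#'
#' @param x An object carrying a variant label.
#' @return Character scalar.
#' @export
setGeneric("variantId", function(x) standardGeneric("variantId"))

#' Nucleotide state
#'
#' @param x An object carrying a nucleotide-state label.
#' @return Character scalar, `"GDP"` or `"GTP"`.
#' @export
setGeneric("nucleotideState", function(x) standardGeneric("nucleotideState"))

#' Atom metadata table
#'
#' @param x A [TrajectoryEnsemble-class] object.
#' @return A `data.frame` with one row per atom (`eleno`, `elety`,
#'   `resid`, `chain`, `resno`, `element`).
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' Frame coordinate matrix
#'
#' @param x A [TrajectoryEnsemble-class] object.
#' @param ... Passed to methods; `select` restricts to an atom index
#'   vector.
#' @return Numeric matrix, frames by 3*atoms, bio3d xyz ordering
#'   (x1, y1, z1, x2, ...).
#' @export
setGeneric("frameCoords", function(x, ...) standardGeneric("frameCoords"))

#' Replicate index per frame
#'
#' @param x A [TrajectoryEnsemble-class] object.
#' @return Integer vector with one entry per frame.
#' @export
setGeneric("replicateIndex", function(x) standardGeneric("replicateIndex"))

#' Indices of C-alpha atoms
#'
#' @param x A [TrajectoryEnsemble-class] object.
#' @return Integer vector of atom indices whose atom name is `CA`.
#' @export
setGeneric("caIndices", function(x) standardGeneric("caIndices"))

#' Named residue ranges of a region map
#'
#' @param x A [RegionMap-class] object.
#' @return Named list of length-2 integer vectors (inclusive ranges).
#' @export
setGeneric("regionRanges", function(x) standardGeneric("regionRanges"))

#' Score data of a ScoreTable
#'
#' @param x A [ScoreTable-class] object.
#' @return `data.frame` with columns `variant`, `nucleotide`, then one
#'   numeric column per metric.
#' @export
setGeneric("scoreData", function(x) standardGeneric("scoreData"))

#' Wild-type reference statistics of a ScoreTable
#'
#' @param x A [ScoreTable-class] object.
#' @return `data.frame` with columns `metric`, `nucleotide`, `mean`,
#'   `sd`, `median`.
#' @export
setGeneric("wtStats", function(x) standardGeneric("wtStats"))

#' Well occupancy ratio
#'
#' @param x A [WellStats-class] object.
#' @return Numeric scalar in \[0, 1\]: frames in well II over all
#'   classified frames.
#' @export
setGeneric("wellRatio", function(x) standardGeneric("wellRatio"))
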