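#' @include trajectory-ensemble.R region-map.R
NULL

.atomsFromPdb <- function(pdb, chain = "A") {
  at <- pdb$atom
  keep <- at$type %in% c("ATOM", "HETATM")
  if (!is.null(chain) && any(at$chain %in% chain)) keep <- keep & at$chain %in% chain
  idx <- which(keep)
  list(
    idx = idx,
    atoms = data.frame(
      eleno = at$eleno[idx], elety = at$elety[idx], resid = at$resid[idx],
      chain = ifelse(is.na(at$chain[idx]), "A", at$chain[idx]),
      resno = at$resno[idx],
      element = if (is.null(at$elesy)) "" else ifelse(is.na(at$elesy[idx]), "", at$elesy[idx]),
      stringsAsFactors = FALSE))
}

#' Read a reference structure from PDB
#'
#' Reads one chain (chain A by default) of a standard PDB file into a
#' light structure record usable as a superposition / RMSD reference
#' and by [assessSwitchResolution()]. Missing residues are tolerated:
#' downstream mapping is by residue number, not position.
#'
#' @param path PDB file.
#' @param chain chain identifier(s) to keep, default `"A"`.
#' @return List of class `"ProteinStructure"` with elements `atoms`
#'   (metadata `data.frame`) and `xyz` (length 3N coordinate vector).
#' @export
readStructure <- function(path, chain = "A") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  sel <- .atomsFromPdb(pdb, chain)
  structure(list(atoms = sel$atoms,
                 xyz = as.numeric(pdb$xyz[1, atomXyzCols(sel$idx)]),
                 source = path),
            class = "ProteinStructure")
}

#' C-alpha coordinates keyed by residue number
#'
#' @param x a `"ProteinStructure"` or [TrajectoryEnsemble-class] (first
#'   frame used).
#' @return n x 3 matrix with rownames = residue numbers; residues
#'   without a CA record are absent.
#' @export
caCoordsByResno <- function(x) {
  if (methods::is(x, "TrajectoryEnsemble")) {
    atoms <- atomTable(x); xyz <- frameCoords(x)[1, ]
  } else {
    atoms <- x$atoms; xyz <- x$xyz
  }
  idx <- which(atoms$elety == "CA")
  m <- matrix(xyz[atomXyzCols(idx)], ncol = 3, byrow = TRUE)
  rownames(m) <- atoms$resno[idx]
  m
}

#' Load a trajectory ensemble from disk
#'
#' Reads a PDB topology plus one trajectory file per replicate (DCD or
#' multi-model PDB) and concatenates the replicate blocks. Atom counts
#' are checked between the topology and every trajectory file.
#'
#' @param topologyPath PDB file defining the atom table.
#' @param trajectoryPaths character vector of trajectory files; `.dcd`
#'   is read as DCD, anything else as multi-model PDB.
#' @param variantId,nucleotide ensemble labels.
#' @param chain chain to keep from the topology, default `"A"`.
#' @return A [TrajectoryEnsemble-class] with one replicate per file and
#'   source-file provenance retained.
#' @export
loadEnsemble <- function(topologyPath, trajectoryPaths, variantId, nucleotide,
                         chain = "A") {
  if (!file.exists(topologyPath))
    stop(sprintf("file not found: %s", topologyPath))
  missing <- trajectoryPaths[!file.exists(trajectoryPaths)]
  if (length(missing))
    stop(sprintf("file not found: %s", missing[1]))
  top <- bio3d::read.pdb(topologyPath, verbose = FALSE)
  sel <- .atomsFromPdb(top, chain)
  nTotal <- nrow(top$atom)
  blocks <- list(); repIdx <- list()
  for (i in seq_along(trajectoryPaths)) {
    f <- trajectoryPaths[i]
    xyz <- tryCatch({
      if (grepl("\\.dcd$", f, ignore.case = TRUE))
        unclass(bio3d::read.dcd(f, verbose = FALSE))
      else {
        p <- bio3d::read.pdb(f, multi = TRUE, verbose = FALSE)
        unclass(p$xyz)
      }
    }, error = function(e)
      stop(sprintf("unreadable trajectory '%s': %s", f, conditionMessage(e)),
           call. = FALSE))
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    if (ncol(xyz) != 3L * nTotal)
      stop(sprintf(
        "atom-count mismatch in '%s': trajectory has %d atoms, topology %d",
        f, ncol(xyz) %/% 3L, nTotal))
    blocks[[i]] <- xyz[, atomXyzCols(sel$idx), drop = FALSE]
    repIdx[[i]] <- rep(i, nrow(xyz))
  }
  trajectoryEnsemble(
    do.call(rbind, blocks), sel$atoms, variantId, nucleotide,
    replicate = unlist(repIdx),
    provenance = c(topologyPath, trajectoryPaths))
}

#' Write an ensemble as PDB topology plus multi-model PDB replicates
#'
#' Writes `topology.pdb` (first frame) and one multi-model PDB per
#' replicate (`rep1.pdb`, ...) into `dir`; together with
#' [loadEnsemble()] this provides trajectory roundtrip support at PDB
#' coordinate precision (1e-3 Angstrom).
#'
#' @param ensemble a [TrajectoryEnsemble-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with `topology` and `trajectories` paths.
#' @export
writeEnsemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  at <- atomTable(ensemble)
  wr <- function(file, xyz) {
    bio3d::write.pdb(file = file, xyz = xyz,
                     eleno = at$eleno, elety = at$elety, resid = at$resid,
                     chain = at$chain, resno = at$resno)
  }
  topo <- file.path(dir, "topology.pdb")
  wr(topo, frameCoords(ensemble)[1, , drop = FALSE])
  reps <- sort(unique(replicateIndex(ensemble)))
  trajs <- character(length(reps))
  for (i in seq_along(reps)) {
    trajs[i] <- file.path(dir, sprintf("rep%d.pdb", reps[i]))
    wr(trajs[i], frameCoords(ensemble)[replicateIndex(ensemble) == reps[i], ,
                                       drop = FALSE])
  }
  invisible(list(topology = topo, trajectories = trajs))
}

#' Flag unresolved switch regions in a structure
#'
#' A region is unresolved iff any residue in its range lacks a CA
#' coordinate record — the rule used to assess whether mobile loops
#' were too dynamic in the crystal to assign coordinates.
#'
#' @param structure a `"ProteinStructure"` (see [readStructure()]) or a
#'   [TrajectoryEnsemble-class].
#' @param map a [RegionMap-class].
#' @return Named character vector over regions with values
#'   `"resolved"` / `"unresolved"`.
#' @export
assessSwitchResolution <- function(structure, map) {
  present <- as.integer(rownames(caCoordsByResno(structure)))
  vapply(regionRanges(map), function(r) {
    if (all(seq.int(r[1], r[2]) %in% present)) "resolved" else "unresolved"
  }, character(1))
}
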