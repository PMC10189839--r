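#' TrajectoryEnsemble: replicate frames of one variant in one nucleotide state
#'
#' Holds the concatenated replicate frames of atomic coordinates for a
#' single variant in a single nucleotide state, together with the shared
#' atom metadata table and the replicate index of every frame.
#' Coordinates use the bio3d xyz layout: each frame is one row of the
#' `xyz` matrix, columns ordered x1, y1, z1, x2, y2, z2, ...
#'
#' @slot variantId character(1), e.g. `"WT"` or `"G12D"`.
#' @slot nucleotide character(1), `"GDP"` or `"GTP"`.
#' @slot xyz numeric matrix, frames x (3 * atoms), all finite.
#' @slot atoms `data.frame` with columns `eleno`, `elety`, `resid`,
#'   `chain`, `resno`, `element`; one row per atom, shared by all frames.
#' @slot replicate integer vector, length `nrow(xyz)`; which replicate
#'   each frame belongs to.
#' @slot superposed logical(1); whether [superposeEnsemble()] has been
#'   applied.
#' @slot provenance character; source file paths or generator tags.
#'
#' @seealso [trajectoryEnsemble()], [generateEnsemble()],
#'   [loadEnsemble()], [superposeEnsemble()]
#' @export
setClass("TrajectoryEnsemble",
  representation(
    variantId  = "character",
    nucleotide = "character",
    xyz        = "matrix",
    atoms      = "data.frame",
    replicate  = "integer",
    superposed = "logical",
    provenance = "character"
  ),
  prototype(superposed = FALSE, provenance = character())
)

setValidity("TrajectoryEnsemble", function(object) {
  msg <- character()
  if (length(object@variantId) != 1L) msg <- c(msg, "variantId must be length 1")
  if (length(object@nucleotide) != 1L || !object@nucleotide %in% c("GDP", "GTP"))
    msg <- c(msg, "nucleotide must be 'GDP' or 'GTP'")
  if (!is.numeric(object@xyz)) msg <- c(msg, "xyz must be numeric")
  if (any(!is.finite(object@xyz))) msg <- c(msg, "coordinates must be finite")
  need <- c("eleno", "elety", "resid", "chain", "resno", "element")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms must have columns:", paste(need, collapse = ", ")))
  else {
    if (ncol(object@xyz) != 3L * nrow(object@atoms))
      msg <- c(msg, "ncol(xyz) must equal 3 * nrow(atoms)")
    # residue numbers must be non-decreasing within a chain, and the
    # sequence of residue blocks strictly increasing
    for (ch in unique(object@atoms$chain)) {
      rn <- object@atoms$resno[object@atoms$chain == ch]
      ublk <- rle(rn)$values
      if (any(diff(ublk) <= 0))
        msg <- c(msg, sprintf("residue indices not strictly increasing in chain %s", ch))
    }
  }
  if (length(object@replicate) != nrow(object@xyz))
    msg <- c(msg, "replicate must have one entry per frame")
  if (length(msg)) msg else TRUE
})

#' RegionMap: named residue ranges of a switch-regulated GTPase
#'
#' Inclusive 1-based residue ranges naming functional regions
#' (phosphate-binding loop, the two switch loops, allosteric lobe),
#' plus the set of region names excluded from superposition fits.
#'
#' @slot regions named list of length-2 integer vectors (inclusive
#'   ranges), all within the protein.
#' @slot alignmentExclusions character; names of `regions` whose
#'   residues are dropped from fitting (typically the mobile switches).
#'
#' @seealso [regionMap()], [krasRegionMap()]
#' @export
setClass("RegionMap",
  representation(regions = "list", alignmentExclusions = "character")
)

setValidity("RegionMap", function(object) {
  msg <- character()
  if (length(object@regions) == 0L) msg <- c(msg, "regions must be non-empty")
  if (is.null(names(object@regions)) || any(!nzchar(names(object@regions))))
    msg <- c(msg, "regions must be named")
  for (nm in names(object@regions)) {
    r <- object@regions[[nm]]
    if (length(r) != 2L || any(r < 1L) || r[2] < r[1])
      msg <- c(msg, sprintf("region '%s' must be an increasing 1-based range", nm))
  }
  bad <- setdiff(object@alignmentExclusions, names(object@regions))
  if (length(bad))
    msg <- c(msg, paste("unknown alignment exclusions:", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' PCModel: principal components of C-alpha coordinates
#'
#' Orthonormal basis from a PCA of flattened C-alpha coordinates over
#' pooled ensemble frames, with eigenvalue spectrum and fit metadata.
#' Component signs are fixed so each component's largest-magnitude
#' loading is positive.
#'
#' @slot center numeric, mean coordinate vector (length 3 * n_ca).
#' @slot loadings numeric matrix (3 * n_ca) x k, orthonormal columns.
#' @slot sdev numeric(k), component standard deviations.
#' @slot varFrac numeric(k), variance fractions, non-increasing.
#' @slot nFramesFit integer(1), frames used in the fit.
#' @slot scope character(1), e.g. `"GDP"`, `"GTP"`, or `"pooled"`.
#'
#' @seealso [fitPCA()], [projectFrames()]
#' @export
setClass("PCModel",
  representation(
    center = "numeric", loadings = "matrix", sdev = "numeric",
    varFrac = "numeric", nFramesFit = "integer", scope = "character"
  )
)

setValidity("PCModel", function(object) {
  msg <- character()
  k <- ncol(object@loadings)
  if (length(object@sdev) != k || length(object@varFrac) != k)
    msg <- c(msg, "sdev/varFrac length must match loadings columns")
  if (any(object@varFrac < -1e-12) || any(object@varFrac > 1 + 1e-12))
    msg <- c(msg, "variance fractions must lie in [0, 1]")
  if (any(diff(object@varFrac) > 1e-12))
    msg <- c(msg, "variance fractions must be non-increasing")
  if (sum(object@varFrac) > 1 + 1e-8)
    msg <- c(msg, "variance fractions must sum to <= 1")
  g <- crossprod(object@loadings)
  if (max(abs(g - diag(k))) > 1e-6)
    msg <- c(msg, "loadings must be orthonormal")
  if (length(msg)) msg else TRUE
})

#' FESurface: free-energy landscape over a 2D PC subspace
#'
#' A binned density over two principal components converted to an
#' observed free energy, F = -kT log(rho / rho_max) (kcal/mol), so the
#' most occupied bin has F = 0 and empty bins are undefined (`NA`).
#'
#' @slot xBreaks,yBreaks numeric bin edges along the two components.
#' @slot counts integer matrix of bin occupancies.
#' @slot free numeric matrix of free energies (kcal/mol); `NA` where
#'   unoccupied.
#' @slot kT numeric(1), thermal energy in kcal/mol.
#' @slot pcs integer(2), which components span the surface.
#'
#' @seealso [buildFEL()]
#' @export
setClass("FESurface",
  representation(
    xBreaks = "numeric", yBreaks = "numeric",
    counts = "matrix", free = "matrix", kT = "numeric", pcs = "integer"
  )
)

setValidity("FESurface", function(object) {
  msg <- character()
  occ <- object@counts > 0
  if (!any(occ)) msg <- c(msg, "at least one bin must be occupied")
  else {
    if (abs(min(object@free[occ])) > 1e-9)
      msg <- c(msg, "minimum free energy over occupied bins must be 0")
    if (any(object@free[occ] < -1e-9)) msg <- c(msg, "free energies must be >= 0")
    if (any(!is.na(object@free[!occ]))) msg <- c(msg, "empty bins must be NA")
  }
  if (length(msg)) msg else TRUE
})

#' WellStats: two-well occupancy summary along PC1
#'
#' Frame counts on either side of a density-minimum boundary along PC1,
#' kept per replicate, with the pooled occupancy ratio
#' n_II / (n_I + n_II). A ratio of 0 means well II is never sampled; a
#' ratio of 1 means well I is never sampled.
#'
#' @slot boundary numeric(1), boundary position along PC1.
#' @slot wellIISide character(1), `"above"` or `"below"`: which side of
#'   the boundary is well II.
#' @slot countI,countII integer vectors, per-replicate frame counts.
#' @slot ratio numeric(1) in \[0, 1\].
#'
#' @seealso [occupancyRatio()], [detectWells()]
#' @export
setClass("WellStats",
  representation(
    boundary = "numeric", wellIISide = "character",
    countI = "integer", countII = "integer", ratio = "numeric"
  )
)

setValidity("WellStats", function(object) {
  msg <- character()
  if (!object@wellIISide %in% c("above", "below"))
    msg <- c(msg, "wellIISide must be 'above' or 'below'")
  tot <- sum(object@countI) + sum(object@countII)
  if (tot > 0 && abs(object@ratio - sum(object@countII) / tot) > 1e-12)
    msg <- c(msg, "ratio must equal pooled n_II / (n_I + n_II)")
  if (object@ratio < 0 || object@ratio > 1) msg <- c(msg, "ratio must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ScoreTable: variant x state metric values with WT reference statistics
#'
#' Long-format score table: one row per (variant, nucleotide) with one
#' numeric column per metric, together with the wild-type reference
#' statistics (mean, SD, median) per metric and state used for all
#' sigma-standardizations downstream.
#'
#' @slot scores `data.frame` with columns `variant`, `nucleotide`, then
#'   numeric metric columns.
#' @slot wt `data.frame` with columns `metric`, `nucleotide`, `mean`,
#'   `sd`, `median`.
#' @slot wtId character(1), the variant label of the wild type row(s).
#'
#' @seealso [scoreTable()], [generateScoreTable()],
#'   [buildMetaclassMatrix()]
#' @export
setClass("ScoreTable",
  representation(scores = "data.frame", wt = "data.frame", wtId = "character"),
  prototype(wtId = "WT")
)

setValidity("ScoreTable", function(object) {
  msg <- character()
  if (!all(c("variant", "nucleotide") %in% names(object@scores)))
    msg <- c(msg, "scores must have 'variant' and 'nucleotide' columns")
  if (!all(c("metric", "nucleotide", "mean", "sd", "median") %in% names(object@wt)))
    msg <- c(msg, "wt must have metric/nucleotide/mean/sd/median columns")
  if (all(c("variant", "nucleotide") %in% names(object@scores))) {
    for (st in unique(object@scores$nucleotide)) {
      if (!any(object@scores$variant == object@wtId &
               object@scores$nucleotide == st))
        msg <- c(msg, sprintf("WT row ('%s') missing for state %s", object@wtId, st))
    }
  }
  if (length(msg)) msg else TRUE
})
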