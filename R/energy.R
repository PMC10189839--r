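#' @include trajectory-ensemble.R
NULL

#' Coulomb constant, kcal A / (mol e^2)
#' @keywords internal
.COULOMB_K <- 332.0716

#' CHARMM-style switching function
#'
#' `S(r) = 1` for `r <= rOn`, 0 for `r >= rOff`, and the cubic-in-r^2
#' CHARMM switching polynomial
#' `(rOff^2 - r^2)^2 (rOff^2 + 2 r^2 - 3 rOn^2) / (rOff^2 - rOn^2)^3`
#' in between; continuous (with continuous derivative) at both
#' boundaries.
#'
#' @param r distances (Angstrom).
#' @param rOn,rOff switching radii (Angstrom), `rOn < rOff`; defaults
#'   10 and 12.
#' @return Numeric vector of switching factors in \[0, 1\].
#' @export
switchingFunction <- function(r, rOn = 10, rOff = 12) {
  if (rOn >= rOff) stop("rOn must be < rOff")
  r2 <- r^2; on2 <- rOn^2; off2 <- rOff^2
  s <- ifelse(r <= rOn, 1,
       ifelse(r >= rOff, 0,
              (off2 - r2)^2 * (off2 + 2 * r2 - 3 * on2) / (off2 - on2)^3))
  s
}

#' Per-atom nonbonded parameter table
#'
#' @param atomName,residueName character keys matched against the atom
#'   table (`elety`, `resid`).
#' @param charge partial charges (e).
#' @param rminHalf Rmin/2 (Angstrom).
#' @param epsilon well depths (kcal/mol), `>= 0`.
#' @return `data.frame` of class `"NonbondedParams"`.
#' @export
nonbondedParams <- function(atomName, residueName, charge, rminHalf, epsilon) {
  if (any(epsilon < 0)) stop("epsilon must be >= 0")
  out <- data.frame(atom_name = atomName, residue_name = residueName,
                    charge = charge, rmin_half = rminHalf, epsilon = epsilon,
                    stringsAsFactors = FALSE)
  class(out) <- c("NonbondedParams", "data.frame")
  out
}

#' Read a nonbonded parameter table from CSV
#'
#' Expects columns `atom_name`, `residue_name`, `charge`, `rmin_half`,
#' `epsilon`.
#'
#' @param path CSV file.
#' @return A `"NonbondedParams"` table.
#' @export
readNonbondedParams <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nonbondedParams(df$atom_name, df$residue_name, df$charge,
                  df$rmin_half, df$epsilon)
}

# match params rows to atoms; error listing unmatched atoms
.matchParams <- function(atoms, params) {
  key <- paste(atoms$elety, atoms$resid)
  pkey <- paste(params$atom_name, params$residue_name)
  idx <- match(key, pkey)
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])
    stop(sprintf("missing nonbonded parameters for atoms: %s",
                 paste(bad, collapse = ", ")))
  }
  params[idx, , drop = FALSE]
}

#' Protein-ligand nonbonded interaction energy per frame
#'
#' Direct-sum pairwise Coulomb and Lennard-Jones energies between a
#' protein and a ligand selection, with CHARMM-style switching applied
#' to both terms between `rOn` and `rOff` (pairs beyond `rOff`
#' contribute exactly 0):
#' `E_coul = sum C q_i q_j / r_ij * S(r_ij)` with
#' `C = 332.0716 kcal A / (mol e^2)`, and
#' `E_LJ = sum eps_ij [ (Rmin_ij/r_ij)^12 - 2 (Rmin_ij/r_ij)^6 ] * S(r_ij)`
#' with `eps_ij` the geometric mean and `Rmin_ij` the sum of the two
#' Rmin/2 values (CHARMM combining rules). This is a per-frame
#' pair-interaction energy, not a lattice (Ewald) sum.
#'
#' @param ensemble a [TrajectoryEnsemble-class] with all-atom frames.
#' @param params a `"NonbondedParams"` table covering every selected
#'   atom.
#' @param proteinSel,ligandSel disjoint integer vectors of atom indices
#'   into the atom table.
#' @param rOn,rOff switching radii (Angstrom), defaults 10 and 12.
#' @return `data.frame` of class `"EnergySeries"` with columns `frame`,
#'   `e_coul`, `e_lj`, `e_int` (kcal/mol; `e_int = e_coul + e_lj`);
#'   mean/SD of `e_int` in `attr(, "summary")`.
#' @export
computeInteractionEnergy <- function(ensemble, params, proteinSel, ligandSel,
                                     rOn = 10, rOff = 12) {
  if (length(intersect(proteinSel, ligandSel)))
    stop("protein and ligand selections overlap")
  at <- atomTable(ensemble)
  pp <- .matchParams(at[proteinSel, , drop = FALSE], params)
  pl <- .matchParams(at[ligandSel, , drop = FALSE], params)
  qq <- outer(pp$charge, pl$charge)                      # np x nl
  eps <- sqrt(outer(pp$epsilon, pl$epsilon))
  rmin <- outer(pp$rmin_half, pl$rmin_half, `+`)
  xyz <- frameCoords(ensemble)
  pCols <- atomXyzCols(proteinSel); lCols <- atomXyzCols(ligandSel)
  nF <- nFrames(ensemble)
  eC <- eL <- numeric(nF)
  for (t in seq_len(nF)) {
    P <- .frameTo3col(xyz[t, pCols]); L <- .frameTo3col(xyz[t, lCols])
    d2 <- outer(rowSums(P^2), rowSums(L^2), `+`) - 2 * P %*% t(L)
    r <- sqrt(pmax(d2, 0))
    s <- switchingFunction(r, rOn, rOff)
    within <- s > 0
    if (any(within)) {
      eC[t] <- sum((.COULOMB_K * qq[within] / r[within]) * s[within])
      x6 <- (rmin[within] / r[within])^6
      eL[t] <- sum(eps[within] * (x6^2 - 2 * x6) * s[within])
    }
  }
  out <- data.frame(frame = seq_len(nF), e_coul = eC, e_lj = eL,
                    e_int = eC + eL)
  attr(out, "summary") <- c(mean = mean(out$e_int), sd = stats::sd(out$e_int))
  class(out) <- c("EnergySeries", "data.frame")
  out
}

#' Read a per-frame energy series from a two-column CSV
#'
#' Expects two numeric columns (frame, energy). Non-numeric rows raise
#' an error naming the offending line.
#'
#' @param path CSV file.
#' @return `data.frame` of class `"EnergySeries"` with columns `frame`,
#'   `e_int`, and mean/SD in `attr(, "summary")`.
#' @export
ingestEnergySeries <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(raw) < 2L) stop("expected a two-column CSV")
  num <- suppressWarnings(data.frame(frame = as.numeric(raw[[1]]),
                                     e_int = as.numeric(raw[[2]])))
  bad <- which(is.na(num$frame) | is.na(num$e_int))
  if (length(bad))
    stop(sprintf("non-numeric value at line %d of %s", bad[1] + 1L, path))
  attr(num, "summary") <- c(mean = mean(num$e_int), sd = stats::sd(num$e_int))
  class(num) <- c("EnergySeries", "data.frame")
  num
}

#' Write a per-frame energy series as CSV
#'
#' @param energy numeric vector or `"EnergySeries"`.
#' @param path output CSV.
#' @return The path, invisibly.
#' @export
writeEnergySeries <- function(energy, path) {
  df <- if (is.data.frame(energy)) data.frame(frame = energy$frame,
                                              energy = energy$e_int)
        else data.frame(frame = seq_along(energy), energy = energy)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
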