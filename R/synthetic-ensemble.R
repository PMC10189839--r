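#' @include trajectory-ensemble.R
NULL

#' Ideal-chain base geometry
#'
#' Residues on a smooth helix-like curve with ~3.8 Angstrom spacing
#' between consecutive C-alpha positions, giving realistic inter-residue
#' distances without requiring an input structure.
#'
#' @param n number of residues.
#' @return n x 3 numeric matrix of coordinates (Angstrom).
#' @export
idealChainCoords <- function(n) {
  radius <- 2.3; rise <- 1.5; twist <- 100 * pi / 180
  i <- seq_len(n) - 1
  cbind(radius * cos(i * twist), radius * sin(i * twist), rise * i)
}

#' Random orthonormal displacement modes
#'
#' Draws `k` mutually orthonormal displacement directions over the 3N
#' C-alpha coordinates, optionally restricted to a residue range so the
#' mode moves only part of the chain (e.g. one switch loop).
#'
#' @param nResidues number of residues.
#' @param k number of modes.
#' @param region optional length-2 inclusive residue range restriction.
#' @param seed integer seed.
#' @return 3N x k matrix with orthonormal columns, zero outside `region`.
#' @export
randomModes <- function(nResidues, k, region = NULL, seed = 1) {
  set.seed(seed)
  d <- 3L * nResidues
  raw <- matrix(stats::rnorm(d * k), nrow = d)
  if (!is.null(region)) {
    keep <- atomXyzCols(seq.int(region[1], region[2]))
    raw[setdiff(seq_len(d), keep), ] <- 0
  }
  qr.Q(qr(raw))[, seq_len(k), drop = FALSE]
}

#' Specify a synthetic conformational ensemble
#'
#' Validated specification consumed by [generateEnsemble()]. Frames are
#' built as base coordinates plus zero-mean Gaussian excitations of
#' orthonormal displacement modes, an optional two-state collective
#' coordinate with controlled occupancy, and per-residue isotropic
#' noise.
#'
#' @param nResidues,nReplicates,nFramesPerReplicate counts;
#'   `nFramesPerReplicate >= 2`.
#' @param baseCoords `"ideal-chain"` or an nResidues x 3 matrix
#'   (Angstrom).
#' @param modes list of mode definitions, each
#'   `list(direction = <3N unit vector>, sd = <amplitude SD, Angstrom>)`.
#'   Directions must be mutually orthonormal.
#' @param twoWell optional two-state collective coordinate:
#'   `list(direction = <3N unit vector>, centerI =, centerII = <positions
#'   along the direction, Angstrom>, occupancyII = <fraction in [0,1]>,
#'   dwell = <mean dwell length, frames>)`.
#' @param noiseSd per-residue isotropic noise SD (Angstrom); scalar or
#'   length `nResidues`.
#' @param seed integer; all randomness flows from it through a derived
#'   stream per replicate.
#' @return A validated list of class `"EnsembleSpec"`.
#' @seealso [generateEnsemble()]
#' @export
ensembleSpec <- function(nResidues, nReplicates = 1L, nFramesPerReplicate = 100L,
                         baseCoords = "ideal-chain", modes = list(),
                         twoWell = NULL, noiseSd = 0, seed = 1L) {
  stopifnot(nResidues >= 2, nReplicates >= 1)
  if (nFramesPerReplicate < 2) stop("nFramesPerReplicate must be >= 2")
  if (identical(baseCoords, "ideal-chain")) baseCoords <- idealChainCoords(nResidues)
  baseCoords <- as.matrix(baseCoords)
  if (!all(dim(baseCoords) == c(nResidues, 3)))
    stop("baseCoords must be an nResidues x 3 matrix")
  d <- 3L * nResidues
  dirs <- c(lapply(modes, `[[`, "direction"),
            if (!is.null(twoWell)) list(twoWell$direction))
  if (length(dirs)) {
    V <- do.call(cbind, dirs)
    if (nrow(V) != d) stop("mode directions must have length 3 * nResidues")
    g <- crossprod(V)
    if (max(abs(g - diag(ncol(V)))) > 1e-6)
      stop("mode and two-well directions must be mutually orthonormal")
  }
  if (!is.null(twoWell)) {
    if (is.null(twoWell$occupancyII) || twoWell$occupancyII < 0 || twoWell$occupancyII > 1)
      stop("twoWell occupancyII must lie in [0, 1]")
    if (is.null(twoWell$dwell)) twoWell$dwell <- 10
    p <- twoWell$occupancyII
    if (p > 0 && p < 1 && p / (twoWell$dwell * (1 - p)) > 1)
      stop("dwell too short for the requested occupancyII")
  }
  noiseSd <- rep_len(noiseSd, nResidues)
  if (any(noiseSd < 0)) stop("noiseSd must be >= 0")
  structure(
    list(nResidues = as.integer(nResidues), nReplicates = as.integer(nReplicates),
         nFramesPerReplicate = as.integer(nFramesPerReplicate),
         baseCoords = baseCoords, modes = modes, twoWell = twoWell,
         noiseSd = noiseSd, seed = as.integer(seed)),
    class = "EnsembleSpec")
}

# derived per-replicate stream seed; keeps replicate-level determinism
.streamSeed <- function(seed, r) {
  as.integer((as.double(seed) * 48271 + r * 7919) %% 2147483647)
}

# two-state Markov chain with stationary P(state II) = p and mean dwell
# length `dwell` in state II; states coded 0 (I) / 1 (II)
.simTwoState <- function(n, p, dwell) {
  if (p <= 0) return(integer(n))
  if (p >= 1) return(rep(1L, n))
  q21 <- 1 / dwell            # P(II -> I)
  q12 <- q21 * p / (1 - p)    # P(I -> II)
  s <- integer(n)
  s[1] <- stats::rbinom(1L, 1L, p)
  u <- stats::runif(n)
  for (t in seq_len(n - 1L)) {
    s[t + 1L] <- if (s[t] == 1L) {
      if (u[t] < q21) 0L else 1L
    } else {
      if (u[t] < q12) 1L else 0L
    }
  }
  s
}

#' Generate a synthetic trajectory ensemble with planted ground truth
#'
#' Builds frames as
#' `base + sum_k a_k(t) v_k + c(t) v_w + noise`, where the `a_k(t)` are
#' zero-mean Gaussians of the specified SDs, `c(t)` alternates between
#' the two well centers as a two-state Markov chain with the specified
#' stationary occupancy and mean dwell length, and the noise is
#' per-residue isotropic Gaussian. Identical spec and seed give
#' identical output.
#'
#' @param spec an [ensembleSpec()].
#' @param variantId,nucleotide labels for the resulting ensemble.
#' @return A list with elements
#'   \describe{
#'     \item{ensemble}{a [TrajectoryEnsemble-class] (CA-only model).}
#'     \item{truth}{planted ground truth: `occupancyII`, `stateSeq`
#'       (per-frame 0/1 well states), per-residue `rmsf` (Angstrom),
#'       `modes`, `twoWell`, `noiseSd`.}
#'   }
#' @examples
#' sp <- ensembleSpec(10, 1, 50, noiseSd = 0.3, seed = 7)
#' out <- generateEnsemble(sp)
#' out$truth$rmsf[1]   # = 0.3 * sqrt(3)
#' @export
generateEnsemble <- function(spec, variantId = "synthetic", nucleotide = "GDP") {
  stopifnot(inherits(spec, "EnsembleSpec"))
  n <- spec$nResidues; d <- 3L * n
  nf <- spec$nFramesPerReplicate; nr <- spec$nReplicates
  base <- as.vector(t(spec$baseCoords))  # xyz layout
  amps <- vapply(spec$modes, `[[`, numeric(1), "sd")
  V <- if (length(spec$modes))
    do.call(cbind, lapply(spec$modes, `[[`, "direction")) else NULL

  xyz <- matrix(NA_real_, nrow = nf * nr, ncol = d)
  states <- integer(nf * nr)
  for (r in seq_len(nr)) {
    set.seed(.streamSeed(spec$seed, r))
    rows <- (r - 1L) * nf + seq_len(nf)
    fr <- matrix(rep(base, each = nf), nrow = nf)
    if (!is.null(V)) {
      a <- matrix(stats::rnorm(nf * length(amps)), nrow = nf) %*% diag(amps, length(amps))
      fr <- fr + a %*% t(V)
    }
    if (!is.null(spec$twoWell)) {
      tw <- spec$twoWell
      s <- .simTwoState(nf, tw$occupancyII, tw$dwell)
      cc <- ifelse(s == 1L, tw$centerII, tw$centerI)
      fr <- fr + outer(cc, tw$direction)
      states[rows] <- s
    }
    if (any(spec$noiseSd > 0)) {
      sdv <- rep(spec$noiseSd, each = 1)     # per residue
      noise <- matrix(stats::rnorm(nf * d), nrow = nf) *
        matrix(rep(rep(sdv, each = 3), each = nf), nrow = nf)
      fr <- fr + noise
    }
    xyz[rows, ] <- fr
  }

  # planted per-residue RMSF: noise + mode + two-well variance shares
  perResVar <- 3 * spec$noiseSd^2
  if (!is.null(V)) {
    w <- vapply(seq_len(n), function(i)
      colSums(V[atomXyzCols(i), , drop = FALSE]^2), numeric(length(amps)))
    if (is.null(dim(w))) w <- matrix(w, nrow = length(amps))
    perResVar <- perResVar + as.vector(amps^2 %*% w)
  }
  if (!is.null(spec$twoWell)) {
    tw <- spec$twoWell
    vc <- tw$occupancyII * (1 - tw$occupancyII) * (tw$centerII - tw$centerI)^2
    wtw <- vapply(seq_len(n), function(i) sum(tw$direction[atomXyzCols(i)]^2), numeric(1))
    perResVar <- perResVar + vc * wtw
  }

  ens <- trajectoryEnsemble(
    xyz, caAtomTable(n), variantId, nucleotide,
    replicate = rep(seq_len(nr), each = nf),
    provenance = sprintf("generateEnsemble(seed=%d)", spec$seed))
  list(ensemble = ens,
       truth = list(
         occupancyII = if (is.null(spec$twoWell)) NA_real_ else spec$twoWell$occupancyII,
         stateSeq = states, rmsf = sqrt(perResVar),
         modes = spec$modes, twoWell = spec$twoWell, noiseSd = spec$noiseSd))
}
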