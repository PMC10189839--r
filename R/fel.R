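#' @include AllClasses.R AllGenerics.R
NULL

#' Boltzmann constant in kcal/(mol K)
#' @keywords internal
.KB_KCAL <- 0.0019872

#' Free-energy landscape over a 2D PC subspace
#'
#' Bins the pooled projections of all variants into a 2D histogram and
#' converts the density to an observed free energy
#' `F = -kT log(rho / rho_max)` (kcal/mol), so the most occupied bin
#' has `F = 0` and empty bins are undefined. The bin range is the data
#' extent padded by 5% unless explicit breaks are given.
#'
#' @param projections frames x >=2 matrix of PC coordinates (pooled
#'   over variants).
#' @param pcs length-2 integer, which components span the surface
#'   (default 1, 2).
#' @param nBins bins per axis, default 50.
#' @param temperatureK temperature (K), default 300.
#' @param xBreaks,yBreaks optional explicit bin edges.
#' @return A [FESurface-class].
#' @export
buildFEL <- function(projections, pcs = c(1L, 2L), nBins = 50L,
                     temperatureK = 300, xBreaks = NULL, yBreaks = NULL) {
  x <- projections[, pcs[1]]; y <- projections[, pcs[2]]
  pad <- function(v) {
    r <- range(v); w <- diff(r)
    if (w == 0) w <- max(abs(r[1]), 1e-6)
    c(r[1] - 0.05 * w, r[2] + 0.05 * w)
  }
  if (is.null(xBreaks)) xBreaks <- seq(pad(x)[1], pad(x)[2], length.out = nBins + 1L)
  if (is.null(yBreaks)) yBreaks <- seq(pad(y)[1], pad(y)[2], length.out = nBins + 1L)
  xi <- cut(x, xBreaks, include.lowest = TRUE, labels = FALSE)
  yi <- cut(y, yBreaks, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(xi) & !is.na(yi)
  counts <- matrix(0L, nrow = length(xBreaks) - 1L, ncol = length(yBreaks) - 1L)
  tab <- table(factor(xi[keep], levels = seq_len(nrow(counts))),
               factor(yi[keep], levels = seq_len(ncol(counts))))
  counts[] <- as.integer(tab)
  if (!any(counts > 0)) stop("no occupied bins")
  kT <- .KB_KCAL * temperatureK
  free <- matrix(NA_real_, nrow(counts), ncol(counts))
  occ <- counts > 0
  free[occ] <- -kT * log(counts[occ] / max(counts))
  methods::new("FESurface", xBreaks = xBreaks, yBreaks = yBreaks,
               counts = counts, free = free, kT = kT, pcs = as.integer(pcs))
}

setMethod("show", "FESurface", function(object) {
  occ <- sum(object@counts > 0)
  cat(sprintf(
    "FESurface over PC%d/PC%d: %d x %d bins (%d occupied), kT = %.4f kcal/mol, max F = %.2f kcal/mol\n",
    object@pcs[1], object@pcs[2], nrow(object@counts), ncol(object@counts),
    occ, object@kT, max(object@free, na.rm = TRUE)))
})

#' Bin midpoints of a free-energy surface
#'
#' @param surface a [FESurface-class].
#' @return List with numeric vectors `x` and `y`.
#' @export
felMidpoints <- function(surface) {
  list(x = (surface@xBreaks[-1] + surface@xBreaks[-length(surface@xBreaks)]) / 2,
       y = (surface@yBreaks[-1] + surface@yBreaks[-length(surface@yBreaks)]) / 2)
}

#' Detect a two-well structure along PC1
#'
#' Kernel-density estimate (Gaussian kernel, Silverman bandwidth) along
#' the pooled PC1 projections of all variants; the well boundary is the
#' location of the density minimum between the two highest local
#' maxima. Unimodal densities return an undefined boundary with a flag.
#'
#' @param pc1 numeric vector of pooled PC1 projections, `>= 100`
#'   samples.
#' @param minModeFrac minimum height of the minor mode as a fraction
#'   of the major mode, default 0.05: smaller bumps are treated as
#'   density-estimate wiggles, not wells.
#' @param minDip minimum relative dip of the inter-mode valley below
#'   the lower peak, default 0.1.
#' @return List with `boundary` (numeric or `NA`), `unimodal`
#'   (logical), `modes` (positions of the two highest maxima, or the
#'   single mode), and the `density` object.
#' @export
detectWells <- function(pc1, minModeFrac = 0.05, minDip = 0.1) {
  if (length(pc1) < 100L) stop("need at least 100 samples for a stable density")
  d <- stats::density(pc1, bw = "nrd0")
  y <- d$y
  # interior indices i with y[i-1] < y[i] >= y[i+1]
  isMax <- which(diff(sign(diff(y))) < 0) + 1L
  isMax <- isMax[y[isMax] >= minModeFrac * max(y)]
  unimodalOut <- list(boundary = NA_real_, unimodal = TRUE,
                      modes = d$x[which.max(y)], density = d)
  if (length(isMax) < 2L) return(unimodalOut)
  # the second well is the highest maximum separated from the global
  # mode by a clear valley; maxima without such a dip are wiggles of
  # the same well
  g <- isMax[which.max(y[isMax])]
  second <- NA_integer_; secondH <- 0
  for (cand in setdiff(isMax, g)) {
    valley <- min(y[seq.int(min(cand, g), max(cand, g))])
    if (valley <= (1 - minDip) * min(y[cand], y[g]) && y[cand] > secondH) {
      second <- cand; secondH <- y[cand]
    }
  }
  if (is.na(second)) return(unimodalOut)
  between <- seq.int(min(second, g), max(second, g))
  bIdx <- between[which.min(y[between])]
  list(boundary = d$x[bIdx], unimodal = FALSE,
       modes = sort(d$x[c(g, second)]), density = d)
}

#' Which side of the boundary is well II, given the WT
#'
#' Well II is defined as the side opposite the wild-type modal well
#' (the WT predominantly occupies well I).
#'
#' @param wtPc1 wild-type PC1 projections.
#' @param boundary boundary position from [detectWells()].
#' @return `"above"` or `"below"`.
#' @export
wellIISideFromWT <- function(wtPc1, boundary) {
  if (stats::median(wtPc1) > boundary) "below" else "above"
}

#' Two-well occupancy ratio of a variant
#'
#' Fraction of frames on the well-II side of the boundary:
#' `ratio = n_II / (n_I + n_II)`. A ratio of 0 means the variant never
#' samples well II; a ratio of 1 means it never samples well I.
#' Per-replicate counts are retained.
#'
#' @param pc1 variant PC1 projections (per frame).
#' @param boundary boundary from [detectWells()]; `NA` is an error
#'   directing the caller to the unimodal flag.
#' @param wellIISide `"above"` or `"below"`.
#' @param replicate optional per-frame replicate index.
#' @return A [WellStats-class].
#' @export
occupancyRatio <- function(pc1, boundary, wellIISide = c("below", "above"),
                           replicate = NULL) {
  if (is.na(boundary))
    stop("boundary undefined (unimodal density); see detectWells()$unimodal")
  wellIISide <- match.arg(wellIISide)
  if (is.null(replicate)) replicate <- rep(1L, length(pc1))
  inII <- if (wellIISide == "above") pc1 > boundary else pc1 < boundary
  reps <- sort(unique(replicate))
  cII <- vapply(reps, function(r) sum(inII[replicate == r]), integer(1))
  cI <- vapply(reps, function(r) sum(!inII[replicate == r]), integer(1))
  methods::new("WellStats", boundary = boundary, wellIISide = wellIISide,
               countI = cI, countII = cII,
               ratio = sum(cII) / (sum(cI) + sum(cII)))
}

#' @describeIn WellStats pooled occupancy ratio
#' @param x,object a `WellStats`
#' @export
setMethod("wellRatio", "WellStats", function(x) x@ratio)

setMethod("show", "WellStats", function(object) {
  cat(sprintf(
    "WellStats: boundary %.3f (well II %s), ratio %.3f (%d II / %d total frames, %d replicate(s))\n",
    object@boundary, object@wellIISide, object@ratio,
    sum(object@countII), sum(object@countI) + sum(object@countII),
    length(object@countI)))
})
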