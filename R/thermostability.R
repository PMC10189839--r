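#' @include synthetic-other.R
NULL

#' Read a melting curve from CSV
#'
#' Expects columns `temperature_C`, `ratio_350_330` (or any two
#' numeric columns in that order). Temperatures must be strictly
#' increasing with at least 20 points.
#'
#' @param path CSV file.
#' @param variantId,state optional labels attached as attributes.
#' @return `data.frame` of class `"MeltingCurve"`.
#' @export
readMeltingCurve <- function(path, variantId = NA_character_,
                             state = NA_character_) {
  df <- utils::read.csv(path)
  names(df)[1:2] <- c("temperature_C", "ratio_350_330")
  validateMeltingCurve(df)
  attr(df, "variantId") <- variantId
  attr(df, "state") <- state
  class(df) <- c("MeltingCurve", "data.frame")
  df
}

#' Validate a melting curve
#'
#' @param curve `data.frame` with `temperature_C`, `ratio_350_330`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validateMeltingCurve <- function(curve) {
  if (nrow(curve) < 20L) stop("melting curve needs at least 20 points")
  if (any(diff(curve$temperature_C) <= 0))
    stop("temperatures must be strictly increasing")
  invisible(TRUE)
}

#' Call the melting temperature from a thermal-unfolding curve
#'
#' The fluorescence ratio is differentiated with a moving polynomial
#' (Savitzky-Golay) derivative filter, and the melting temperature is
#' taken as the temperature of the first-derivative peak maximum,
#' refined below the grid spacing by the vertex of a local quadratic
#' fit around the peak. Curves without a distinct transition
#' (derivative peak prominence below `minProminence` times the
#' derivative spread) raise a no-transition error. Invariant to affine
#' rescaling of the ratio axis.
#'
#' @param curve a `"MeltingCurve"` or `data.frame` with
#'   `temperature_C`, `ratio_350_330`.
#' @param window smoothing window (points, odd), default 11.
#' @param order polynomial order, default 3.
#' @param minProminence peak prominence threshold in units of the
#'   median absolute derivative, default 5.
#' @param refineHalf half-width (points) of the local quadratic peak
#'   refinement, default 6.
#' @return Melting temperature (deg C). Secondary derivative peaks
#'   within 50% of the main peak are flagged via
#'   `attr(, "secondaryPeaks")`.
#' @export
fitTm <- function(curve, window = 11L, order = 3L, minProminence = 5,
                  refineHalf = 6L) {
  validateMeltingCurve(curve)
  tt <- curve$temperature_C
  step <- stats::median(diff(tt))
  d <- signal::sgolayfilt(curve$ratio_350_330, p = order, n = window,
                          m = 1) / step
  n <- length(d)
  p <- which.max(d)
  spread <- stats::median(abs(d))
  if (!is.finite(spread) || spread == 0) spread <- stats::sd(d)
  if (!is.finite(spread) || spread == 0 || d[p] < minProminence * spread)
    stop("no transition detected: derivative peak indistinct")
  tm <- tt[p]
  i <- max(1L, p - refineHalf):min(n, p + refineHalf)
  X <- cbind(1, tt[i], tt[i]^2)
  co <- qr.coef(qr(X), d[i])
  if (is.finite(co[3]) && co[3] < 0) {
    vertex <- -co[2] / (2 * co[3])
    if (abs(vertex - tt[p]) <= refineHalf * step) tm <- vertex
  }
  # flag secondary local maxima comparable to the main transition
  locMax <- which(diff(sign(diff(d))) < 0) + 1L
  locMax <- setdiff(locMax, p)
  sec <- tt[locMax[d[locMax] >= 0.5 * d[p] & d[locMax] > minProminence * spread]]
  attr(tm, "secondaryPeaks") <- sec
  tm
}

#' Derived melting-temperature statistics per variant
#'
#' From a table of called Tm values per variant and nucleotide state
#' (GDP and the non-hydrolyzable GTP-analog state, PNP), computes per
#' variant: `dTm_state = Tm_mut,state - Tm_WT,state`,
#' `ddTm_GDP_PNP = Tm_GDP - Tm_PNP` (within protein), and the
#' activation stability change `ddTm_star = dTm_PNP - dTm_GDP`. The
#' algebraic identity
#' `ddTm_star = ddTm_GDP_PNP(WT) - ddTm_GDP_PNP(mutant)` holds exactly
#' on every complete record; the WT record has `dTm = 0` and
#' `ddTm_star = 0`. Variants missing one state are flagged partial.
#'
#' @param tmTable `data.frame` with columns `variant`, `state`
#'   (`"GDP"` / `"PNP"`), `tm` (deg C); WT must be present in both
#'   states.
#' @param wtId wild-type label, default `"WT"`.
#' @return `data.frame` of class `"TmRecord"` with one row per variant:
#'   `variant`, `tm_gdp`, `tm_pnp`, `dtm_gdp`, `dtm_pnp`,
#'   `ddtm_gdp_pnp`, `ddtm_star`, `partial`.
#' @export
tmStatistics <- function(tmTable, wtId = "WT") {
  need <- c("variant", "state", "tm")
  if (!all(need %in% names(tmTable)))
    stop("tmTable needs columns variant, state, tm")
  getTm <- function(v, s) {
    x <- tmTable$tm[tmTable$variant == v & tmTable$state == s]
    if (length(x)) mean(x) else NA_real_
  }
  wtGdp <- getTm(wtId, "GDP"); wtPnp <- getTm(wtId, "PNP")
  if (is.na(wtGdp) || is.na(wtPnp))
    stop(sprintf("WT ('%s') must be present in both GDP and PNP states", wtId))
  variants <- unique(tmTable$variant)
  out <- do.call(rbind, lapply(variants, function(v) {
    g <- getTm(v, "GDP"); p <- getTm(v, "PNP")
    data.frame(variant = v, tm_gdp = g, tm_pnp = p,
               dtm_gdp = g - wtGdp, dtm_pnp = p - wtPnp,
               ddtm_gdp_pnp = g - p,
               ddtm_star = (p - wtPnp) - (g - wtGdp),
               partial = is.na(g) || is.na(p),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("TmRecord", "data.frame")
  out
}

#' Write a melting curve as CSV
#'
#' @param curve a melting-curve `data.frame`.
#' @param path output CSV.
#' @return The path, invisibly.
#' @export
writeMeltingCurve <- function(curve, path) {
  utils::write.csv(curve[, c("temperature_C", "ratio_350_330")], path,
                   row.names = FALSE)
  invisible(path)
}
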