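#' @include score-table.R classify.R
NULL

#' K-means groups of variants within one nucleotide state
#'
#' Standard k-means on the WT-z-standardized metric columns of one
#' state, best of `nRestarts` by within-cluster sum of squares, seeded
#' for determinism. Run independently per nucleotide state with the
#' default k = 6.
#'
#' @param x a [ScoreTable-class].
#' @param nucleotide which state to cluster.
#' @param k number of groups, default 6; must not exceed the number of
#'   variants.
#' @param seed integer seed.
#' @param nRestarts random restarts, default 50.
#' @return List with `assignments` (named integer vector over
#'   variants), `centers`, `totWithinSS`.
#' @export
kmeansGroups <- function(x, nucleotide, k = 6L, seed = 1L, nRestarts = 50L) {
  m <- stateScoreMatrix(x, nucleotide, standardize = TRUE)
  if (k > nrow(m)) stop("k must not exceed the number of variants")
  set.seed(seed)
  km <- stats::kmeans(m, centers = k, nstart = nRestarts, iter.max = 100L)
  list(assignments = stats::setNames(km$cluster, rownames(m)),
       centers = km$centers, totWithinSS = km$tot.withinss)
}

#' Ranked meta-class signatures of variant groups
#'
#' For each group, meta-classes are ranked by within-group occupancy
#' fraction (ties broken by global occupancy, then name); the retained
#' meta-class set is the union of every group's top `topN`.
#'
#' @param assignments named group vector (e.g. from [kmeansGroups()]);
#'   names are variants.
#' @param metaclassMatrix binary variant x meta-class matrix from
#'   [buildMetaclassMatrix()] (shared variants).
#' @param topN defining features kept per group, default 10.
#' @return List with `signatures` (one `data.frame` per group:
#'   `metaclass`, `occupancy`, `rank`) and `retained` (character vector
#'   of retained meta-classes).
#' @export
groupSignatures <- function(assignments, metaclassMatrix, topN = 10L) {
  shared <- intersect(names(assignments), rownames(metaclassMatrix))
  if (!length(shared)) stop("groups and matrix share no variants")
  assignments <- assignments[shared]
  M <- metaclassMatrix[shared, , drop = FALSE]
  globalOcc <- colMeans(M)
  sigs <- list(); retained <- character()
  for (g in sort(unique(assignments))) {
    members <- names(assignments)[assignments == g]
    if (!length(members)) stop(sprintf("group %s is empty", g))
    occ <- colMeans(M[members, , drop = FALSE])
    ord <- order(-occ, -globalOcc, colnames(M), method = "radix")
    df <- data.frame(metaclass = colnames(M)[ord], occupancy = occ[ord],
                     rank = seq_along(ord), row.names = NULL,
                     stringsAsFactors = FALSE)
    sigs[[as.character(g)]] <- df
    top <- df$metaclass[df$rank <= topN & df$occupancy > 0]
    retained <- union(retained, top)
  }
  list(signatures = sigs, retained = retained)
}

#' Metric cross-correlation matrix across variants
#'
#' Pearson correlations between metric columns across variants, per
#' nucleotide state; symmetric with unit diagonal. Constant columns
#' give `NA` entries with a warning.
#'
#' @param x a [ScoreTable-class] with at least 3 variants.
#' @param nucleotide state.
#' @return metrics x metrics correlation matrix.
#' @export
crossCorrelation <- function(x, nucleotide) {
  m <- stateScoreMatrix(x, nucleotide)
  m <- m[, colSums(!is.na(m)) > 0, drop = FALSE]
  if (nrow(m) < 3L) stop("need at least 3 variants")
  sdv <- apply(m, 2, stats::sd, na.rm = TRUE)
  const <- !is.na(sdv) & sdv == 0
  if (any(const))
    warning(sprintf("constant metric(s): %s; correlations undefined",
                    paste(colnames(m)[const], collapse = ", ")))
  cc <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  diag(cc) <- ifelse(const, NA_real_, 1)
  cc
}

#' 2D embedding of the score table
#'
#' Embeds every (variant, state) row of the WT-standardized metric
#' matrix into 2D through a pluggable backend. The always-available
#' `"pca"` backend uses the two leading principal components (exact
#' distance preservation for rank-2 data); `"umap"` dispatches to the
#' `uwot` or `umap` package when one is installed and errors otherwise.
#' Missing values are handled by dropping affected metric columns
#' (default) or mean imputation.
#'
#' @param x a [ScoreTable-class].
#' @param method `"pca"` (default) or `"umap"`.
#' @param seed integer seed (used by stochastic backends).
#' @param missing `"drop"` (default) or `"impute"`.
#' @param annotate optional named numeric vector (names =
#'   `variant.nucleotide`) merged into the output for coloring, e.g.
#'   melting temperatures.
#' @return `data.frame` with columns `variant`, `nucleotide`, `dim1`,
#'   `dim2`, and `annotation` if supplied.
#' @export
embed2D <- function(x, method = c("pca", "umap"), seed = 1L,
                    missing = c("drop", "impute"), annotate = NULL) {
  method <- match.arg(method); missing <- match.arg(missing)
  sc <- x@scores
  common <- Reduce(intersect,
                   lapply(unique(sc$nucleotide),
                          function(st) availableMetrics(x, st)))
  m <- do.call(rbind, lapply(unique(sc$nucleotide), function(st)
    stateScoreMatrix(x, st, standardize = TRUE, metrics = common)))
  meta <- do.call(rbind, lapply(unique(sc$nucleotide), function(st) {
    s <- sc[sc$nucleotide == st, c("variant", "nucleotide")]
    s
  }))
  if (anyNA(m)) {
    if (missing == "drop") m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
    else for (j in seq_len(ncol(m)))
      m[is.na(m[, j]), j] <- mean(m[, j], na.rm = TRUE)
  }
  if (ncol(m) < 2L) stop("fewer than 2 usable metric columns")
  set.seed(seed)
  if (method == "pca") {
    pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    xy <- pc$x[, 1:2, drop = FALSE]
  } else {
    if (requireNamespace("uwot", quietly = TRUE)) {
      xy <- uwot::umap(m, n_components = 2)
    } else if (requireNamespace("umap", quietly = TRUE)) {
      xy <- umap::umap(m)$layout
    } else {
      stop("no UMAP backend installed; use method = 'pca'")
    }
  }
  out <- data.frame(variant = meta$variant, nucleotide = meta$nucleotide,
                    dim1 = xy[, 1], dim2 = xy[, 2], stringsAsFactors = FALSE)
  if (!is.null(annotate)) {
    key <- paste(out$variant, out$nucleotide, sep = ".")
    out$annotation <- as.numeric(annotate[key])
  }
  rownames(out) <- NULL
  out
}
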