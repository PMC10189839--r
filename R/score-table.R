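#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a ScoreTable
#'
#' @param scores `data.frame` with columns `variant`, `nucleotide`,
#'   then one numeric column per metric.
#' @param wt `data.frame` of wild-type reference statistics with
#'   columns `metric`, `nucleotide`, `mean`, `sd`, `median`.
#' @param wtId variant label of the wild-type row(s), default `"WT"`.
#' @return A [ScoreTable-class] object.
#' @seealso [generateScoreTable()], [buildMetaclassMatrix()]
#' @export
scoreTable <- function(scores, wt, wtId = "WT") {
  methods::new("ScoreTable", scores = scores, wt = wt, wtId = wtId)
}

#' @describeIn ScoreTable score rows
#' @param x,object a `ScoreTable`
#' @export
setMethod("scoreData", "ScoreTable", function(x) x@scores)

#' @describeIn ScoreTable wild-type reference statistics
#' @export
setMethod("wtStats", "ScoreTable", function(x) x@wt)

#' @describeIn ScoreTable wild-type variant label
#' @export
setMethod("variantId", "ScoreTable", function(x) x@wtId)

#' Metric column names of a ScoreTable
#'
#' @param x a [ScoreTable-class].
#' @return Character vector of metric names.
#' @export
metricNames <- function(x) {
  setdiff(names(x@scores), c("variant", "nucleotide"))
}

#' Look up WT statistics for one metric and state
#'
#' @param x a [ScoreTable-class].
#' @param metric metric name.
#' @param nucleotide state.
#' @return One-row `data.frame` with `mean`, `sd`, `median`.
#' @export
wtStat <- function(x, metric, nucleotide) {
  w <- x@wt[x@wt$metric == metric & x@wt$nucleotide == nucleotide, , drop = FALSE]
  if (nrow(w) != 1L)
    stop(sprintf("missing WT statistics for metric '%s' (%s)", metric, nucleotide))
  w
}

#' Metrics with WT statistics available for a state
#'
#' @param x a [ScoreTable-class].
#' @param nucleotide state.
#' @return Character vector of metric names that have a WT reference
#'   row for this state.
#' @export
availableMetrics <- function(x, nucleotide) {
  intersect(metricNames(x),
            x@wt$metric[x@wt$nucleotide == nucleotide])
}

#' Extract the score matrix for one nucleotide state
#'
#' @param x a [ScoreTable-class].
#' @param nucleotide state to extract.
#' @param standardize if `TRUE`, z-standardize each metric by its WT
#'   mean and SD; metrics lacking WT statistics for this state are
#'   dropped unless explicitly requested via `metrics`.
#' @param metrics optional metric subset.
#' @return Numeric matrix, variants x metrics, rownames = variant.
#' @export
stateScoreMatrix <- function(x, nucleotide, standardize = FALSE,
                             metrics = NULL) {
  if (is.null(metrics))
    metrics <- if (standardize) availableMetrics(x, nucleotide)
               else metricNames(x)
  sc <- x@scores[x@scores$nucleotide == nucleotide, , drop = FALSE]
  m <- as.matrix(sc[, metrics, drop = FALSE])
  rownames(m) <- sc$variant
  if (standardize) {
    for (j in colnames(m)) {
      w <- wtStat(x, j, nucleotide)
      if (!is.finite(w$sd) || w$sd <= 0)
        stop(sprintf("WT SD is zero for metric '%s'", j))
      m[, j] <- (m[, j] - w$mean) / w$sd
    }
  }
  m
}

setMethod("show", "ScoreTable", function(object) {
  cat(sprintf("ScoreTable: %d rows (%d variants x states %s), %d metrics\n",
              nrow(object@scores), length(unique(object@scores$variant)),
              paste(unique(object@scores$nucleotide), collapse = "/"),
              length(metricNames(object))))
})

#' Write / read a ScoreTable as CSV
#'
#' Two files are used: the scores themselves and the WT reference
#' statistics (`<stem>.csv`, `<stem>_wt_stats.csv`).
#'
#' @param x a [ScoreTable-class].
#' @param stem path stem without extension.
#' @return `writeScoreTable` returns the two paths invisibly;
#'   `readScoreTable` returns a [ScoreTable-class].
#' @export
writeScoreTable <- function(x, stem) {
  p1 <- paste0(stem, ".csv"); p2 <- paste0(stem, "_wt_stats.csv")
  utils::write.csv(x@scores, p1, row.names = FALSE)
  utils::write.csv(x@wt, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' @rdname writeScoreTable
#' @param wtId wild-type variant label.
#' @export
readScoreTable <- function(stem, wtId = "WT") {
  scoreTable(utils::read.csv(paste0(stem, ".csv"), stringsAsFactors = FALSE),
             utils::read.csv(paste0(stem, "_wt_stats.csv"), stringsAsFactors = FALSE),
             wtId = wtId)
}
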