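#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a RegionMap
#'
#' @param ... named inclusive residue ranges, each a length-2 integer
#'   vector, e.g. `switch1 = c(25, 40)`.
#' @param alignmentExclusions character vector of region names to drop
#'   from superposition fits.
#' @return A [RegionMap-class] object.
#' @examples
#' rm <- regionMap(p_loop = c(10, 17), switch1 = c(25, 40),
#'                 alignmentExclusions = "switch1")
#' regionRanges(rm)
#' @export
regionMap <- function(..., alignmentExclusions = character()) {
  regions <- lapply(list(...), function(r) as.integer(r))
  methods::new("RegionMap", regions = regions,
               alignmentExclusions = alignmentExclusions)
}

#' Default KRAS region map
#'
#' Residue ranges for the 1-169 KRAS construct: phosphate-binding loop
#' 10-17, Switch 1 25-40, Switch 2 57-75, C-terminal allosteric lobe
#' 87-166. The two mobile switch loops are excluded from superposition
#' fits by default. All ranges are configurable via [regionMap()].
#'
#' @return A [RegionMap-class] object.
#' @export
krasRegionMap <- function() {
  regionMap(
    p_loop = c(10L, 17L), switch1 = c(25L, 40L), switch2 = c(57L, 75L),
    allosteric_lobe = c(87L, 166L),
    alignmentExclusions = c("switch1", "switch2"))
}

#' @describeIn RegionMap named residue ranges
#' @param x,object a `RegionMap`
#' @export
setMethod("regionRanges", "RegionMap", function(x) x@regions)

#' Residues belonging to a set of regions
#'
#' @param map a [RegionMap-class].
#' @param which region names; defaults to all.
#' @return Sorted integer vector of residue numbers.
#' @export
regionResidues <- function(map, which = names(regionRanges(map))) {
  rr <- regionRanges(map)[which]
  sort(unique(unlist(lapply(rr, function(r) seq.int(r[1], r[2])))))
}

#' Residues excluded from alignment fits
#'
#' @param map a [RegionMap-class].
#' @return Integer vector (possibly empty) of excluded residue numbers.
#' @export
alignmentExcludedResidues <- function(map) {
  if (length(map@alignmentExclusions) == 0L) return(integer())
  regionResidues(map, map@alignmentExclusions)
}

setMethod("show", "RegionMap", function(object) {
  cat("RegionMap:\n")
  for (nm in names(object@regions)) {
    r <- object@regions[[nm]]
    cat(sprintf("  %-16s %d-%d%s\n", nm, r[1], r[2],
                if (nm %in% object@alignmentExclusions) "  (excluded from fits)" else ""))
  }
})
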