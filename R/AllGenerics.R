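#' Genetic position of a physical position
#'
#' Linear interpolation of cumulative genetic distance (cM) between map
#' anchors; beyond the terminal anchors, linear extrapolation using the
#' terminal anchor's local rate. Exact at anchors, vectorised over
#' \code{pos_bp}, and non-decreasing in \code{pos_bp}.
#'
#' @param map a [GeneticMap-class].
#' @param chrom chromosome label present in the map.
#' @param pos_bp physical position(s), bp.
#' @return genetic position(s) in cM.
#' @examples
#' gm <- uniformGeneticMap("chr1", rate_cm_mb = 1)
#' cmAt(gm, "chr1", 2.5e6) # 2.5 cM
#' @export
setGeneric("cmAt", function(map, chrom, pos_bp) standardGeneric("cmAt"))

#' Physical position of a genetic position (inverse map lookup)
#'
#' Inverse of [cmAt()]: returns the physical position whose interpolated
#' genetic position equals \code{cm}. Within zero-rate plateaus the leftmost
#' position is returned.
#'
#' @param map a [GeneticMap-class].
#' @param chrom chromosome label present in the map.
#' @param cm genetic position(s), cM.
#' @return physical position(s) in bp.
#' @export
setGeneric("bpAt", function(map, chrom, cm) standardGeneric("bpAt"))

#' @rdname HaplotypePanel-class
#' @param x a HaplotypePanel or FlankWindow.
#' @export
setGeneric("alleleMatrix", function(x) standardGeneric("alleleMatrix"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("snpPositions", function(x) standardGeneric("snpPositions"))

#' @rdname HaplotypePanel-class
#' @export
setGeneric("hapIds", function(x) standardGeneric("hapIds"))
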