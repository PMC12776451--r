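#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges granges
#' @importFrom IRanges IRanges
NULL

#' CNVCalls: per-sample copy-number variant calls
#'
#' A \code{GRanges} subclass holding one interval call per row with the
#' metadata columns \code{sample_id}, \code{state} (\code{"DEL"} or
#' \code{"DUP"}), \code{n_probes} (array SNPs spanned), \code{caller} and
#' optionally \code{copy_number} (0--4). Coordinates are 1-based inclusive,
#' so the width of a range equals \code{end - start + 1}.
#'
#' @slot .
#'   inherits all slots from \code{GRanges}; all call-level information lives
#'   in the metadata columns listed above.
#' @seealso [CNVCalls()] for the constructor, [readCnvCalls()] for the TSV
#'   reader.
#' @exportClass CNVCalls
setClass("CNVCalls", contains = "GRanges")

.validCNVCalls <- function(object) {
  msg <- character()
  mc <- mcols(object)
  need <- c("sample_id", "state", "n_probes", "caller")
  miss <- setdiff(need, colnames(mc))
  if (length(miss))
    return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
  if (length(object)) {
    if (!all(mc$state %in% c("DEL", "DUP")))
      msg <- c(msg, "state must be 'DEL' or 'DUP'")
    if (any(is.na(mc$n_probes)) || any(mc$n_probes < 1))
      msg <- c(msg, "n_probes must be >= 1")
    if ("copy_number" %in% colnames(mc)) {
      cn <- mc$copy_number
      ok <- is.na(cn) |
        (mc$state == "DEL" & cn < 2) |
        (mc$state == "DUP" & cn > 2)
      if (!all(ok))
        msg <- c(msg, "copy_number inconsistent with state (DEL needs cn<2, DUP cn>2)")
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("CNVCalls", .validCNVCalls)

#' Construct a CNVCalls object
#'
#' @param sample_id character vector of sample identifiers.
#' @param chrom chromosome labels.
#' @param start,end 1-based inclusive interval boundaries.
#' @param state `"DEL"` or `"DUP"` per call.
#' @param n_probes number of array SNPs spanned by each call.
#' @param caller caller label (recycled if length 1).
#' @param copy_number optional integer copy number (0--4); `NA` allowed.
#' @return a [CNVCalls-class] object.
#' @examples
#' CNVCalls("S1", "chr6", 31355318, 31451476, "DEL", 50, "callerA")
#' @export
CNVCalls <- function(sample_id = character(), chrom = character(),
                     start = integer(), end = integer(), state = character(),
                     n_probes = integer(), caller = character(),
                     copy_number = NA_integer_) {
  n <- max(length(sample_id), length(chrom), length(start), length(end),
           length(state), length(n_probes))
  if (length(start) == 0L) n <- 0L
  gr <- GRanges(rep_len(as.character(chrom), n),
                IRanges(start = rep_len(as.numeric(start), n),
                        end = rep_len(as.numeric(end), n)))
  mcols(gr) <- DataFrame(
    sample_id = rep_len(as.character(sample_id), n),
    state = rep_len(as.character(state), n),
    n_probes = rep_len(as.integer(n_probes), n),
    caller = rep_len(as.character(caller), n),
    copy_number = rep_len(as.integer(copy_number), n)
  )
  new("CNVCalls", gr)
}

#' GeneticMap: piecewise-linear genetic map
#'
#' Stores, per chromosome, ordered anchors of physical position (bp),
#' local recombination rate (cM/Mb) and cumulative genetic position (cM).
#' Genetic positions between anchors are linearly interpolated; beyond the
#' terminal anchors they are extrapolated with the terminal anchor's rate.
#'
#' @slot maps named list (one element per chromosome) of data.frames with
#'   columns \code{pos_bp}, \code{rate_cm_mb}, \code{cm}; positions strictly
#'   increasing, cumulative cM non-decreasing, rates non-negative.
#' @seealso [readGeneticMap()], [uniformGeneticMap()], [cmAt()], [bpAt()]
#' @exportClass GeneticMap
setClass("GeneticMap", representation(maps = "list"))

.validGeneticMap <- function(object) {
  for (chrom in names(object@maps)) {
    m <- object@maps[[chrom]]
    if (!all(c("pos_bp", "rate_cm_mb", "cm") %in% names(m)))
      return(sprintf("chromosome %s: anchor table lacks required columns", chrom))
    if (nrow(m) == 0L) return(sprintf("chromosome %s: no anchors", chrom))
    if (is.unsorted(m$pos_bp, strictly = TRUE))
      return(sprintf("chromosome %s: positions not strictly increasing", chrom))
    if (is.unsorted(m$cm))
      return(sprintf("chromosome %s: cumulative cM decreasing", chrom))
    if (any(m$rate_cm_mb < 0))
      return(sprintf("chromosome %s: negative recombination rate", chrom))
  }
  TRUE
}
setValidity("GeneticMap", .validGeneticMap)

#' HaplotypePanel: phased biallelic haplotypes over ordered SNPs
#'
#' @slot alleles integer matrix of 0/1 allele codes, one row per haplotype
#'   (rownames are haplotype ids, conventionally \code{<sample>_h1} /
#'   \code{<sample>_h2}), one column per SNP in position order.
#' @slot positions numeric vector of SNP positions (bp), strictly increasing.
#' @slot chrom single chromosome label.
#' @seealso [HaplotypePanel()], [readHaplotypes()], [buildFlankWindow()]
#' @exportClass HaplotypePanel
setClass("HaplotypePanel",
         representation(alleles = "matrix", positions = "numeric",
                        chrom = "character"))

.validHaplotypePanel <- function(object) {
  if (ncol(object@alleles) != length(object@positions))
    return("allele matrix columns must match number of SNP positions")
  if (length(object@positions) && is.unsorted(object@positions, strictly = TRUE))
    return("SNP positions must be strictly increasing")
  if (length(object@alleles) && !all(object@alleles %in% c(0L, 1L)))
    return("alleles must be coded 0/1")
  if (is.null(rownames(object@alleles)) && nrow(object@alleles) > 0)
    return("haplotypes must be named (rownames of the allele matrix)")
  if (length(object@chrom) != 1L)
    return("chrom must be a single label")
  TRUE
}
setValidity("HaplotypePanel", .validHaplotypePanel)

#' Construct a HaplotypePanel
#'
#' @param alleles 0/1 matrix, haplotypes in rows (rownames = haplotype ids),
#'   SNPs in columns.
#' @param positions SNP positions in bp, ascending, one per column.
#' @param chrom chromosome label.
#' @return a [HaplotypePanel-class] object.
#' @export
HaplotypePanel <- function(alleles, positions, chrom) {
  storage.mode(alleles) <- "integer"
  new("HaplotypePanel", alleles = alleles, positions = as.numeric(positions),
      chrom = as.character(chrom))
}

#' FlankWindow: SNPs flanking a candidate recurrent CNV
#'
#' The window holds the `n` SNPs nearest the CNV on each side (default 60),
#' strictly outside the CNV interval, together with the haplotype alleles
#' restricted to those SNPs. Columns are in genomic order; the first
#' \code{nLeft} columns lie upstream of the CNV start.
#'
#' @slot alleles haplotype-by-SNP 0/1 matrix over the window SNPs.
#' @slot positions window SNP positions (bp), ascending.
#' @slot chrom chromosome label.
#' @slot regionStart,regionEnd CNV boundaries (1-based inclusive bp).
#' @slot nLeft,nRight number of SNPs on each side.
#' @slot shortLeft,shortRight TRUE when fewer than the requested SNPs were
#'   available on that side.
#' @seealso [buildFlankWindow()], [extendShared()], [sharedSegments()]
#' @exportClass FlankWindow
setClass("FlankWindow",
         representation(alleles = "matrix", positions = "numeric",
                        chrom = "character", regionStart = "numeric",
                        regionEnd = "numeric", nLeft = "integer",
                        nRight = "integer", shortLeft = "logical",
                        shortRight = "logical"))

setValidity("FlankWindow", function(object) {
  if (ncol(object@alleles) != length(object@positions))
    return("allele matrix columns must match window positions")
  if (object@nLeft + object@nRight != length(object@positions))
    return("nLeft + nRight must equal the number of window SNPs")
  inside <- object@positions >= object@regionStart &
    object@positions <= object@regionEnd
  if (any(inside)) return("window SNPs must lie strictly outside the CNV")
  TRUE
})

#' AgeEstimate: Gamma-method coalescence age of a recurrent CNV
#'
#' Holds the age estimate tau (generations), its ingredients and a
#' chi-square-pivot confidence interval. Under the independence model each
#' carrier haplotype's shared flank length (left + right, in Morgans) is the
#' sum of two exponentials with rate tau, so tau-hat = 2 / l_ave.
#'
#' @slot tau point estimate, generations.
#' @slot lAve (weighted) mean shared genetic length, Morgans.
#' @slot n number of haplotypes entering the estimate.
#' @slot ciLow,ciHigh confidence bounds, generations.
#' @slot alpha interval level is \code{1 - alpha}.
#' @slot weightingMode \code{"per_haplotype"} or \code{"per_breakpoint_group"}.
#' @slot weights named numeric: haplotype count per breakpoint group.
#' @slot nCensored number of censored segments excluded.
#' @seealso [estimateTau()], [tauConfidence()]
#' @exportClass AgeEstimate
setClass("AgeEstimate",
         representation(tau = "numeric", lAve = "numeric", n = "integer",
                        ciLow = "numeric", ciHigh = "numeric",
                        alpha = "numeric", weightingMode = "character",
                        weights = "numeric", nCensored = "integer"))

setValidity("AgeEstimate", function(object) {
  if (object@lAve <= 0) return("l_ave must be positive")
  if (abs(object@tau - 2 / object@lAve) > 1e-8 * object@tau)
    return("tau must equal 2 / l_ave")
  if (length(object@ciLow) && length(object@ciHigh) &&
      object@ciLow > object@ciHigh)
    return("ci_low must not exceed ci_high")
  TRUE
})
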