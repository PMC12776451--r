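#' Build the SNP window flanking a candidate recurrent CNV
#'
#' Selects the \code{nSnps} SNPs nearest the CNV on each side, strictly
#' outside \code{[regionStart, regionEnd]}. When a side holds fewer SNPs
#' than requested, all of them are taken and the side is flagged short; a
#' side with no SNPs at all is an error.
#'
#' @param panel a [HaplotypePanel-class] covering the CNV's chromosome.
#' @param regionStart,regionEnd CNV boundaries, 1-based inclusive bp.
#' @param nSnps SNPs to take per side (default 60).
#' @return a [FlankWindow-class].
#' @export
buildFlankWindow <- function(panel, regionStart, regionEnd, nSnps = 60) {
  pos <- panel@positions
  left <- which(pos < regionStart)
  right <- which(pos > regionEnd)
  if (!length(left)) stop("no SNPs upstream of the CNV region")
  if (!length(right)) stop("no SNPs downstream of the CNV region")
  shortLeft <- length(left) < nSnps
  shortRight <- length(right) < nSnps
  left <- utils::tail(left, nSnps)
  right <- utils::head(right, nSnps)
  cols <- c(left, right)
  new("FlankWindow",
      alleles = panel@alleles[, cols, drop = FALSE],
      positions = pos[cols], chrom = panel@chrom,
      regionStart = as.numeric(regionStart),
      regionEnd = as.numeric(regionEnd),
      nLeft = length(left), nRight = length(right),
      shortLeft = shortLeft, shortRight = shortRight)
}

#' Consensus (putative ancestral) haplotype of CNV carriers
#'
#' Per-SNP modal allele among the carrier haplotypes. A recurrent CNV
#' descending from one ancestor sits on a characteristic haplotype, which
#' the consensus reconstructs. Ties take the allele of the haplotype with
#' the lexicographically first id (deterministic).
#'
#' @param x a [FlankWindow-class] or 0/1 allele matrix (haplotypes in rows,
#'   rownames = haplotype ids).
#' @param hapIds haplotype ids to use (default: all rows).
#' @return integer 0/1 vector, one allele per SNP.
#' @export
consensusHaplotype <- function(x, hapIds = NULL) {
  al <- if (is(x, "FlankWindow")) x@alleles else x
  if (!is.null(hapIds)) al <- al[hapIds, , drop = FALSE]
  if (nrow(al) == 0L) stop("no carrier haplotypes")
  first <- al[order(rownames(al))[1], ]
  ones <- colSums(al)
  n <- nrow(al)
  out <- integer(ncol(al))
  out[ones * 2 > n] <- 1L
  tie <- ones * 2 == n
  out[tie] <- first[tie]
  out
}

## Core outward walk over a mismatch pattern, one side of the CNV.
## match: logical vector ordered outward from the CNV boundary.
## A mismatch at step i is rescued when the next rescueK SNPs outward all
## match (all remaining ones, if fewer than rescueK remain); an empty
## look-ahead rescues nothing, so rescueK = 0 stops at the first mismatch.
.walkShared <- function(match, rescueK) {
  m <- length(match)
  last <- 0L
  rescued <- 0L
  i <- 1L
  while (i <= m) {
    if (match[i]) {
      last <- i
    } else {
      ahead <- seq.int(i + 1L, length.out = min(rescueK, m - i))
      if (length(ahead) && all(match[ahead])) {
        rescued <- rescued + 1L
      } else break
    }
    i <- i + 1L
  }
  list(terminus = last, n_rescued = rescued, censored = last == m)
}

#' Extend a shared haplotype outward from the CNV boundary
#'
#' Walks SNP by SNP away from the CNV, comparing the carrier haplotype to
#' the reference (consensus/ancestral) haplotype. A mismatching SNP is
#' "rescued" -- treated as a point mutation or genotyping error -- when the
#' \code{rescueK} SNPs beyond it all match (all remaining SNPs when fewer
#' than \code{rescueK} are left); otherwise the shared segment ends at the
#' last matching SNP. Reaching the window edge censors the segment.
#'
#' @param hap carrier haplotype: 0/1 vector over the window's SNPs, or a
#'   haplotype id found in the window.
#' @param consensus reference haplotype over the window's SNPs.
#' @param window a [FlankWindow-class].
#' @param direction `"left"` (upstream) or `"right"` (downstream).
#' @param rescueK look-ahead length for the rescue rule (default 5; 0
#'   disables rescue, `Inf` requires all remaining SNPs to match).
#' @return list with \code{terminus} (number of SNPs reached, 0 = none),
#'   \code{terminus_bp} (position of the last matching SNP, or the CNV
#'   boundary when no SNP matched), \code{n_rescued} and \code{censored}.
#' @export
extendShared <- function(hap, consensus, window,
                         direction = c("left", "right"), rescueK = 5) {
  direction <- match.arg(direction)
  if (is.character(hap) && length(hap) == 1L)
    hap <- window@alleles[hap, ]
  stopifnot(length(hap) == ncol(window@alleles),
            length(consensus) == ncol(window@alleles))
  nL <- window@nLeft
  if (direction == "left") {
    idx <- rev(seq_len(nL))                    # outward: decreasing position
    boundary <- window@regionStart
  } else {
    idx <- nL + seq_len(window@nRight)         # outward: increasing position
    boundary <- window@regionEnd
  }
  walk <- .walkShared(hap[idx] == consensus[idx], rescueK)
  walk$terminus_bp <- if (walk$terminus == 0L) boundary else
    window@positions[idx[walk$terminus]]
  walk
}

#' Maximal shared flanking segment of one carrier haplotype
#'
#' Runs [extendShared()] in both directions and converts the termini to a
#' genetic length on the map: the sum of the upstream and downstream shared
#' genetic distances, in Morgans. This length is the per-haplotype input
#' l_i of the Gamma age estimator.
#'
#' @inheritParams extendShared
#' @param map a [GeneticMap-class] covering the window.
#' @param hapId label stored on the output row (defaults to \code{hap} when
#'   that is an id).
#' @return one-row data.frame: \code{hap_id}, \code{left_terminus_bp},
#'   \code{right_terminus_bp}, \code{censored_left}, \code{censored_right},
#'   \code{n_rescued}, \code{length_bp}, \code{genetic_length_morgans}.
#' @export
sharedSegment <- function(hap, consensus, window, map, rescueK = 5,
                          hapId = NULL) {
  if (is.null(hapId))
    hapId <- if (is.character(hap) && length(hap) == 1L) hap else NA_character_
  L <- extendShared(hap, consensus, window, "left", rescueK)
  R <- extendShared(hap, consensus, window, "right", rescueK)
  chrom <- window@chrom
  gl <- (cmAt(map, chrom, window@regionStart) -
           cmAt(map, chrom, L$terminus_bp) +
           cmAt(map, chrom, R$terminus_bp) -
           cmAt(map, chrom, window@regionEnd)) / 100
  data.frame(
    hap_id = hapId,
    left_terminus_bp = L$terminus_bp,
    right_terminus_bp = R$terminus_bp,
    censored_left = L$censored,
    censored_right = R$censored,
    n_rescued = L$n_rescued + R$n_rescued,
    length_bp = (window@regionStart - L$terminus_bp) +
      (R$terminus_bp - window@regionEnd),
    genetic_length_morgans = gl,
    stringsAsFactors = FALSE
  )
}

#' Shared flanking segments for a set of carrier haplotypes
#'
#' Consensus mode (default) measures every carrier haplotype against the
#' modal carrier haplotype (or a supplied reference). Pairwise mode takes,
#' per haplotype and side, the longest extension against any other carrier
#' haplotype.
#'
#' @param window a [FlankWindow-class].
#' @param carrierHapIds haplotype ids of the CNV-bearing chromosomes.
#' @param map a [GeneticMap-class].
#' @param rescueK rescue look-ahead (default 5).
#' @param mode `"consensus"` or `"pairwise"`.
#' @param reference optional reference haplotype overriding the computed
#'   consensus (e.g. a known ancestral haplotype in simulations).
#' @return data.frame, one row per carrier haplotype (see [sharedSegment()]).
#' @export
sharedSegments <- function(window, carrierHapIds, map, rescueK = 5,
                           mode = c("consensus", "pairwise"),
                           reference = NULL) {
  mode <- match.arg(mode)
  if (mode == "consensus") {
    cons <- if (is.null(reference))
      consensusHaplotype(window, carrierHapIds) else reference
    out <- do.call(rbind, lapply(carrierHapIds, function(h)
      sharedSegment(h, cons, window, map, rescueK)))
    rownames(out) <- NULL
    return(out)
  }
  out <- do.call(rbind, lapply(carrierHapIds, function(h) {
    others <- setdiff(carrierHapIds, h)
    if (!length(others)) stop("pairwise mode needs >= 2 carrier haplotypes")
    segs <- lapply(others, function(o)
      sharedSegment(h, window@alleles[o, ], window, map, rescueK, hapId = h))
    best_left <- which.min(vapply(segs, `[[`, numeric(1), "left_terminus_bp"))
    best_right <- which.max(vapply(segs, `[[`, numeric(1),
                                   "right_terminus_bp"))
    sL <- segs[[best_left]]; sR <- segs[[best_right]]
    data.frame(
      hap_id = h,
      left_terminus_bp = sL$left_terminus_bp,
      right_terminus_bp = sR$right_terminus_bp,
      censored_left = sL$censored_left,
      censored_right = sR$censored_right,
      n_rescued = NA_integer_,
      length_bp = (window@regionStart - sL$left_terminus_bp) +
        (sR$right_terminus_bp - window@regionEnd),
      genetic_length_morgans =
        (cmAt(map, window@chrom, window@regionStart) -
           cmAt(map, window@chrom, sL$left_terminus_bp) +
           cmAt(map, window@chrom, sR$right_terminus_bp) -
           cmAt(map, window@chrom, window@regionEnd)) / 100,
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Drop close relatives from a haplotype set
#'
#' Given pairs of related samples (first/second degree, precomputed
#' externally), repeatedly removes the sample participating in the most
#' remaining pairs (ties broken lexicographically) until no related pair is
#' left. Both haplotypes of a dropped sample are removed.
#'
#' @param hapIds haplotype ids, \code{<sample>_h1} / \code{<sample>_h2} (or
#'   bare sample ids).
#' @param relatedPairs two-column matrix/data.frame of related sample pairs.
#' @return the retained haplotype ids.
#' @export
excludeRelatives <- function(hapIds, relatedPairs) {
  if (is.null(relatedPairs) || nrow(relatedPairs) == 0L) return(hapIds)
  samples <- unique(sub("_h[12]$", "", hapIds))
  pairs <- as.matrix(relatedPairs[, 1:2])
  pairs <- pairs[pairs[, 1] %in% samples & pairs[, 2] %in% samples, ,
                 drop = FALSE]
  dropped <- character()
  while (nrow(pairs) > 0L) {
    deg <- sort(table(c(pairs[, 1], pairs[, 2])), decreasing = TRUE)
    top <- names(deg)[deg == max(deg)]
    victim <- sort(top)[1]
    dropped <- c(dropped, victim)
    pairs <- pairs[pairs[, 1] != victim & pairs[, 2] != victim, ,
                   drop = FALSE]
  }
  keep_sample <- sub("_h[12]$", "", hapIds)
  hapIds[!(keep_sample %in% dropped)]
}
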