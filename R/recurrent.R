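.modal <- function(x) {
  tab <- table(x)
  cand <- as.numeric(names(tab)[tab == max(tab)])
  min(cand)  # ties -> smallest coordinate
}

#' Cluster CNV calls into recurrent groups by shared breakpoints
#'
#' Same-chromosome, same-state calls whose start boundaries differ by at
#' most \code{bpTolerance} AND whose end boundaries differ by at most
#' \code{bpTolerance} are joined by single linkage. The default tolerance of
#' 0 bp requires exact probe-level boundary agreement, as expected for
#' recurrent events genotyped on one array. The group region is the modal
#' start/end over members (ties to the smallest coordinate) and a group is
#' flagged recurrent when carried by two or more distinct samples.
#'
#' @param calls a [CNVCalls-class] from one population/array.
#' @param bpTolerance non-negative breakpoint tolerance in bp.
#' @param nIndividuals cohort size for carrier frequencies (carriers /
#'   individuals); allele frequency additionally counts two alleles for
#'   members whose copy number marks them homozygous (0 or 4).
#' @param population optional population label stored on every group.
#' @return data.frame with one row per group: \code{chrom}, \code{start},
#'   \code{end}, \code{state}, \code{population}, \code{n_carriers},
#'   \code{carrier_freq}, \code{carrier_freq_2dp} (truncated, display
#'   convention), \code{allele_freq}, \code{recurrent} and a list column
#'   \code{samples}.
#' @export
clusterRecurrent <- function(calls, bpTolerance = 0, nIndividuals = NA,
                             population = NA_character_) {
  stopifnot(bpTolerance >= 0)
  df <- .callDf(calls)
  df$copy_number <- mcols(calls)$copy_number
  out <- list()
  for (k in unique(paste(df$chrom, df$state, sep = "\r"))) {
    idx <- which(paste(df$chrom, df$state, sep = "\r") == k)
    n <- length(idx)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        if (abs(df$start[idx[i]] - df$start[idx[j]]) <= bpTolerance &&
            abs(df$end[idx[i]] - df$end[idx[j]]) <= bpTolerance) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    for (g in unique(comp)) {
      members <- idx[comp == g]
      samples <- sort(unique(df$sample[members]))
      cn <- df$copy_number[members][match(samples, df$sample[members])]
      n_alleles <- sum(ifelse(!is.na(cn) & cn %in% c(0L, 4L), 2L, 1L))
      out[[length(out) + 1L]] <- data.frame(
        chrom = df$chrom[members[1]],
        start = .modal(df$start[members]),
        end = .modal(df$end[members]),
        state = df$state[members[1]],
        population = population,
        n_carriers = length(samples),
        carrier_freq = if (is.na(nIndividuals)) NA_real_ else
          length(samples) / nIndividuals,
        allele_freq = if (is.na(nIndividuals)) NA_real_ else
          n_alleles / (2 * nIndividuals),
        recurrent = length(samples) >= 2L,
        samples = I(list(samples)),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), state = character(),
                      population = character(), n_carriers = integer(),
                      carrier_freq = numeric(), allele_freq = numeric(),
                      recurrent = logical(), samples = I(list()),
                      carrier_freq_2dp = numeric()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$end, res$state), , drop = FALSE]
  rownames(res) <- NULL
  ## display column: 2-decimal truncation, alongside full precision
  res$carrier_freq_2dp <- floor(res$carrier_freq * 100) / 100
  res
}

#' Match recurrent groups across two populations
#'
#' Groups genotyped on different arrays rarely share exact boundaries, so
#' matching uses reciprocal overlap: pairs with equal state whose overlap
#' covers at least \code{minRecipOverlap} of both regions, assigned
#' one-to-one greedily by greatest overlap.
#'
#' @param groupsA,groupsB group tables from [clusterRecurrent()].
#' @param minRecipOverlap reciprocal-overlap threshold (default 0.8).
#' @return data.frame of matched pairs with indices into the two inputs,
#'   the shared state, region coordinates and both overlap fractions.
#' @export
matchAcrossPopulations <- function(groupsA, groupsB, minRecipOverlap = 0.8) {
  cand <- NULL
  for (i in seq_len(nrow(groupsA))) {
    for (j in seq_len(nrow(groupsB))) {
      if (groupsA$chrom[i] != groupsB$chrom[j]) next
      if (groupsA$state[i] != groupsB$state[j]) next
      ov <- min(groupsA$end[i], groupsB$end[j]) -
        max(groupsA$start[i], groupsB$start[j]) + 1
      if (ov <= 0) next
      fa <- ov / (groupsA$end[i] - groupsA$start[i] + 1)
      fb <- ov / (groupsB$end[j] - groupsB$start[j] + 1)
      if (fa >= minRecipOverlap && fb >= minRecipOverlap)
        cand <- rbind(cand, data.frame(i = i, j = j, ov = ov,
                                       overlap_a = fa, overlap_b = fb))
    }
  }
  empty <- data.frame(index_a = integer(), index_b = integer(),
                      chrom = character(), state = character(),
                      start_a = numeric(), end_a = numeric(),
                      start_b = numeric(), end_b = numeric(),
                      overlap_a = numeric(), overlap_b = numeric())
  if (is.null(cand)) return(empty)
  cand <- cand[order(-cand$ov, cand$i, cand$j), , drop = FALSE]
  used_a <- logical(nrow(groupsA)); used_b <- logical(nrow(groupsB))
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      index_a = i, index_b = j,
      chrom = groupsA$chrom[i], state = groupsA$state[i],
      start_a = groupsA$start[i], end_a = groupsA$end[i],
      start_b = groupsB$start[j], end_b = groupsB$end[j],
      overlap_a = cand$overlap_a[r], overlap_b = cand$overlap_b[r])
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Select recurrent groups eligible for association testing
#'
#' Eligibility requires enough carriers for a detectable large effect:
#' \code{n_carriers >= minCarriers} and \code{carrier_freq > minFrequency}
#' (strict, so a frequency exactly at the threshold is excluded).
#'
#' @param groups group table from [clusterRecurrent()].
#' @param minCarriers minimum carrier count.
#' @param minFrequency carrier-frequency threshold (default 0.022, the
#'   frequency above which an odds ratio of 10 is detectable with 80% power
#'   at these cohort sizes).
#' @return the eligible subset of \code{groups}.
#' @export
selectTestable <- function(groups, minCarriers, minFrequency = 0.022) {
  keep <- groups$n_carriers >= minCarriers &
    !is.na(groups$carrier_freq) & groups$carrier_freq > minFrequency
  groups[keep, , drop = FALSE]
}
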