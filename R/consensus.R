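.isAutosome <- function(chrom) {
  core <- sub("^chr", "", as.character(chrom))
  suppressWarnings(!is.na(as.integer(core)) & as.integer(core) >= 1 &
                     as.integer(core) <= 22)
}

.callDf <- function(calls) {
  data.frame(
    sample = mcols(calls)$sample_id,
    chrom = as.character(GenomicRanges::seqnames(calls)),
    start = GenomicRanges::start(calls),
    end = GenomicRanges::end(calls),
    state = mcols(calls)$state,
    n_probes = mcols(calls)$n_probes,
    caller = mcols(calls)$caller,
    stringsAsFactors = FALSE
  )
}

#' Dual-caller consensus CNV calls
#'
#' A call is retained only when both callers detect it: calls from the two
#' input sets with identical sample, chromosome and state are paired when
#' their reciprocal overlap (overlap / own length, both directions) reaches
#' \code{minRecipOverlap}. Pairing is greedy by descending overlap with ties
#' broken by leftmost start, and each input call is used at most once. The
#' consensus interval is the intersection of the pair (conservative;
#' \code{mode = "union"} available) and its probe count the minimum of the
#' two callers' counts.
#'
#' @param callsA,callsB [CNVCalls-class] objects from the two callers over
#'   the same samples.
#' @param minRecipOverlap reciprocal-overlap threshold in (0, 1]; default 0.5.
#' @param mode consensus interval: `"intersection"` (default) or `"union"`.
#' @return a [CNVCalls-class] of consensus calls, caller label
#'   \code{"<A>+<B>"}; \code{metadata()} records counts of unmatched input
#'   calls per caller.
#' @examples
#' a <- CNVCalls("S1", "chr1", 100000, 200000, "DEL", 30, "A")
#' b <- CNVCalls("S1", "chr1", 150000, 250000, "DEL", 28, "B")
#' intersectCallers(a, b)  # consensus [150000, 200000]
#' @export
intersectCallers <- function(callsA, callsB, minRecipOverlap = 0.5,
                             mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  stopifnot(minRecipOverlap > 0, minRecipOverlap <= 1)
  a <- .callDf(callsA)
  b <- .callDf(callsB)
  ## candidate pairs: same sample/chrom/state with any overlap
  pairs <- NULL
  if (nrow(a) && nrow(b)) {
    key_a <- paste(a$sample, a$chrom, a$state, sep = "\r")
    key_b <- paste(b$sample, b$chrom, b$state, sep = "\r")
    for (k in intersect(unique(key_a), unique(key_b))) {
      ia <- which(key_a == k)
      ib <- which(key_b == k)
      grid <- expand.grid(i = ia, j = ib)
      ov <- pmin(a$end[grid$i], b$end[grid$j]) -
        pmax(a$start[grid$i], b$start[grid$j]) + 1
      keep <- ov > 0 &
        ov / (a$end[grid$i] - a$start[grid$i] + 1) >= minRecipOverlap &
        ov / (b$end[grid$j] - b$start[grid$j] + 1) >= minRecipOverlap
      if (any(keep))
        pairs <- rbind(pairs, cbind(grid[keep, , drop = FALSE],
                                    ov = ov[keep]))
    }
  }
  rows <- list()
  if (!is.null(pairs)) {
    ord <- order(-pairs$ov, pmin(a$start[pairs$i], b$start[pairs$j]),
                 a$start[pairs$i], b$start[pairs$j])
    pairs <- pairs[ord, , drop = FALSE]
    used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$i[r]; j <- pairs$j[r]
      if (used_a[i] || used_b[j]) next
      used_a[i] <- TRUE; used_b[j] <- TRUE
      if (mode == "intersection") {
        s <- max(a$start[i], b$start[j]); e <- min(a$end[i], b$end[j])
      } else {
        s <- min(a$start[i], b$start[j]); e <- max(a$end[i], b$end[j])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample = a$sample[i], chrom = a$chrom[i], start = s, end = e,
        state = a$state[i], n_probes = min(a$n_probes[i], b$n_probes[j]),
        stringsAsFactors = FALSE)
    }
    n_used_a <- sum(used_a); n_used_b <- sum(used_b)
  } else {
    n_used_a <- 0L; n_used_b <- 0L
  }
  lab <- paste(unique(c(a$caller, "A"))[1], unique(c(b$caller, "B"))[1],
               sep = "+")
  out <- if (length(rows)) {
    df <- do.call(rbind, rows)
    df <- df[order(df$chrom, df$start, df$end, df$sample), , drop = FALSE]
    CNVCalls(df$sample, df$chrom, df$start, df$end, df$state, df$n_probes,
             caller = lab)
  } else CNVCalls()
  metadata(out)$unmatched <- c(caller_a = nrow(a) - n_used_a,
                               caller_b = nrow(b) - n_used_b)
  out
}

#' Retention filters for CNV calls
#'
#' Keeps calls spanning at least \code{minProbes} array SNPs, at least
#' \code{minSizeBp} in size, and (by default) on autosomes only. Rejection
#' counts per rule are recorded in \code{metadata()} of the result.
#'
#' @param calls a [CNVCalls-class].
#' @param minProbes minimum probes spanned (default 10).
#' @param minSizeBp minimum size in bp, end - start + 1 (default 10 kb).
#' @param autosomesOnly drop calls on non-autosomal chromosomes.
#' @return the retained [CNVCalls-class] subset.
#' @export
filterCalls <- function(calls, minProbes = 10, minSizeBp = 10000,
                        autosomesOnly = TRUE) {
  size <- GenomicRanges::width(calls)
  probe_ok <- mcols(calls)$n_probes >= minProbes
  size_ok <- size >= minSizeBp
  auto_ok <- if (autosomesOnly)
    .isAutosome(GenomicRanges::seqnames(calls))
  else rep(TRUE, length(calls))
  keep <- probe_ok & size_ok & auto_ok
  out <- calls[keep]
  metadata(out)$rejected <- c(probes = sum(!probe_ok),
                              size = sum(!size_ok),
                              autosome = sum(!auto_ok))
  out
}

#' Cohort-level CNV descriptives
#'
#' Counts, deletion/duplication fractions, mean size and events per person.
#' Either pass a [CNVCalls-class] object, or the deletion/duplication event
#' counts directly (as when summarising published totals).
#'
#' @param calls a [CNVCalls-class], or NULL when giving counts.
#' @param nIndividuals cohort size (> 0).
#' @param nDel,nDup event counts, used when \code{calls} is NULL.
#' @param meanSizeKb optional mean event size (kb) when \code{calls} is NULL.
#' @return data.frame with one row: \code{n_individuals}, \code{n_events},
#'   \code{n_del}, \code{n_dup}, \code{frac_del}, \code{frac_dup},
#'   \code{pct_del}, \code{pct_dup} (nearest integer),
#'   \code{mean_size_kb}, \code{events_per_person} (full precision) and
#'   \code{events_per_person_report} (one decimal), plus an \code{empty}
#'   flag for event-free cohorts.
#' @examples
#' cohortSummary(nIndividuals = 387, nDel = 939, nDup = 445)
#' @export
cohortSummary <- function(calls = NULL, nIndividuals, nDel = NULL,
                          nDup = NULL, meanSizeKb = NA_real_) {
  if (nIndividuals <= 0) stop("nIndividuals must be positive")
  if (!is.null(calls)) {
    nDel <- sum(mcols(calls)$state == "DEL")
    nDup <- sum(mcols(calls)$state == "DUP")
    meanSizeKb <- if (length(calls))
      mean(GenomicRanges::width(calls)) / 1000 else NA_real_
  }
  n_events <- nDel + nDup
  empty <- n_events == 0
  frac_del <- if (empty) 0 else nDel / n_events
  frac_dup <- if (empty) 0 else nDup / n_events
  epp <- n_events / nIndividuals
  data.frame(
    n_individuals = nIndividuals, n_events = n_events,
    n_del = nDel, n_dup = nDup,
    frac_del = frac_del, frac_dup = frac_dup,
    pct_del = round(100 * frac_del), pct_dup = round(100 * frac_dup),
    mean_size_kb = meanSizeKb,
    events_per_person = epp,
    events_per_person_report = round(epp, 1),
    empty = empty
  )
}
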