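.segmentLengths <- function(segments, dropCensored = TRUE) {
  if (is.data.frame(segments)) {
    cens <- segments$censored_left | segments$censored_right
    l <- segments$genetic_length_morgans
  } else {
    cens <- rep(FALSE, length(segments))
    l <- as.numeric(segments)
  }
  if (dropCensored) {
    list(l = l[!cens], n_censored = sum(cens))
  } else {
    list(l = l, n_censored = 0L)
  }
}

#' Gamma-method coalescence age from shared flank lengths
#'
#' Under the independence model, each carrier haplotype's shared flank
#' (upstream + downstream genetic length l_i, Morgans) is the sum of two
#' exponential per-side lengths with rate tau, the age in generations, so
#' tau-hat = 2 / l_ave. \code{per_haplotype} weighting averages l_i over
#' haplotypes; \code{per_breakpoint_group} groups haplotypes by identical
#' (left, right) termini and weights each group's length by its haplotype
#' count -- algebraically the same mean, exposed separately because both
#' readings of "weighted by haplotypes sharing a breakpoint" occur in
#' practice. Censored segments (sharing beyond the examined window) are
#' excluded by default; set \code{dropCensored = FALSE} to treat their
#' observed lengths as complete, which bounds the age from above.
#'
#' @param segments data.frame from [sharedSegments()] (columns
#'   \code{genetic_length_morgans}, \code{censored_left},
#'   \code{censored_right}, optionally termini for grouping), or a bare
#'   numeric vector of lengths in Morgans.
#' @param weightingMode `"per_haplotype"` or `"per_breakpoint_group"`.
#' @param alpha confidence level is \code{1 - alpha} (default 0.05).
#' @param dropCensored exclude censored segments (default TRUE).
#' @return an [AgeEstimate-class].
#' @examples
#' estimateTau(c(0.01, 0.01, 0.01, 0.04))  # l_ave 0.0175, tau ~ 114.3
#' @export
estimateTau <- function(segments,
                        weightingMode = c("per_haplotype",
                                          "per_breakpoint_group"),
                        alpha = 0.05, dropCensored = TRUE) {
  weightingMode <- match.arg(weightingMode)
  sl <- .segmentLengths(segments, dropCensored)
  l <- sl$l
  if (!length(l) || all(l <= 0))
    stop("no uncensored segments with positive genetic length")
  if (weightingMode == "per_breakpoint_group" && is.data.frame(segments)) {
    obs <- segments[!(segments$censored_left | segments$censored_right) |
                      !dropCensored, , drop = FALSE]
    key <- paste(obs$left_terminus_bp, obs$right_terminus_bp)
    w <- table(key)
    lj <- tapply(obs$genetic_length_morgans, key, mean)
    weights <- as.numeric(w[names(lj)])
    names(weights) <- names(lj)
    l_ave <- sum(weights * lj) / sum(weights)
  } else {
    weights <- stats::setNames(rep(1, length(l)), seq_along(l))
    l_ave <- mean(l)
  }
  ci <- tauConfidence(l, alpha)
  new("AgeEstimate", tau = 2 / l_ave, lAve = l_ave, n = length(l),
      ciLow = ci[["ci_low"]], ciHigh = ci[["ci_high"]], alpha = alpha,
      weightingMode = weightingMode, weights = weights,
      nCensored = as.integer(sl$n_censored))
}

#' Chi-square pivot confidence interval for the Gamma-method age
#'
#' Each l_i is the sum of two per-side lengths, exponential with rate tau,
#' so 2 tau sum(l_i) follows a chi-square law with 4n degrees of freedom.
#' Inverting the pivot gives an exact interval under the independence
#' model: \code{[qchisq(alpha/2, 4n), qchisq(1 - alpha/2, 4n)] / (2 sum l)}.
#'
#' @param segments as in [estimateTau()]; censored segments are excluded.
#' @param alpha interval level is \code{1 - alpha}.
#' @return named numeric: \code{ci_low}, \code{ci_high} (generations).
#' @export
tauConfidence <- function(segments, alpha = 0.05) {
  l <- .segmentLengths(segments)$l
  n <- length(l)
  if (n == 0L) stop("no uncensored segments")
  s <- sum(l)
  c(ci_low = stats::qchisq(alpha / 2, df = 4 * n) / (2 * s),
    ci_high = stats::qchisq(1 - alpha / 2, df = 4 * n) / (2 * s))
}

#' Bootstrap confidence interval for the Gamma-method age
#'
#' Percentile bootstrap over haplotypes, as a model-free alternative to the
#' chi-square pivot of [tauConfidence()].
#'
#' @inheritParams tauConfidence
#' @param reps bootstrap replicates.
#' @param seed RNG seed.
#' @return named numeric: \code{ci_low}, \code{ci_high}.
#' @export
tauConfidenceBoot <- function(segments, alpha = 0.05, reps = 2000,
                              seed = 1) {
  l <- .segmentLengths(segments)$l
  if (!length(l)) stop("no uncensored segments")
  set.seed(seed)
  taus <- vapply(seq_len(reps), function(i)
    2 / mean(sample(l, replace = TRUE)), numeric(1))
  q <- stats::quantile(taus, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  c(ci_low = q[1], ci_high = q[2])
}

#' Compare two sets of ages (or any values) by Mann-Whitney rank test
#'
#' Wilcoxon rank-sum with exact enumeration for small untied groups (both
#' sizes at most 8) and the normal approximation with tie correction
#' otherwise.
#'
#' @param a,b numeric vectors (e.g. tau estimates of two classes of
#'   recurrent CNVs), both non-empty.
#' @return list with \code{U} (statistic for \code{a}), \code{p_two_sided}.
#' @export
compareAgeGroups <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ties <- any(duplicated(c(a, b)))
  exact <- length(a) <= 8 && length(b) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE))
  list(U = unname(wt$statistic), p_two_sided = wt$p.value)
}
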