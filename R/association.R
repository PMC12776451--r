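#' Cross-tabulate carrier status against a binary phenotype
#'
#' Builds the 2x2 table (a = carrier cases, b = carrier non-cases,
#' c = non-carrier cases, d = non-carrier non-cases). Samples missing
#' either value are excluded with a logged count.
#'
#' @param carrierStatus named 0/1 vector (names = sample ids).
#' @param phenotype named 0/1 vector over the same sample universe.
#' @return named integer vector \code{c(a, b, c, d)}; attribute
#'   \code{n_excluded} counts samples missing a value.
#' @export
twoByTwo <- function(carrierStatus, phenotype) {
  common <- intersect(names(carrierStatus), names(phenotype))
  if (!length(common)) stop("carrier and phenotype sample sets are disjoint")
  cs <- carrierStatus[common]
  ph <- phenotype[common]
  ok <- !is.na(cs) & !is.na(ph)
  n_excl <- (length(unique(c(names(carrierStatus), names(phenotype)))) -
               length(common)) + sum(!ok)
  cs <- cs[ok]; ph <- ph[ok]
  tab <- c(a = sum(cs == 1 & ph == 1), b = sum(cs == 1 & ph == 0),
           c = sum(cs == 0 & ph == 1), d = sum(cs == 0 & ph == 0))
  attr(tab, "n_excluded") <- n_excl
  tab
}

#' Odds ratio with Woolf (log-normal) confidence interval
#'
#' OR = ad/bc with interval
#' \code{exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))}. Any zero cell
#' triggers the Haldane-Anscombe correction (+0.5 to every cell), flagged
#' in the result; a zero margin leaves the OR undefined.
#'
#' @param tab 2x2 counts \code{c(a, b, c, d)} as from [twoByTwo()].
#' @param alpha interval level is \code{1 - alpha}.
#' @return list: \code{or}, \code{ci_low}, \code{ci_high},
#'   \code{corrected} (Haldane-Anscombe applied), \code{undefined}.
#' @examples
#' oddsRatioCI(c(22, 5, 209, 151))  # OR 3.18, CI 1.18-8.59
#' @export
oddsRatioCI <- function(tab, alpha = 0.05) {
  stopifnot(length(tab) == 4, all(tab >= 0))
  a <- tab[[1]]; b <- tab[[2]]; cc <- tab[[3]]; d <- tab[[4]]
  undefined <- (a + b == 0) || (cc + d == 0) || (a + cc == 0) || (b + d == 0)
  corrected <- FALSE
  if (!undefined && any(c(a, b, cc, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
    corrected <- TRUE
  }
  if (undefined)
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                corrected = FALSE, undefined = TRUE))
  or <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- stats::qnorm(1 - alpha / 2)
  list(or = or, ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       corrected = corrected, undefined = FALSE)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction: \code{chi2 = N (ad - bc)^2 / (r1 r2 c1
#' c2)}, two-sided p from the chi-square law with 1 df. The one-sided p is
#' half the two-sided value when the observed odds ratio exceeds 1 and
#' \code{1 - p/2} otherwise. A warning is raised when any expected cell is
#' at most 5; a zero margin leaves the statistic undefined.
#'
#' @param tab 2x2 counts \code{c(a, b, c, d)}.
#' @return list: \code{chi2}, \code{p_two_sided}, \code{p_one_sided},
#'   \code{undefined}.
#' @export
chiSquareP <- function(tab) {
  stopifnot(length(tab) == 4, all(tab >= 0))
  a <- tab[[1]]; b <- tab[[2]]; cc <- tab[[3]]; d <- tab[[4]]
  N <- a + b + cc + d
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(list(chi2 = NA_real_, p_two_sided = NA_real_,
                p_one_sided = NA_real_, undefined = TRUE))
  expected <- outer(c(r1, r2), c(c1, c2)) / N
  if (any(expected <= 5))
    warning("expected cell count <= 5; chi-square approximation is weak")
  chi2 <- N * (a * d - b * cc)^2 / (r1 * r2 * c1 * c2)
  p2 <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  p1 <- if (a * d > b * cc) p2 / 2 else 1 - p2 / 2
  list(chi2 = chi2, p_two_sided = p2, p_one_sided = p1, undefined = FALSE)
}

#' Multiple-testing adjustment
#'
#' Bonferroni (\code{min(1, m p)}) or Benjamini-Hochberg step-up with
#' monotonicity enforcement, via \code{stats::p.adjust}.
#'
#' @param p p-values in [0, 1].
#' @param method `"bonferroni"` or `"bh"`.
#' @param m number of tests (defaults to \code{length(p)}).
#' @return adjusted p-values.
#' @export
adjustP <- function(p, method = c("bonferroni", "bh"), m = length(p)) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni",
                  n = m)
}

#' Association of one recurrent CNV with a binary phenotype
#'
#' Convenience wrapper combining [twoByTwo()], [oddsRatioCI()],
#' [chiSquareP()] and Bonferroni/BH adjustment for \code{m} tests.
#'
#' @inheritParams twoByTwo
#' @param m number of recurrent CNVs tested (for the adjustments).
#' @param alpha interval level is \code{1 - alpha}.
#' @return one-row data.frame with the table cells, OR and CI, chi2, raw
#'   one-/two-sided p, \code{p_bonferroni} and \code{q_bh}.
#' @export
associationTest <- function(carrierStatus, phenotype, m = 1, alpha = 0.05) {
  tab <- twoByTwo(carrierStatus, phenotype)
  or <- oddsRatioCI(tab, alpha)
  ch <- suppressWarnings(chiSquareP(tab))
  data.frame(
    a = tab[["a"]], b = tab[["b"]], c = tab[["c"]], d = tab[["d"]],
    or = or$or, ci_low = or$ci_low, ci_high = or$ci_high,
    chi2 = ch$chi2, p_two_sided = ch$p_two_sided,
    p_one_sided = ch$p_one_sided,
    p_bonferroni = min(1, m * ch$p_two_sided),
    q_bh = NA_real_  # meaningful only across a family; see adjustP()
  )
}

#' Per-sample CNV burden: event count and gene load
#'
#' Gene load counts the distinct genes overlapped by at least 1 bp by any
#' of the sample's CNVs (partial overlap counts; a gene hit by two CNVs
#' counts once).
#'
#' @param calls a [CNVCalls-class] (typically consensus calls).
#' @param genes \code{GRanges} of gene intervals with a \code{name} column
#'   (e.g. from [readGenesBed()]).
#' @param samples optional sample universe; samples without calls get zero
#'   burden.
#' @return data.frame: \code{sample}, \code{n_cnvs}, \code{gene_load}.
#' @export
burdenMetrics <- function(calls, genes, samples = NULL) {
  ids <- mcols(calls)$sample_id
  if (is.null(samples)) samples <- sort(unique(ids))
  hits <- GenomicRanges::findOverlaps(calls, genes, minoverlap = 1L)
  gene_of_hit <- genes$name[S4Vectors::subjectHits(hits)]
  sample_of_hit <- ids[S4Vectors::queryHits(hits)]
  load <- vapply(samples, function(s)
    length(unique(gene_of_hit[sample_of_hit == s])), integer(1))
  data.frame(sample = samples,
             n_cnvs = as.integer(table(factor(ids, levels = samples))),
             gene_load = load, row.names = NULL)
}

#' Mann-Whitney test of CNV burden between phenotype classes
#'
#' @param burdens named numeric vector of per-sample burden values.
#' @param phenotype named 0/1 vector; both classes must be non-empty.
#' @return list with \code{U}, \code{p_two_sided}, and per-class means.
#' @export
burdenTest <- function(burdens, phenotype) {
  common <- intersect(names(burdens), names(phenotype))
  x <- burdens[common][phenotype[common] == 1]
  y <- burdens[common][phenotype[common] == 0]
  if (!length(x) || !length(y)) stop("both phenotype classes must be non-empty")
  res <- compareAgeGroups(x, y)
  c(res, list(mean_cases = mean(x), mean_controls = mean(y)))
}

#' Solve carrier / non-carrier case probabilities
#'
#' Given the population prevalence K, carrier frequency f and carrier odds
#' ratio, finds p0 (non-carrier case probability) such that
#' \code{f p1 + (1 - f) p0 = K} with \code{odds(p1) = OR odds(p0)}.
#'
#' @param prevalence target population prevalence K in (0, 1).
#' @param carrierFreq carrier frequency f in [0, 1).
#' @param oddsRatio carrier odds ratio (> 0).
#' @return named numeric: \code{p0}, \code{p1}.
#' @export
solveCaseProbs <- function(prevalence, carrierFreq, oddsRatio) {
  stopifnot(prevalence > 0, prevalence < 1, carrierFreq >= 0,
            carrierFreq < 1, oddsRatio > 0)
  p1_of <- function(p0) oddsRatio * p0 / (1 - p0 + oddsRatio * p0)
  f <- function(p0) carrierFreq * p1_of(p0) + (1 - carrierFreq) * p0 -
    prevalence
  lo <- 1e-12; hi <- 1 - 1e-12
  if (f(lo) > 0 || f(hi) < 0)
    stop("infeasible prevalence/frequency/odds-ratio combination")
  p0 <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  c(p0 = p0, p1 = p1_of(p0))
}

#' Power of the carrier chi-square test, by simulation
#'
#' Simulates carrier counts ~ Binomial(n, carrierFreq), assigns case status
#' with carrier/non-carrier probabilities solved so the population
#' prevalence matches the target under the given carrier odds ratio, and
#' counts the fraction of replicates whose Pearson chi-square p-value (two
#' sided, no continuity correction) falls below \code{alpha}.
#'
#' @param n cohort size.
#' @param prevalence population case prevalence.
#' @param carrierFreq carrier frequency.
#' @param oddsRatio carrier odds ratio.
#' @param alpha test level (default 0.05).
#' @param reps simulation replicates (>= 1000 recommended).
#' @param seed RNG seed.
#' @return list: \code{power}, \code{se} (binomial standard error),
#'   \code{reps}.
#' @export
powerBySimulation <- function(n, prevalence, carrierFreq, oddsRatio,
                              alpha = 0.05, reps = 1000, seed = 1) {
  pr <- solveCaseProbs(prevalence, carrierFreq, oddsRatio)
  set.seed(seed)
  ncar <- stats::rbinom(reps, n, carrierFreq)
  a <- stats::rbinom(reps, ncar, pr[["p1"]])
  cc <- stats::rbinom(reps, n - ncar, pr[["p0"]])
  b <- ncar - a
  d <- (n - ncar) - cc
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  chi2 <- ifelse(r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0, NA_real_,
                 n * (a * d - b * cc)^2 / (r1 * r2 * c1 * c2))
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  hit <- !is.na(p) & p < alpha
  power <- mean(hit)
  list(power = power, se = sqrt(power * (1 - power) / reps), reps = reps)
}
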