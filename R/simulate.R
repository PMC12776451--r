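#' Simulation configuration for a synthetic recurrent-CNV study
#'
#' The generator emulates the statistical structure the analysis assumes:
#' carriers of a focal CNV share an ancestral flanking haplotype whose
#' per-side genetic length is exponential with rate \code{tau} per Morgan;
#' within the shared segment each SNP is flipped independently with
#' probability \code{epsilon} (point mutation or genotyping error);
#' outside it, alleles come from population background frequencies. Two
#' noisy caller tables and binary phenotypes with a target carrier odds
#' ratio complete the study inputs.
#'
#' The SNP window defaults to a per-side genetic span of \code{6/tau}
#' Morgans: wide enough that the first recombination almost surely falls
#' inside the examined window (censoring probability exp(-6)), while the
#' inter-SNP spacing \code{span/nSnpsPerFlank} stays well below the mean
#' shared length \code{1/tau}.
#'
#' @param tau coalescence age in generations (> 0).
#' @param nCarriers carrier individuals (one CNV haplotype each).
#' @param nNoncarriers non-carrier individuals.
#' @param nSnpsPerFlank SNPs simulated on each side of the CNV.
#' @param chrom,regionStart,regionEnd the focal CNV region (defaults mirror
#'   a 96-kb deletion on 6p21.33).
#' @param rateCmMb uniform recombination rate, cM/Mb.
#' @param flankSpanMorgans per-side genetic span of the simulated window.
#' @param epsilon per-SNP mismatch rate on shared segments.
#' @param mafRange range of per-SNP minor-allele frequencies.
#' @param callerJitterBp boundary jitter (uniform on +/- this) per caller.
#' @param callerDropoutProb per-caller event drop probability.
#' @param baselinePrevalence population case prevalence.
#' @param carrierOddsRatio carrier odds ratio for the phenotype.
#' @param probeSpacingBp array probe spacing used for simulated probe
#'   counts.
#' @param seed mandatory RNG seed.
#' @return a validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(tau = 500, nCarriers = 50, nNoncarriers = 150,
                      nSnpsPerFlank = 60, chrom = "chr6",
                      regionStart = 31355318, regionEnd = 31451476,
                      rateCmMb = 1, flankSpanMorgans = 6 / tau,
                      epsilon = 0.002, mafRange = c(0.1, 0.5),
                      callerJitterBp = 0, callerDropoutProb = 0,
                      baselinePrevalence = 0.6, carrierOddsRatio = 1,
                      seed) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(tau = tau, nCarriers = nCarriers, nNoncarriers = nNoncarriers,
              nSnpsPerFlank = nSnpsPerFlank, chrom = chrom,
              regionStart = regionStart, regionEnd = regionEnd,
              rateCmMb = rateCmMb, flankSpanMorgans = flankSpanMorgans,
              epsilon = epsilon, mafRange = mafRange,
              callerJitterBp = callerJitterBp,
              callerDropoutProb = callerDropoutProb,
              baselinePrevalence = baselinePrevalence,
              carrierOddsRatio = carrierOddsRatio,
              probeSpacingBp = 5000, seed = as.integer(seed))
  probs <- c(cfg$epsilon, cfg$callerDropoutProb, cfg$baselinePrevalence,
             cfg$mafRange)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$tau <= 0) stop("tau must be positive")
  if (cfg$regionEnd < cfg$regionStart) stop("regionEnd < regionStart")
  class(cfg) <- c("SimConfig", "list")
  cfg
}

#' Simulate the genomic region around a focal CNV
#'
#' Draws SNP positions uniformly over the two flanks (span set by the
#' config), builds the genetic map, samples per-SNP background allele
#' frequencies and the ancestral haplotype carried by the CNV founder.
#'
#' @param config a [simConfig()] object.
#' @return list: \code{map} ([GeneticMap-class]), \code{positions},
#'   \code{freq1} (per-SNP frequency of allele 1), \code{ancestral} (0/1
#'   vector), \code{chrom}, \code{regionStart}, \code{regionEnd},
#'   \code{nLeft}, \code{nRight}.
#' @export
simulateRegion <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  map <- uniformGeneticMap(config$chrom, config$rateCmMb)
  span_bp <- config$flankSpanMorgans * 100 / config$rateCmMb * 1e6
  n <- config$nSnpsPerFlank
  left <- sort(unique(round(stats::runif(n, config$regionStart - span_bp,
                                         config$regionStart - 1))))
  right <- sort(unique(round(stats::runif(n, config$regionEnd + 1,
                                          config$regionEnd + span_bp))))
  while (length(left) < n)
    left <- sort(unique(c(left, round(stats::runif(n - length(left),
                                                   config$regionStart - span_bp,
                                                   config$regionStart - 1)))))
  while (length(right) < n)
    right <- sort(unique(c(right, round(stats::runif(n - length(right),
                                                     config$regionEnd + 1,
                                                     config$regionEnd + span_bp)))))
  pos <- c(left, right)
  maf <- stats::runif(length(pos), config$mafRange[1], config$mafRange[2])
  freq1 <- ifelse(stats::runif(length(pos)) < 0.5, maf, 1 - maf)
  ancestral <- stats::rbinom(length(pos), 1, freq1)
  list(map = map, positions = pos, freq1 = freq1, ancestral = ancestral,
       chrom = config$chrom, regionStart = config$regionStart,
       regionEnd = config$regionEnd, nLeft = length(left),
       nRight = length(right))
}

#' Simulate carrier and non-carrier haplotypes with known ground truth
#'
#' Each carrier contributes one CNV-bearing haplotype that copies the
#' ancestral alleles over a shared segment whose per-side genetic length is
#' exponential with rate \code{tau} (truncated at the simulated window,
#' setting the censored flag), with per-SNP flips at rate \code{epsilon};
#' alleles outside the segment, the carrier's second haplotype and all
#' non-carrier haplotypes are independent background draws.
#'
#' @param config a [simConfig()] object.
#' @param region output of [simulateRegion()].
#' @return list: \code{panel} ([HaplotypePanel-class]),
#'   \code{carrierHapIds}, \code{carrierSamples}, \code{truth} (data.frame
#'   per carrier haplotype: per-side genetic lengths in Morgans, censoring
#'   flags, and SNP-resolution termini in bp).
#' @export
simulateCarriers <- function(config, region) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed + 1L)
  pos <- region$positions
  cmpos <- cmAt(region$map, region$chrom, pos)
  cm_start <- cmAt(region$map, region$chrom, region$regionStart)
  cm_end <- cmAt(region$map, region$chrom, region$regionEnd)
  span <- config$flankSpanMorgans
  nc <- config$nCarriers
  nn <- config$nNoncarriers
  left_idx <- seq_len(region$nLeft)
  right_idx <- region$nLeft + seq_len(region$nRight)

  bg <- function() stats::rbinom(length(pos), 1, region$freq1)
  rows <- list()
  truth <- list()
  carrier_samples <- sprintf("C%03d", seq_len(nc))
  for (i in seq_len(nc)) {
    l_raw <- stats::rexp(2, rate = config$tau)  # left, right (Morgans)
    cens <- l_raw > span
    l <- pmin(l_raw, span)
    in_seg <- (cmpos >= cm_start - l[1] * 100) &
      (cmpos <= cm_end + l[2] * 100)
    hap <- bg()
    hap[in_seg] <- region$ancestral[in_seg]
    if (config$epsilon > 0) {
      flip <- in_seg & stats::runif(length(pos)) < config$epsilon
      hap[flip] <- 1L - hap[flip]
    }
    li <- intersect(which(in_seg), left_idx)
    ri <- intersect(which(in_seg), right_idx)
    truth[[i]] <- data.frame(
      hap_id = paste0(carrier_samples[i], "_h1"),
      l_left_morgans = l[1], l_right_morgans = l[2],
      censored_left = cens[1], censored_right = cens[2],
      left_terminus_bp = if (length(li)) pos[min(li)] else region$regionStart,
      right_terminus_bp = if (length(ri)) pos[max(ri)] else region$regionEnd,
      stringsAsFactors = FALSE)
    rows[[2 * i - 1]] <- hap
    rows[[2 * i]] <- bg()
  }
  noncarrier_samples <- sprintf("N%03d", seq_len(nn))
  for (i in seq_len(nn)) {
    rows[[2 * nc + 2 * i - 1]] <- bg()
    rows[[2 * nc + 2 * i]] <- bg()
  }
  al <- do.call(rbind, rows)
  samples <- c(carrier_samples, noncarrier_samples)
  rownames(al) <- as.vector(rbind(paste0(samples, "_h1"),
                                  paste0(samples, "_h2")))
  list(panel = HaplotypePanel(al, pos, region$chrom),
       carrierHapIds = paste0(carrier_samples, "_h1"),
       carrierSamples = carrier_samples,
       truth = do.call(rbind, truth))
}

#' True CNV calls implied by a set of carriers
#'
#' @param config a [simConfig()] object.
#' @param carrierSamples carrier sample ids.
#' @return a [CNVCalls-class] with one DEL call per carrier at the focal
#'   region (caller label \code{"truth"}).
#' @export
trueCnvCalls <- function(config, carrierSamples) {
  n <- length(carrierSamples)
  size <- config$regionEnd - config$regionStart + 1
  CNVCalls(carrierSamples, config$chrom,
           rep(config$regionStart, n), rep(config$regionEnd, n),
           "DEL", max(1L, round(size / config$probeSpacingBp)), "truth")
}

#' Simulate two noisy caller tables from true CNV calls
#'
#' Each caller reports each true event with probability
#' \code{1 - callerDropoutProb} (independently per caller), jittering both
#' boundaries uniformly on \code{+/- callerJitterBp}; probe counts follow
#' the simulated probe spacing.
#'
#' @param trueCnvs a [CNVCalls-class] of true events.
#' @param config a [simConfig()] object.
#' @return list of two [CNVCalls-class] objects, \code{caller_a} and
#'   \code{caller_b}.
#' @export
simulateCallerTables <- function(trueCnvs, config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed + 2L)
  jit <- config$callerJitterBp
  one <- function(label) {
    keep <- stats::runif(length(trueCnvs)) >= config$callerDropoutProb
    x <- trueCnvs[keep]
    if (!length(x))
      return(CNVCalls())
    s <- GenomicRanges::start(x) +
      if (jit > 0) sample(-jit:jit, length(x), TRUE) else 0L
    e <- GenomicRanges::end(x) +
      if (jit > 0) sample(-jit:jit, length(x), TRUE) else 0L
    e <- pmax(e, s)
    np <- pmax(1L, round((e - s + 1) / config$probeSpacingBp))
    CNVCalls(mcols(x)$sample_id,
             as.character(GenomicRanges::seqnames(x)), s, e,
             mcols(x)$state, np, label)
  }
  list(caller_a = one("caller_a"), caller_b = one("caller_b"))
}

#' Simulate binary phenotypes with a target carrier odds ratio
#'
#' The non-carrier case probability is solved so that the population
#' prevalence matches \code{baselinePrevalence} given the observed carrier
#' frequency and the odds ratio ([solveCaseProbs()]); case status is then
#' drawn per sample. A secondary diagnosis label is added independently so
#' that "any psychiatric diagnosis" is a strict superset of AUD.
#'
#' @param carrierStatus named 0/1 vector over samples.
#' @param baselinePrevalence target population prevalence of AUD.
#' @param carrierOddsRatio carrier odds ratio.
#' @param seed RNG seed.
#' @param otherDiagProb probability of an independent non-AUD diagnosis.
#' @return data.frame as from [readPhenotypes()].
#' @export
simulatePhenotypes <- function(carrierStatus, baselinePrevalence,
                               carrierOddsRatio, seed,
                               otherDiagProb = 0.15) {
  f <- mean(carrierStatus)
  pr <- solveCaseProbs(baselinePrevalence, f, carrierOddsRatio)
  set.seed(seed)
  p <- ifelse(carrierStatus == 1, pr[["p1"]], pr[["p0"]])
  aud <- stats::rbinom(length(p), 1, p)
  other <- stats::rbinom(length(p), 1, otherDiagProb)
  labels <- c("MDD", "PTSD", "Phobia", "GAD")
  other_lab <- sample(labels, length(p), replace = TRUE)
  sets <- lapply(seq_along(p), function(i) {
    s <- character()
    if (aud[i] == 1) s <- "AUD"
    if (other[i] == 1) s <- c(s, other_lab[i])
    s
  })
  data.frame(sample = names(carrierStatus), aud = aud,
             diagnoses = I(sets), any_psych = as.integer(lengths(sets) > 0),
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic study
#'
#' Region, haplotypes with ground truth, two caller tables and phenotypes,
#' all reproducible from the config seed.
#'
#' @param config a [simConfig()] object.
#' @return list: \code{region}, \code{map}, \code{panel},
#'   \code{carrierHapIds}, \code{carrierSamples}, \code{truth},
#'   \code{callers} (list of two [CNVCalls-class]), \code{phenotypes},
#'   \code{config}.
#' @export
simulateStudy <- function(config) {
  region <- simulateRegion(config)
  carriers <- simulateCarriers(config, region)
  truth_calls <- trueCnvCalls(config, carriers$carrierSamples)
  callers <- simulateCallerTables(truth_calls, config)
  samples <- unique(sub("_h[12]$", "", hapIds(carriers$panel)))
  status <- stats::setNames(as.integer(samples %in% carriers$carrierSamples),
                            samples)
  pheno <- simulatePhenotypes(status, config$baselinePrevalence,
                              config$carrierOddsRatio,
                              seed = config$seed + 3L)
  list(region = region, map = region$map, panel = carriers$panel,
       carrierHapIds = carriers$carrierHapIds,
       carrierSamples = carriers$carrierSamples, truth = carriers$truth,
       trueCalls = truth_calls, callers = callers, phenotypes = pheno,
       config = config)
}
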