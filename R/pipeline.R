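#' Default pipeline configuration
#'
#' Returns the full parameter set with the standard retention and analysis
#' defaults: 10-probe / 10-kb / autosome call filters, reciprocal overlap
#' 0.5 for dual-caller consensus, exact (0 bp) breakpoint tolerance within
#' a population and 0.8 reciprocal overlap across populations, 60 flanking
#' SNPs with 5-SNP rescue, per-haplotype weighting, alpha 0.05, carrier
#' thresholds of 25 carriers and frequency 0.022. File paths must be filled
#' in before [runPipeline()].
#'
#' @return named list of config entries.
#' @export
defaultPipelineConfig <- function() {
  list(
    caller_a = NULL, caller_b = NULL, caller_a_label = "caller_a",
    caller_b_label = "caller_b", map = NULL, map_chrom = NULL,
    haplotypes = NULL, phenotypes = NULL, genes_bed = NULL,
    population = "POP1", n_individuals = NULL,
    min_reciprocal_overlap = 0.5, min_probes = 10, min_size_bp = 10000,
    autosomes_only = TRUE, bp_tolerance = 0, cross_pop_overlap = 0.8,
    n_flank_snps = 60, rescue_k = 5, weighting_mode = "per_haplotype",
    alpha = 0.05, mt_method = "bonferroni", min_carriers = 25,
    min_frequency = 0.022, years_per_generation = NULL, seed = 1
  )
}

#' Read / write a pipeline config as YAML
#'
#' @param path YAML file of config keys; unknown keys are rejected.
#' @return the merged config list (defaults overridden by the file).
#' @export
readPipelineConfig <- function(path) {
  cfg <- defaultPipelineConfig()
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  utils::modifyList(cfg, user)
}

#' @rdname readPipelineConfig
#' @param config config list.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

#' Run the full recurrent-CNV analysis pipeline
#'
#' Executes consensus -> retention filters -> recurrent-group clustering ->
#' testable-group selection -> flanking-haplotype sharing -> Gamma-method
#' dating -> carrier association (AUD and any psychiatric diagnosis) and,
#' when gene intervals are supplied, per-sample burden with Mann-Whitney
#' tests. All stage parameters come from the config; every output table and
#' a per-stage count log are written under \code{outDir} together with the
#' resolved config.
#'
#' @param config list from [defaultPipelineConfig()] /
#'   [readPipelineConfig()] with the input paths filled in.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results
#'   (\code{consensus}, \code{filtered}, \code{groups}, \code{testable},
#'   \code{ages}, \code{assoc}, \code{burden}, \code{log}).
#' @export
runPipeline <- function(config, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  note("founderCNV %s; seed %s", as.character(utils::packageVersion("founderCNV")),
       config$seed)

  calls_a <- stage("read", readCnvCalls(config$caller_a,
                                        config$caller_a_label))
  calls_b <- stage("read", readCnvCalls(config$caller_b,
                                        config$caller_b_label))
  note("input calls: %d (%s), %d (%s)", length(calls_a),
       config$caller_a_label, length(calls_b), config$caller_b_label)

  cons <- stage("consensus",
                intersectCallers(calls_a, calls_b,
                                 config$min_reciprocal_overlap))
  un <- metadata(cons)$unmatched
  note("consensus: %d calls; unmatched %d/%d", length(cons), un[1], un[2])
  writeCnvCalls(cons, file.path(outDir, "consensus.tsv"))

  filt <- stage("filter",
                filterCalls(cons, config$min_probes, config$min_size_bp,
                            config$autosomes_only))
  rej <- metadata(filt)$rejected
  note("filtered: %d retained; rejected probes=%d size=%d autosome=%d",
       length(filt), rej["probes"], rej["size"], rej["autosome"])
  writeCnvCalls(filt, file.path(outDir, "filtered.tsv"))

  n_ind <- config$n_individuals
  if (is.null(n_ind))
    n_ind <- length(unique(c(mcols(calls_a)$sample_id,
                             mcols(calls_b)$sample_id)))
  groups <- stage("detect-rcnv",
                  clusterRecurrent(filt, config$bp_tolerance, n_ind,
                                   config$population))
  note("groups: %d (%d recurrent)", nrow(groups), sum(groups$recurrent))
  gdf <- groups[names(groups) != "samples"]
  utils::write.table(gdf, file.path(outDir, "groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  testable <- stage("select", selectTestable(groups, config$min_carriers,
                                             config$min_frequency))
  note("testable groups: %d (>=%d carriers, freq > %s)", nrow(testable),
       config$min_carriers, config$min_frequency)

  ## dating: groups on the haplotype panel's chromosome
  ages <- NULL
  if (!is.null(config$haplotypes) && !is.null(config$map) &&
      nrow(testable)) {
    panel <- stage("share", readHaplotypes(config$haplotypes))
    map <- stage("share", readGeneticMap(config$map, config$map_chrom))
    for (g in seq_len(nrow(testable))) {
      if (testable$chrom[g] != panel@chrom) next
      res <- tryCatch({
        win <- buildFlankWindow(panel, testable$start[g], testable$end[g],
                                config$n_flank_snps)
        carriers <- unlist(testable$samples[g])
        hids <- intersect(paste0(rep(carriers, each = 2), c("_h1", "_h2")),
                          hapIds(panel))
        segs <- sharedSegments(win, hids, map, config$rescue_k)
        est <- estimateTau(segs, config$weighting_mode, config$alpha)
        data.frame(chrom = testable$chrom[g], start = testable$start[g],
                   end = testable$end[g], state = testable$state[g],
                   n_haplotypes = est@n, n_censored = est@nCensored,
                   l_ave_morgans = est@lAve, tau = est@tau,
                   ci_low = est@ciLow, ci_high = est@ciHigh,
                   years = if (is.null(config$years_per_generation))
                     NA_real_ else est@tau * config$years_per_generation)
      }, error = function(e) {
        note("dating skipped for group %d: %s", g, conditionMessage(e))
        NULL
      })
      ages <- rbind(ages, res)
    }
    if (!is.null(ages))
      utils::write.table(ages, file.path(outDir, "ages.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    note("dated groups: %d", if (is.null(ages)) 0L else nrow(ages))
  }

  ## association
  assoc <- NULL
  if (!is.null(config$phenotypes) && nrow(testable)) {
    pheno <- stage("assoc", readPhenotypes(config$phenotypes))
    aud <- stats::setNames(pheno$aud, pheno$sample)
    psych <- stats::setNames(pheno$any_psych, pheno$sample)
    m <- nrow(testable)
    rows <- lapply(seq_len(m), function(g) {
      carriers <- unlist(testable$samples[g])
      status <- stats::setNames(as.integer(pheno$sample %in% carriers),
                                pheno$sample)
      r_aud <- associationTest(status, aud, m, config$alpha)
      r_psy <- associationTest(status, psych, m, config$alpha)
      data.frame(chrom = testable$chrom[g], start = testable$start[g],
                 end = testable$end[g], state = testable$state[g],
                 n_carriers = testable$n_carriers[g],
                 or_aud = r_aud$or, ci_low_aud = r_aud$ci_low,
                 ci_high_aud = r_aud$ci_high, p_aud = r_aud$p_two_sided,
                 or_psych = r_psy$or, ci_low_psych = r_psy$ci_low,
                 ci_high_psych = r_psy$ci_high, p_psych = r_psy$p_two_sided)
    })
    assoc <- do.call(rbind, rows)
    adj <- if (config$mt_method == "bh") "bh" else "bonferroni"
    assoc$p_aud_adj <- adjustP(assoc$p_aud, adj, m)
    assoc$p_psych_adj <- adjustP(assoc$p_psych, adj, m)
    utils::write.table(assoc, file.path(outDir, "assoc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("association: %d groups x 2 phenotypes, %s-adjusted", m, adj)
  }

  ## burden
  burden <- NULL
  if (!is.null(config$genes_bed) && !is.null(config$phenotypes)) {
    genes <- stage("burden", readGenesBed(config$genes_bed))
    pheno <- readPhenotypes(config$phenotypes)
    burden <- burdenMetrics(filt, genes, pheno$sample)
    aud <- stats::setNames(pheno$aud, pheno$sample)
    bt_n <- burdenTest(stats::setNames(burden$n_cnvs, burden$sample), aud)
    bt_g <- burdenTest(stats::setNames(burden$gene_load, burden$sample), aud)
    utils::write.table(burden, file.path(outDir, "burden.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("burden: n_cnvs p=%.4g, gene_load p=%.4g (AUD, Mann-Whitney)",
         bt_n$p_two_sided, bt_g$p_two_sided)
  }

  writePipelineConfig(config, file.path(outDir, "config_resolved.yaml"))
  writeLines(log, file.path(outDir, "run_log.txt"))
  invisible(list(consensus = cons, filtered = filt, groups = groups,
                 testable = testable, ages = ages, assoc = assoc,
                 burden = burden, log = log))
}
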