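#' Read CNV calls from a tab-separated file
#'
#' Expects a header line \code{sample chrom start end state n_probes}
#' (an optional \code{copy_number} column is honoured). Coordinates are
#' 1-based inclusive. Rows violating the call invariants (end < start,
#' state outside DEL/DUP, n_probes < 1) are rejected with their row numbers.
#'
#' @param path path to the TSV file.
#' @param caller caller label stored on every call.
#' @return a [CNVCalls-class] object.
#' @export
readCnvCalls <- function(path, caller) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "chrom", "start", "end", "state", "n_probes")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("CNV call file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df) == 0L)
    return(CNVCalls())
  bad <- which(df$end < df$start | !(df$state %in% c("DEL", "DUP")) |
                 is.na(df$n_probes) | df$n_probes < 1)
  if (length(bad))
    stop("invalid CNV call record(s) at row(s): ", paste(bad, collapse = ", "))
  cn <- if ("copy_number" %in% names(df)) df$copy_number else NA_integer_
  CNVCalls(sample_id = df$sample, chrom = df$chrom, start = df$start,
           end = df$end, state = df$state, n_probes = df$n_probes,
           caller = caller, copy_number = cn)
}

#' Write CNV calls to a tab-separated file
#'
#' @param calls a [CNVCalls-class] object.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeCnvCalls <- function(calls, path) {
  df <- data.frame(
    sample = mcols(calls)$sample_id,
    chrom = as.character(GenomicRanges::seqnames(calls)),
    start = GenomicRanges::start(calls),
    end = GenomicRanges::end(calls),
    state = mcols(calls)$state,
    n_probes = mcols(calls)$n_probes,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a genetic map from anchor vectors
#'
#' @param chrom chromosome label per anchor.
#' @param pos_bp anchor positions (bp), strictly increasing per chromosome.
#' @param rate_cm_mb local recombination rate at each anchor, cM/Mb.
#' @param cm cumulative genetic position at each anchor, cM.
#' @return a [GeneticMap-class].
#' @export
geneticMap <- function(chrom, pos_bp, rate_cm_mb, cm) {
  df <- data.frame(chrom = as.character(chrom), pos_bp = as.numeric(pos_bp),
                   rate_cm_mb = as.numeric(rate_cm_mb), cm = as.numeric(cm))
  maps <- lapply(split(df[-1], df$chrom), function(m) {
    m[order(m$pos_bp), , drop = FALSE]
  })
  # order(): queries within a chromosome must see increasing anchors; the
  # validity method still rejects duplicated positions and decreasing cM.
  obj <- new("GeneticMap", maps = maps)
  validObject(obj)
  obj
}

#' Single-anchor constant-rate genetic map
#'
#' @param chrom chromosome label(s).
#' @param rate_cm_mb constant recombination rate, cM/Mb.
#' @param origin_bp position carrying genetic position 0 cM.
#' @return a [GeneticMap-class] extrapolating at \code{rate_cm_mb} everywhere.
#' @export
uniformGeneticMap <- function(chrom, rate_cm_mb = 1, origin_bp = 0) {
  maps <- lapply(stats::setNames(nm = as.character(chrom)), function(ch) {
    data.frame(pos_bp = origin_bp, rate_cm_mb = rate_cm_mb, cm = 0)
  })
  new("GeneticMap", maps = maps)
}

#' Read a genetic map from HapMap-style text
#'
#' Accepts either the 4-column dialect (chromosome, position bp, rate cM/Mb,
#' cumulative cM) or a 3-column per-chromosome file (position, rate,
#' cumulative cM) with the chromosome given via \code{chrom}. Anchors must be
#' sorted by position with non-decreasing cumulative cM.
#'
#' @param path path to the map file (whitespace/tab separated, with header).
#' @param chrom chromosome label, required for the 3-column dialect.
#' @return a [GeneticMap-class].
#' @export
readGeneticMap <- function(path, chrom = NULL) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) == 4L) {
    names(df) <- c("chrom", "pos_bp", "rate_cm_mb", "cm")
  } else if (ncol(df) == 3L) {
    if (is.null(chrom))
      stop("3-column genetic map needs an explicit 'chrom' label")
    names(df) <- c("pos_bp", "rate_cm_mb", "cm")
    df <- cbind(chrom = chrom, df)
  } else {
    stop("genetic map must have 3 or 4 columns, found ", ncol(df))
  }
  for (ch in unique(df$chrom)) {
    p <- df$pos_bp[df$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("genetic map anchors for ", ch, " are not sorted by position")
  }
  geneticMap(df$chrom, df$pos_bp, df$rate_cm_mb, df$cm)
}

#' Write a genetic map (4-column dialect)
#'
#' @param map a [GeneticMap-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeGeneticMap <- function(map, path) {
  rows <- do.call(rbind, lapply(names(map@maps), function(ch) {
    cbind(chrom = ch, map@maps[[ch]])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.mapFor <- function(map, chrom) {
  m <- map@maps[[as.character(chrom)]]
  if (is.null(m))
    stop("chromosome ", chrom, " absent from genetic map")
  m
}

#' @rdname cmAt
#' @export
setMethod("cmAt", "GeneticMap", function(map, chrom, pos_bp) {
  m <- .mapFor(map, chrom)
  pos_bp <- as.numeric(pos_bp)
  n <- nrow(m)
  out <- numeric(length(pos_bp))
  lo <- pos_bp <= m$pos_bp[1]
  hi <- pos_bp >= m$pos_bp[n]
  out[lo] <- m$cm[1] - (m$pos_bp[1] - pos_bp[lo]) * m$rate_cm_mb[1] / 1e6
  out[hi] <- m$cm[n] + (pos_bp[hi] - m$pos_bp[n]) * m$rate_cm_mb[n] / 1e6
  mid <- !(lo | hi)
  if (any(mid))
    out[mid] <- stats::approx(m$pos_bp, m$cm, xout = pos_bp[mid],
                              ties = "ordered")$y
  out
})

#' @rdname bpAt
#' @export
setMethod("bpAt", "GeneticMap", function(map, chrom, cm) {
  m <- .mapFor(map, chrom)
  cm <- as.numeric(cm)
  n <- nrow(m)
  out <- numeric(length(cm))
  lo <- cm <= m$cm[1]
  hi <- cm >= m$cm[n]
  rate1 <- m$rate_cm_mb[1]
  raten <- m$rate_cm_mb[n]
  out[lo] <- if (rate1 > 0)
    m$pos_bp[1] - (m$cm[1] - cm[lo]) / rate1 * 1e6 else m$pos_bp[1]
  out[hi] <- if (raten > 0)
    m$pos_bp[n] + (cm[hi] - m$cm[n]) / raten * 1e6 else m$pos_bp[n]
  mid <- !(lo | hi)
  if (any(mid))
    out[mid] <- stats::approx(m$cm, m$pos_bp, xout = cm[mid],
                              ties = min)$y
  out
})

#' Genetic length of an interval in Morgans
#'
#' Convenience wrapper: \code{(cmAt(end) - cmAt(start)) / 100}.
#'
#' @param map a [GeneticMap-class].
#' @param chrom chromosome label.
#' @param start_bp,end_bp interval boundaries (bp).
#' @return genetic length in Morgans.
#' @export
morgansBetween <- function(map, chrom, start_bp, end_bp) {
  (cmAt(map, chrom, end_bp) - cmAt(map, chrom, start_bp)) / 100
}

#' Read phased haplotypes
#'
#' Two dialects: a phased-genotype VCF (GT with \code{|}; parsed with
#' \pkg{VariantAnnotation}) or a simple matrix TSV whose first two columns
#' are \code{chrom} and \code{pos} followed by one 0/1 column per haplotype
#' (see [writeHaplotypes()]). Multi-allelic sites are skipped with a message;
#' an unphased genotype is an error; sites with missing alleles are dropped
#' (default) or fatal.
#'
#' @param path input path.
#' @param format `"auto"` (by extension), `"vcf"` or `"matrix"`.
#' @param missing how to treat sites with missing alleles: `"drop"` the site
#'   (logged) or `"fail"`.
#' @return a [HaplotypePanel-class] (two haplotypes per diploid VCF sample).
#' @export
readHaplotypes <- function(path, format = c("auto", "vcf", "matrix"),
                           missing = c("drop", "fail")) {
  format <- match.arg(format)
  missing <- match.arg(missing)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "matrix"
  if (format == "matrix") {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 3L || names(df)[1] != "chrom" || names(df)[2] != "pos")
      stop("haplotype matrix dialect needs columns chrom, pos, <hap ids...>")
    chrom <- unique(df$chrom)
    if (length(chrom) != 1L)
      stop("haplotype panel must cover a single chromosome")
    al <- t(as.matrix(df[-(1:2)]))
    return(HaplotypePanel(al, df$pos, chrom))
  }
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  biallelic <- lengths(rr$ALT) == 1L
  if (any(!biallelic))
    message(sum(!biallelic), " multi-allelic site(s) skipped")
  gt <- VariantAnnotation::geno(vcf)$GT[biallelic, , drop = FALSE]
  pos <- GenomicRanges::start(rr)[biallelic]
  chrom <- as.character(GenomeInfoDb::seqnames(rr))[biallelic]
  if (length(unique(chrom)) != 1L)
    stop("haplotype panel must cover a single chromosome")
  unphased <- matrix(grepl("/", gt, fixed = TRUE), nrow = nrow(gt),
                     dimnames = dimnames(gt))
  if (any(unphased)) {
    i <- which(unphased, arr.ind = TRUE)[1, ]
    stop("unphased genotype at site ", rownames(gt)[i[1]],
         " (sample ", colnames(gt)[i[2]], ")")
  }
  a1 <- suppressWarnings(matrix(as.integer(sub("\\|.*", "", gt)), nrow(gt)))
  a2 <- suppressWarnings(matrix(as.integer(sub(".*\\|", "", gt)), nrow(gt)))
  incomplete <- rowSums(is.na(a1) | is.na(a2)) > 0
  if (any(incomplete)) {
    if (missing == "fail")
      stop("missing allele(s) at ", sum(incomplete), " site(s)")
    message(sum(incomplete), " site(s) with missing alleles dropped")
  }
  keep <- !incomplete
  samples <- colnames(gt)
  al <- rbind(t(a1[keep, , drop = FALSE]), t(a2[keep, , drop = FALSE]))
  rownames(al) <- c(paste0(samples, "_h1"), paste0(samples, "_h2"))
  ord <- order(rep(seq_along(samples), 2))  # interleave h1/h2 per sample
  al <- al[ord, , drop = FALSE]
  HaplotypePanel(al, pos[keep], unique(chrom))
}

#' Write phased haplotypes
#'
#' The matrix dialect round-trips bit-exactly through [readHaplotypes()].
#' The VCF dialect pairs haplotypes \code{<sample>_h1}/\code{_h2} into phased
#' diploid genotypes.
#'
#' @param panel a [HaplotypePanel-class].
#' @param path output path.
#' @param format `"matrix"` or `"vcf"`.
#' @return invisibly, the path.
#' @export
writeHaplotypes <- function(panel, path, format = c("matrix", "vcf")) {
  format <- match.arg(format)
  al <- panel@alleles
  if (format == "matrix") {
    df <- data.frame(chrom = panel@chrom, pos = panel@positions,
                     check.names = FALSE)
    df <- cbind(df, as.data.frame(t(al), check.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  ids <- rownames(al)
  samples <- unique(sub("_h[12]$", "", ids))
  if (!setequal(ids, c(paste0(samples, "_h1"), paste0(samples, "_h2"))))
    stop("VCF output needs paired haplotypes named <sample>_h1 / <sample>_h2")
  gtcols <- vapply(samples, function(s) {
    paste0(al[paste0(s, "_h1"), ], "|", al[paste0(s, "_h2"), ])
  }, character(ncol(al)))
  if (is.null(dim(gtcols))) gtcols <- matrix(gtcols, nrow = 1)
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", panel@chrom, ">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- apply(cbind(panel@chrom, format(panel@positions, scientific = FALSE,
                                          trim = TRUE),
                      paste0("snp", seq_along(panel@positions)),
                      "A", "G", ".", "PASS", ".", "GT", gtcols),
                1, paste, collapse = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a phenotype table
#'
#' TSV with columns \code{sample}, \code{aud} (0/1) and optionally
#' \code{diagnoses} (comma-separated labels; empty for none). AUD carriers
#' are guaranteed to carry the label \code{AUD} in their diagnosis set, and
#' \code{any_psych} is derived as "diagnosis set non-empty".
#'
#' @param path input path.
#' @return data.frame with columns \code{sample}, \code{aud},
#'   \code{diagnoses} (list column) and \code{any_psych}.
#' @export
readPhenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample", "aud") %in% names(df)))
    stop("phenotype table needs columns sample, aud")
  diag <- if ("diagnoses" %in% names(df)) df$diagnoses else ""
  diag[is.na(diag)] <- ""
  sets <- strsplit(diag, ",", fixed = TRUE)
  sets <- lapply(seq_along(sets), function(i) {
    s <- setdiff(trimws(sets[[i]]), "")
    if (df$aud[i] == 1) s <- union(s, "AUD")
    s
  })
  data.frame(sample = df$sample, aud = as.integer(df$aud),
             diagnoses = I(sets),
             any_psych = as.integer(lengths(sets) > 0),
             stringsAsFactors = FALSE)
}

#' Write a phenotype table
#'
#' @param pheno data.frame as returned by [readPhenotypes()] or
#'   [simulatePhenotypes()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writePhenotypes <- function(pheno, path) {
  diag <- vapply(pheno$diagnoses, paste, character(1), collapse = ",")
  utils::write.table(
    data.frame(sample = pheno$sample, aud = pheno$aud, diagnoses = diag),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene intervals from a BED file
#'
#' @param path BED file (0-based half-open, as usual); imported with
#'   \pkg{rtracklayer}, so returned ranges are 1-based inclusive.
#' @return a \code{GRanges} with a \code{name} column.
#' @export
readGenesBed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

## ---- show methods ----------------------------------------------------------

setMethod("show", "GeneticMap", function(object) {
  cat("GeneticMap with", length(object@maps), "chromosome(s)\n")
  for (ch in names(object@maps)) {
    m <- object@maps[[ch]]
    cat(sprintf("  %s: %d anchor(s), %.4g-%.4g cM\n", ch, nrow(m),
                m$cm[1], m$cm[nrow(m)]))
  }
})

setMethod("show", "HaplotypePanel", function(object) {
  cat(sprintf("HaplotypePanel: %d haplotype(s) x %d SNP(s) on %s\n",
              nrow(object@alleles), length(object@positions), object@chrom))
})

setMethod("show", "FlankWindow", function(object) {
  cat(sprintf(
    "FlankWindow on %s around [%s, %s]: %d left / %d right SNP(s)%s\n",
    object@chrom, format(object@regionStart, big.mark = ","),
    format(object@regionEnd, big.mark = ","), object@nLeft, object@nRight,
    if (object@shortLeft || object@shortRight) " (short side)" else ""))
})

setMethod("show", "AgeEstimate", function(object) {
  cat(sprintf(
    "Gamma-method age: tau = %.1f generations (%d%% CI %.1f-%.1f)\n",
    object@tau, round(100 * (1 - object@alpha)), object@ciLow, object@ciHigh))
  cat(sprintf("  l_ave = %.5f Morgans over %d haplotype(s), %s weighting",
              object@lAve, object@n, object@weightingMode))
  if (object@nCensored > 0)
    cat(sprintf("; %d censored segment(s) excluded", object@nCensored))
  cat("\n")
})

## ---- accessors -------------------------------------------------------------

#' @rdname HaplotypePanel-class
#' @export
setMethod("alleleMatrix", "HaplotypePanel", function(x) x@alleles)
#' @rdname HaplotypePanel-class
#' @export
setMethod("alleleMatrix", "FlankWindow", function(x) x@alleles)
#' @rdname HaplotypePanel-class
#' @export
setMethod("snpPositions", "HaplotypePanel", function(x) x@positions)
#' @rdname HaplotypePanel-class
#' @export
setMethod("snpPositions", "FlankWindow", function(x) x@positions)
#' @rdname HaplotypePanel-class
#' @export
setMethod("hapIds", "HaplotypePanel", function(x) rownames(x@alleles))
#' @rdname HaplotypePanel-class
#' @export
setMethod("hapIds", "FlankWindow", function(x) rownames(x@alleles))
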