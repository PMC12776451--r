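# Small in-code fixtures shared across test files.

# A flank window built directly: nLeft/nRight SNPs spaced `gap` bp around
# [regionStart, regionEnd], with a given haplotype matrix.
makeWindow <- function(alleles, nLeft, nRight, regionStart = 1e6,
                       regionEnd = 2e6, gap = 1e4, chrom = "chr1") {
  pos <- c(regionStart - gap * rev(seq_len(nLeft)),
           regionEnd + gap * seq_len(nRight))
  new("FlankWindow", alleles = alleles, positions = pos, chrom = chrom,
      regionStart = regionStart, regionEnd = regionEnd,
      nLeft = as.integer(nLeft), nRight = as.integer(nRight),
      shortLeft = FALSE, shortRight = FALSE)
}

# Write a CNV call TSV and return its path.
writeCallTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Independent oracle for the outward sharing walk, written as a direct
# transcription of the rule (checked against extendShared): scan outward;
# at a mismatch, rescue only when there is at least one SNP ahead and the
# next k (or all remaining) SNPs all match.
walkOracle <- function(match, k) {
  m <- length(match)
  last <- 0L; rescued <- 0L
  for (i in seq_len(m)) {
    if (match[i]) { last <- i; next }
    remaining <- m - i
    ahead <- if (remaining > 0) match[i + seq_len(min(k, remaining))] else
      logical(0)
    if (length(ahead) > 0 && all(ahead)) rescued <- rescued + 1L
    else return(list(terminus = last, n_rescued = rescued,
                     censored = last == m))
  }
  list(terminus = last, n_rescued = rescued, censored = last == m)
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments
# (small n only); used as the independent oracle.
exactMannWhitneyP <- function(a, b) {
  na <- length(a); nb <- length(b)
  vals <- c(a, b)
  U_obs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  combs <- combn(na + nb, na)
  us <- apply(combs, 2, function(idx) {
    aa <- vals[idx]; bb <- vals[-idx]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  })
  mu <- na * nb / 2
  mean(abs(us - mu) >= abs(U_obs - mu) - 1e-9)
}
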