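---
title: "Methods: recurrent-CNV detection, haplotype dating and association"
author: "founderCNV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recurrent-CNV detection, haplotype dating and association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderCNV)
```

## The problem

In founder populations — isolated groups descended from a small number of
ancestors — large copy-number variants can reach appreciable carrier
frequencies instead of occurring as scattered, molecularly distinct
events. A *recurrent* CNV (rCNV) in this sense is one event: every
carrier shares the same breakpoints and the same flanking haplotype,
inherited from a single founder chromosome. That identity makes three
analyses possible that rare CNVs do not support: counting carriers per
population, dating the founding mutation from the decay of the shared
haplotype, and testing carriers against non-carriers for association with
a phenotype. This package implements that pipeline end to end for
SNP-array call sets.

## Consensus calling and retention

Array CNV callers disagree, so a call enters the analysis only when two
callers report it for the same sample, chromosome and copy-number state.
"Detected by both" is operationalised as reciprocal overlap of at least
0.5 — the overlap must cover at least half of *each* caller's interval —
with pairs assigned greedily by descending overlap and each input call
used once. The consensus interval is the **intersection** of the pair:
conservative, which matters downstream because recurrent-group clustering
keys on breakpoints (the union is available via `mode = "union"`). The
consensus probe count is the minimum of the two callers' counts, again the
conservative choice for the probe filter. Retained calls must span at
least 10 array SNPs, be at least 10 kb long, and lie on an autosome. The
three retention rules are independent per-call predicates, so they commute
— a property the test suite asserts — and rejection counts per rule are
recorded on the result.

## Recurrent groups

Within one population (one array, hence one probe grid), calls descending
from the same founder event land on identical probe boundaries, so the
default clustering tolerance is 0 bp: same chromosome, same state, same
start and same end. Single linkage with a configurable tolerance handles
noisier callers. The group region is the modal start/end over members with
ties to the smaller coordinate (deterministic, order-invariant), and a
group is recurrent when at least two distinct samples carry it. Carrier
frequency is carriers / individuals; allele frequency additionally counts
two alleles for members whose copy number (0 or 4) marks homozygosity.
Across populations genotyped on different arrays the probe grids differ,
so matching relaxes to reciprocal overlap ≥ 0.8 with equal state, assigned
one-to-one by greatest overlap.

Groups qualify for association testing when they have enough carriers for
a large effect to be detectable: at least `min_carriers` (default 25) and
carrier frequency strictly above `min_frequency` (default 0.022, the
frequency at which simulation puts adequate power for an odds ratio of 10
at these cohort sizes; `powerBySimulation()` reproduces that calculation
for any design).

## Shared-haplotype measurement

Dating needs, for each carrier haplotype, the genetic length of the
segment over which it still matches the founder haplotype. The package
takes the 60 phased SNPs nearest the CNV on each side (strictly outside
it), reconstructs the putative ancestral haplotype as the per-SNP modal
allele among carrier haplotypes (ties to the lexicographically first
haplotype id, so the result is deterministic), and walks outward from each
CNV boundary:

* a matching SNP extends the segment;
* a mismatching SNP is *rescued* — treated as a point mutation or
  genotyping error rather than a recombination — when the next
  `rescue_k = 5` SNPs outward all match (all remaining SNPs when fewer
  than five remain); an empty look-ahead rescues nothing, so
  `rescue_k = 0` reduces to strict matching;
* otherwise the segment ends at the last matching SNP.

A walk that consumes the whole window leaves the segment *censored*: its
true extent is only bounded below. Censored segments are excluded from
dating by default (the estimator assumes fully observed lengths, and
exclusion is flagged and counted); `dropCensored = FALSE` treats their
observed lengths as complete, which bounds the age from above and supports
"at least N generations" statements. Measuring against the consensus
rather than all pairwise combinations reflects the single-ancestor model;
a pairwise mode exists for heterogeneous groups. Relatives are removed
before measurement by a greedy rule (drop the sample in the most remaining
related pairs, ties lexicographic) given an externally computed list of
first/second-degree pairs.

Two numerical conventions deserve notice. The terminus is the last
*matching* SNP, not the midpoint of the bracketing interval, so each side
under-measures by up to one inter-SNP spacing; and because the haplotype
beyond a true recombination still matches the consensus at roughly the
ancestral-allele frequency, the walk overshoots by a geometric number of
SNPs. The two effects act in opposite directions and, at the default
simulation design (below), net out to a few percent on the age estimate.
The rescue rule interacts with the same trade-off: it restores sides
truncated by an isolated within-segment mutation (in simulation at
mismatch rate 0.01, rescue recovers the full extent on roughly three
quarters of affected sides, strict matching on none), at the price of
occasionally rescuing the first off-segment mismatch and overshooting
slightly further.

## Gamma-method dating

Genetic lengths come from a piecewise-linear map of cumulative cM against
bp (HapMap-style anchors; linear interpolation, extrapolation beyond the
terminal anchors at the terminal rate), carried internally in Morgans
because the estimator's rate parameter is per Morgan. Under lineage
independence each per-side length is exponential with rate tau, so with
l_i the summed left+right length of haplotype i,

* point estimate: `tau_hat = 2 / l_ave`;
* interval: `2 * tau * sum(l_i) ~ chi-square(4n)` inverted at level
  `1 - alpha` (default 0.05). The interval is exact under the model; a
  percentile bootstrap (`tauConfidenceBoot()`) is the model-free
  alternative.

Two weighting conventions are exposed because the phrase "weighted by the
haplotypes sharing a breakpoint" admits both readings: a plain mean over
haplotypes, and a mean over distinct (left, right) breakpoint groups
weighted by group size. They are algebraically identical — the grouped sum
expands to the per-haplotype sum — and the package asserts that identity
rather than guessing further. Ages of two sets of rCNVs (for example,
those shared across populations versus population-specific ones) are
compared by the Mann-Whitney rank test, exact for small untied groups.
Conversion of generations to years is left as an explicit
`years_per_generation` parameter with no default, since no single
generation interval is canonical.

The correlated-genealogy refinement of the Gamma method is deliberately
out of scope: the independence assumption is the stated model, and its
chi-square pivot interval is this package's own addition, labelled as
such.

## The synthetic-data generator

`simConfig()` / `simulateStudy()` generate the statistical structure the
analysis assumes, with ground truth recorded: per-SNP background allele
frequencies (minor-allele frequency uniform on 0.1–0.5), an ancestral
haplotype drawn from them, carrier haplotypes copying the ancestral
alleles over a segment whose per-side genetic length is exponential at
rate tau (truncated at the window with a censoring flag), independent
per-SNP flips at rate epsilon inside the segment, background alleles
outside, plus two noisy caller tables (boundary jitter, independent
dropout) and binary phenotypes whose non-carrier case probability is
solved so the population prevalence is met at the target carrier odds
ratio. Every operation draws from a generator seeded from the mandatory
config seed, so identical configs give byte-identical studies.

The default window places each 60-SNP flank over a genetic span of
`6 / tau` Morgans: the first recombination then falls inside the examined
window with probability `1 - exp(-6)`, and the inter-SNP spacing
`0.1 / tau` Morgans stays an order of magnitude below the mean shared
length. At 1 cM/Mb and tau = 500 that is a 1.2-Mb flank at 20-kb spacing —
ordinary SNP-array territory. This design choice is what makes age
recovery accurate simultaneously at tau = 100 and tau = 1000; a single
fixed physical spacing would censor most segments at small tau or
discretise them away at large tau.

What the generator does *not* emulate bounds what passing tests show:
there is no coalescent correlation between carrier lineages (the
independence model is simulated, so interval coverage is exact by
construction rather than demonstrated robust), no linkage disequilibrium
among background alleles, no demographic history, and no LRR/BAF signal
level — caller behaviour enters only as jitter and dropout. Mutation and
genotyping error are a single i.i.d. mismatch process. Real data would
add LD structure (lengthening overshoot) and pedigree correlation
(widening true intervals); results on synthetic data are a correctness
check of the machinery, not a calibration against cohort reality.

## Degenerate inputs and edge rules

Empty call sets summarise to zero events with an explicit flag rather than
NaN fractions; a cohort of zero individuals is an error. Zero-length
shared segments (coalescence at the first flanking SNP) participate in
l_ave; estimation errors only when every segment is censored or
zero-length. Zero cells in a 2x2 table trigger the Haldane–Anscombe +0.5
correction, flagged on the result; a zero margin leaves the odds ratio and
chi-square undefined rather than corrected. The one-sided chi-square
p-value is half the two-sided value when the observed odds ratio exceeds
1, else `1 - p/2`; both are reported because published tables mix the two
conventions. Multi-allelic VCF sites are skipped with a logged count,
unphased genotypes are fatal, and sites with missing alleles are dropped
by default (conservative for sharing: a dropped site cannot fake a match).

## Problem sizes in the test suite

The shipped tests run the full stack at sizes chosen to give the
statistical assertions teeth while staying quick on one core: age recovery
at tau ∈ {100, 500, 1000} with 50 carriers and mismatch rate 0.002 over
200 replicates per setting (median within 10% of truth); interval coverage
over 1000 simulated cohorts of 25 segments at tau = 500 (95% ± 2%); the
rescue walk against exhaustive enumeration of all 4096 mismatch patterns
of a 12-SNP window for rescue_k ∈ {0, 5, ∞}; dual-caller dropout over
10,000 events; and null power over 10,000 replicates.

## Known limitations

Association is plain chi-square: no covariates, no kinship adjustment, so
p-values in structured cohorts are anti-conservative. The odds ratio
itself is Jensen-biased upward on the log scale when a cell expectation
drops toward 5 (about +9% at 27 carriers in simulation) — the Woolf
interval is the right width, but small-sample point estimates should be
read accordingly. Dating excludes censored segments, which biases ages
upward when the window is narrow relative to 1/tau; widen the SNP window
(or report the censored-as-observed sensitivity estimate) for young
variants. Phasing is assumed done and correct; phase switch errors inside
a flank would truncate sharing and inflate ages.
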