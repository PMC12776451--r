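test_that("flank windows take the nearest SNPs strictly outside the CNV", {
  al <- matrix(0L, 2, 250, dimnames = list(c("A_h1", "A_h2"), NULL))
  pos <- c(seq(1e5, by = 5e3, length.out = 100),          # upstream
           seq(1.5e6, by = 1e3, length.out = 50),          # inside CNV
           seq(2.1e6, by = 5e3, length.out = 100))         # downstream
  panel <- HaplotypePanel(al, pos, "chr1")
  w <- buildFlankWindow(panel, 1.4e6, 2.0e6, nSnps = 60)
  expect_equal(w@nLeft, 60)
  expect_equal(w@nRight, 60)
  expect_true(all(snpPositions(w) < 1.4e6 | snpPositions(w) > 2.0e6))
  # the nearest upstream SNPs are chosen
  expect_equal(max(snpPositions(w)[1:60]), max(pos[pos < 1.4e6]))

  w40 <- buildFlankWindow(panel, 3.5e5, 2.0e6, nSnps = 60)
  expect_equal(w40@nLeft, 50)
  expect_true(w40@shortLeft)
  expect_error(buildFlankWindow(panel, 5e4, 2e6), "upstream")
})

test_that("the consensus haplotype is the per-SNP carrier majority", {
  al <- rbind(B_h1 = c(0L, 0L, 1L, 1L),
              A_h1 = c(0L, 1L, 1L, 0L),
              C_h1 = c(1L, 0L, 1L, 0L))
  expect_equal(consensusHaplotype(al), c(0L, 0L, 1L, 0L))
  expect_equal(consensusHaplotype(al[1, , drop = FALSE]), unname(al[1, ]))
  # 2 vs 2 tie -> allele of lexicographically first haplotype id (A_h1)
  al2 <- rbind(B_h1 = c(1L), A_h1 = c(0L), C_h1 = c(1L), D_h1 = c(0L))
  expect_equal(consensusHaplotype(al2), 0L)
  expect_error(consensusHaplotype(al[0, , drop = FALSE]), "no carrier")
})

test_that("the outward walk applies the five-SNP rescue rule", {
  m <- 60
  cons <- rep(0L, 2 * m)
  mk <- function(mismatch_right) {
    hap <- cons
    hap[m + mismatch_right] <- 1L
    makeWindow(rbind(X_h1 = hap, ref = cons), m, m)
  }
  # all SNPs match -> terminus at window edge, censored, nothing rescued
  w <- mk(integer())
  r <- extendShared("X_h1", cons, w, "right")
  expect_true(r$censored)
  expect_equal(r$terminus, m)
  expect_equal(r$n_rescued, 0)

  # mismatch at SNP 10 with SNPs 11-15 matching -> rescued, walk continues
  r10 <- extendShared("X_h1", cons, mk(10), "right")
  expect_equal(r10$n_rescued, 1)
  expect_true(r10$censored)

  # mismatches at SNPs 10 and 12 -> look-ahead fails, terminus at SNP 9
  r1012 <- extendShared("X_h1", cons, mk(c(10, 12)), "right")
  expect_equal(r1012$terminus, 9)
  expect_equal(r1012$n_rescued, 0)
  expect_false(r1012$censored)

  # rescue disabled: the walk stops at the first mismatch
  r0 <- extendShared("X_h1", cons, mk(10), "right", rescueK = 0)
  expect_equal(r0$terminus, 9)
  # rescue_k = Inf: a single isolated mismatch never terminates the walk,
  # but the infinite look-ahead sees any later mismatch and stops
  rInf <- extendShared("X_h1", cons, mk(30), "right", rescueK = Inf)
  expect_true(rInf$censored)
  expect_equal(rInf$n_rescued, 1)
  rInf2 <- extendShared("X_h1", cons, mk(c(10, 40)), "right", rescueK = Inf)
  expect_equal(rInf2$terminus, 9)
})

test_that("left-side extension walks outward toward smaller positions", {
  m <- 20
  cons <- rep(1L, 2 * m)
  hap <- cons
  hap[m - 2] <- 0L   # third SNP outward on the left, look-ahead fails at edge?
  w <- makeWindow(rbind(X_h1 = hap, ref = cons), m, m)
  r <- extendShared("X_h1", cons, w, "left", rescueK = 5)
  expect_equal(r$n_rescued, 1)  # SNPs 4..8 outward all match
  expect_true(r$censored)
  hap2 <- cons
  hap2[m] <- 0L; hap2[m - 3] <- 0L  # first and fourth SNP outward mismatch
  w2 <- makeWindow(rbind(X_h1 = hap2, ref = cons), m, m)
  r2 <- extendShared("X_h1", cons, w2, "left", rescueK = 5)
  expect_equal(r2$terminus, 0)
  expect_equal(r2$terminus_bp, w2@regionStart)
})

test_that("the walk agrees with its direct-transcription oracle on random patterns", {
  set.seed(42)
  for (i in 1:200) {
    m <- sample(5:30, 1)
    match <- runif(m) < 0.8
    k <- sample(c(0, 1, 3, 5, Inf), 1)
    got <- founderCNV:::.walkShared(match, k)
    want <- walkOracle(match, k)
    expect_identical(got, want)
  }
})

test_that("rescued mismatches are isolated by at least the look-ahead length", {
  set.seed(9)
  for (i in 1:50) {
    m <- 40
    hap <- as.integer(runif(m) < 0.15)
    cons <- rep(0L, 2 * m)
    w <- makeWindow(rbind(X_h1 = c(rep(0L, m), hap), ref = cons), m, m)
    r <- extendShared("X_h1", cons, w, "right", rescueK = 5)
    mm <- which(hap[seq_len(max(r$terminus, 1))] == 1L)
    if (length(mm) > 1)
      expect_true(min(diff(mm)) > 5)
  }
})

test_that("shared-segment genetic lengths follow the map", {
  m <- 30
  cons <- rep(0L, 2 * m)
  gm <- uniformGeneticMap("chr1", 1)
  # full sharing across a 10 kb-spaced 30-SNP window: 0.3 Mb per side
  w <- makeWindow(rbind(X_h1 = cons, ref = cons), m, m, gap = 1e4)
  seg <- sharedSegment("X_h1", cons, w, gm)
  expect_true(seg$censored_left && seg$censored_right)
  expect_equal(seg$genetic_length_morgans,
               ((1e6 - w@positions[1]) + (w@positions[2 * m] - 2e6)) / 1e8)

  # zero sharing on both sides
  hap <- 1L - cons
  w0 <- makeWindow(rbind(X_h1 = hap, ref = cons), m, m, gap = 1e4)
  seg0 <- sharedSegment("X_h1", cons, w0, gm)
  expect_equal(seg0$genetic_length_morgans, 0)
  expect_equal(seg0$length_bp, 0)

  # piecewise map: 2 Mb at 0.5 cM/Mb upstream + 1 Mb at 1 cM/Mb downstream
  gm2 <- geneticMap(rep("chr1", 3), c(0, 1e6, 4e6), c(0.5, 1, 1),
                    c(0, 0.5, 3.5))
  hapL <- cons
  w2 <- new("FlankWindow",
            alleles = rbind(X_h1 = c(0L, 0L), ref = c(0L, 0L)),
            positions = c(-1e6, 3e6), chrom = "chr1",
            regionStart = 1e6, regionEnd = 2e6, nLeft = 1L, nRight = 1L,
            shortLeft = TRUE, shortRight = TRUE)
  seg2 <- sharedSegment("X_h1", c(0L, 0L), w2, gm2)
  # left: 2 Mb at 0.5 cM/Mb = 1 cM; right: 1 Mb at 1 cM/Mb = 1 cM
  expect_equal(seg2$genetic_length_morgans, 0.02)
})

test_that("genetic length grows with terminus distance (map monotonicity)", {
  set.seed(5)
  gm <- geneticMap(rep("chr1", 3), c(0, 1e6, 4e6), c(0.2, 1.4, 0.7),
                   c(0, 0.2, 4.4))
  m <- 25
  cons <- rep(0L, 2 * m)
  lens <- sapply(0:m, function(k) {
    hap <- c(rep(0L, m), rep(0L, k), if (k < m) rep(1L, m - k))
    w <- makeWindow(rbind(X_h1 = hap, ref = cons), m, m, gap = 2e4)
    sharedSegment("X_h1", cons, w, gm, rescueK = 0)$genetic_length_morgans
  })
  expect_true(all(diff(lens) >= -1e-12))
})

test_that("relative exclusion drops the highest-degree samples greedily", {
  ids <- c("A_h1", "A_h2", "B_h1", "B_h2", "C_h1", "C_h2")
  expect_equal(excludeRelatives(ids, NULL), ids)
  one <- excludeRelatives(ids, data.frame(s1 = "A", s2 = "B"))
  expect_setequal(one, c("B_h1", "B_h2", "C_h1", "C_h2"))  # tie drops A
  star <- excludeRelatives(ids, data.frame(s1 = c("A", "A"),
                                           s2 = c("B", "C")))
  expect_setequal(star, c("B_h1", "B_h2", "C_h1", "C_h2"))
})

test_that("pairwise sharing never measures less than the best single partner", {
  set.seed(21)
  m <- 15
  gm <- uniformGeneticMap("chr1", 1)
  al <- matrix(as.integer(runif(6 * 2 * m) < 0.5), nrow = 6,
               dimnames = list(paste0("H", 1:6, "_h1"), NULL))
  w <- makeWindow(al, m, m)
  segC <- sharedSegments(w, rownames(al), gm, mode = "consensus")
  segP <- sharedSegments(w, rownames(al), gm, mode = "pairwise")
  expect_equal(nrow(segP), 6)
  expect_true(all(segP$genetic_length_morgans >= 0))
})
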