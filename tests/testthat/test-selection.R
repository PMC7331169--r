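# independent brute-force oracle for the EHH decay and its integral
oracle_ihh <- function(hap, pos, core, cutoff) {
  n <- ncol(hap)
  total <- 0
  for (step in c(-1L, 1L)) {
    ehh <- 1; ihh <- 0; i <- core
    repeat {
      j <- i + step
      if (j < 1 || j > nrow(hap)) return(NA_real_)
      rng <- if (step > 0) (core + 1):j else j:(core - 1)
      key <- apply(hap[rng, , drop = FALSE], 2, paste, collapse = ",")
      cnt <- table(key)
      e2 <- sum(cnt * (cnt - 1) / 2) / (n * (n - 1) / 2)
      ihh <- ihh + (ehh + e2) / 2 * abs(pos[j] - pos[i])
      ehh <- e2; i <- j
      if (ehh < cutoff) break
    }
    total <- total + ihh
  }
  total
}

test_that("windowed F_ST matches the variance-component oracle", {
  ## pop1: 4 het + 6 hom-ref (p = 0.2); pop2: 6 hom-alt + 4 het (p = 0.8)
  g1 <- c(rep(1L, 4), rep(0L, 6)); g2 <- c(rep(2L, 6), rep(1L, 4))
  pop <- setNames(rep(c("p1", "p2"), each = 10), paste0("s", 1:20))
  geno <- make_geno(rep("chr1", 1), 100L, matrix(c(g1, g2), 1, 20), pop,
                    chrom_lengths = c(chr1 = 1e5))
  fst <- fst_windows(geno, "p1", "p2", window = 1e5)
  ## independent oracle straight from the 1984 variance components
  n1 <- 10; n2 <- 10; p1 <- 0.2; p2 <- 0.8; h1 <- 0.4; h2 <- 0.4
  nbar <- 10; r <- 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- 0.5
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- 0.4
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  expect_equal(fst$value, a / (a + b + cc), tolerance = 1e-12)
  expect_gt(fst$value, 0.3)
})

test_that("F_ST behaves at its limits and the estimators agree", {
  pop <- setNames(rep(c("p1", "p2"), each = 10), paste0("s", 1:20))
  same <- matrix(rep(c(rep(1L, 5), rep(0L, 5)), 2), 1, 20)
  geno <- make_geno("chr1", 100L, same, pop, chrom_lengths = c(chr1 = 1e3))
  expect_lt(abs(fst_windows(geno, "p1", "p2", window = 1e3)$value), 0.06)
  fixed <- matrix(c(rep(0L, 10), rep(2L, 10)), 1, 20)
  geno <- make_geno("chr1", 100L, fixed, pop, chrom_lengths = c(chr1 = 1e3))
  expect_gt(fst_windows(geno, "p1", "p2", window = 1e3)$value, 0.9)
  ## Weir-Cockerham and Hudson correlate on simulated windows
  sim <- fix_sim()
  wc <- fst_windows(sim$geno, "ancestralA", "ancestralB", window = 2e5)
  hu <- fst_windows(sim$geno, "ancestralA", "ancestralB", window = 2e5,
                    estimator = "hudson")
  ok <- !is.na(wc$value) & !is.na(hu$value)
  expect_gt(cor(wc$value[ok], hu$value[ok]), 0.99)
  expect_gt(attr(wc, "genome_mean"), 0.2)     # strongly drifted panels
})

test_that("nucleotide diversity equals the mean pairwise difference", {
  pop <- setNames(rep("p1", 10), paste0("s", 1:10))
  mono <- matrix(0L, 3, 10)
  geno <- make_geno(rep("chr1", 3), c(100L, 200L, 300L), mono, pop,
                    chrom_lengths = c(chr1 = 1e3))
  expect_equal(pi_windows(geno, "p1", window = 1e3)$value, 0)
  ## single site at p = 0.5 with many alleles: pi -> 0.5
  pop50 <- setNames(rep("p1", 50), paste0("s", 1:50))
  half <- matrix(c(rep(0L, 25), rep(2L, 25)), 1, 50)
  geno <- make_geno("chr1", 100L, half, pop50, chrom_lengths = c(chr1 = 1e3))
  expect_equal(pi_windows(geno, "p1", window = 1e3)$value, 0.5,
               tolerance = 0.011)
  ## random window against the O(n^2) pairwise oracle
  set.seed(71)
  gt <- matrix(rbinom(10 * 12, 2, runif(10, 0.1, 0.9)), 10, 12)
  pop12 <- setNames(rep("p1", 12), paste0("s", 1:12))
  geno <- make_geno(rep("chr1", 10), 1:10 * 50L, gt, pop12,
                    chrom_lengths = c(chr1 = 1e3))
  got <- pi_windows(geno, "p1", window = 1e3)
  oracle <- mean(apply(gt, 1, function(g) {
    al <- c(rep(1, sum(g)), rep(0, 24 - sum(g)))
    s <- 0; np <- 0
    for (i in 1:23) for (j in (i + 1):24) {
      s <- s + (al[i] != al[j]); np <- np + 1
    }
    s / np
  }))
  expect_equal(got$value, oracle, tolerance = 1e-12)
  expect_equal(got$pi_per_bp, oracle * 10 / 1e3, tolerance = 1e-12)
})

test_that("iHH matches the hand-computed trapezoid of the EHH decay", {
  pos <- c(100, 200, 300, 400, 600)
  hapA <- rbind(c(0, 1, 0, 1),
                c(0, 0, 1, 1),
                c(0, 0, 0, 0),
                c(0, 0, 1, 1),
                c(0, 1, 0, 1))
  hapB <- rbind(c(0, 1, 1, 0),
                c(0, 1, 0, 1),
                c(0, 0, 1, 1),
                c(0, 1, 1, 0),
                c(1, 0, 1, 0))
  geno <- toy_hap_geno(hapA, hapB, pos)
  sc <- xpehh_scan(geno, "popA", "popB", maf_min = 0, ehh_cutoff = 0.05)
  ## hand arithmetic for popA at the middle core:
  ## right: EHH 1 -> 1/3 (100 bp) -> 0 (200 bp); left: 1 -> 1/3 -> 0
  expect_equal(sc$ihh_a[3], (1 + 1/3) / 2 * 100 + (1/3) / 2 * 200 +
                            (1 + 1/3) / 2 * 100 + (1/3) / 2 * 100)
  expect_equal(sc$ihh_a[3], oracle_ihh(hapA, pos, 3, 0.05))
  expect_equal(sc$ihh_b[3], oracle_ihh(hapB, pos, 3, 0.05))
  expect_equal(sc$raw[3], log(sc$ihh_a[3] / sc$ihh_b[3]))
  ## identical haplotype sets give exactly zero everywhere
  sc0 <- xpehh_scan(toy_hap_geno(hapA, hapA, pos), "popA", "popB",
                    maf_min = 0, ehh_cutoff = 0.05)
  expect_true(all(sc0$raw[!is.na(sc0$raw)] == 0))
})

test_that("standardized scores have zero mean and unit variance", {
  set.seed(73)
  n <- 120
  pos <- sort(sample.int(3e5, n))
  hapA <- matrix(rbinom(n * 12, 1, 0.5), n, 12)
  hapB <- matrix(rbinom(n * 12, 1, 0.5), n, 12)
  geno <- toy_hap_geno(hapA, hapB, pos)
  sc <- xpehh_scan(geno, "popA", "popB", ehh_cutoff = 0.2)
  ok <- !is.na(sc$std)
  expect_gt(sum(ok), 20)
  expect_lt(abs(mean(sc$std[ok])), 1e-6)
  expect_lt(abs(sd(sc$std[ok]) - 1), 1e-6)
})

test_that("region merging follows the one-gap, half-distance, no-singleton rules", {
  ## S S n S S at 10..50 -> one region
  sc <- data.frame(chrom = "c1", pos = c(10, 20, 30, 40, 50),
                   significant = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  reg <- merge_regions(sc)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$n_snps, 4L)
  ## S n n S -> two singleton runs, both dropped
  sc <- data.frame(chrom = "c1", pos = c(10, 20, 30, 40),
                   significant = c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(nrow(merge_regions(sc)), 0L)
  ## flanking extension by half the distance to the nearest non-sig marker
  sc <- data.frame(chrom = "c1", pos = c(50, 100, 200, 260),
                   significant = c(FALSE, TRUE, TRUE, FALSE))
  reg <- merge_regions(sc)
  expect_equal(c(reg$start, reg$end), c(75, 230))
})

test_that("selection overlap is the brute-force interval intersection", {
  a <- data.frame(chrom = "c1", start = c(0, 100), end = c(50, 300))
  b <- data.frame(chrom = "c1", start = 150, end = 200)
  got <- overlap_selection(a, b)
  expect_equal(got[, c("start", "end")],
               data.frame(start = 150, end = 200))
  expect_equal(got$method, "both")
  expect_equal(nrow(overlap_selection(a, data.frame(chrom = "c2",
                                                    start = 0, end = 10))), 0L)
  set.seed(79)
  a <- data.frame(chrom = "c1", start = s <- sort(sample.int(1e4, 10)) * 10,
                  end = s * 10 + 300)
  b <- data.frame(chrom = "c1", start = s2 <- sort(sample.int(1e4, 10)) * 10,
                  end = s2 * 10 + 500)
  got <- overlap_selection(a, b)
  in_both <- function(x) any(a$start < x & x <= a$end) &&
    any(b$start < x & x <= b$end)
  if (nrow(got)) {
    probe <- unlist(Map(seq, got$start + 1, got$end, by = 37))
    expect_true(all(vapply(probe, in_both, TRUE)))
  }
  outside <- setdiff(seq(1, 1e5, by = 991),
                     unlist(Map(seq, got$start + 1, got$end)))
  expect_true(all(!vapply(outside, in_both, TRUE)))
})

test_that("a painted sweep is recovered by merged XP-EHH regions", {
  ## one haplotype copied over a central 500-kb stretch into 90% of popA;
  ## the significance quantile is set so the sweep dominates the
  ## significant set, as it does in a genome-scale scan
  hits <- 0
  for (seed in 1:20) {
    set.seed(100 + seed)
    n <- 600
    pos <- sort(sample.int(6e6, n))
    ctr <- 3e6
    in_sweep <- which(pos >= ctr - 2.5e5 & pos <= ctr + 2.5e5)
    hapA <- matrix(rbinom(n * 20, 1, 0.5), n, 20)
    hapB <- matrix(rbinom(n * 20, 1, 0.5), n, 20)
    donor <- hapA[, 1]
    for (h in 2:18) hapA[in_sweep, h] <- donor[in_sweep]
    geno <- toy_hap_geno(hapA, hapB, pos)
    sc <- xpehh_scan(geno, "popA", "popB", ehh_cutoff = 0.2,
                     quantile = 0.90)
    reg <- merge_regions(sc)
    if (nrow(reg) && any(reg$start <= ctr & ctr <= reg$end))
      hits <- hits + 1
  }
  expect_gte(hits, 18)
})
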