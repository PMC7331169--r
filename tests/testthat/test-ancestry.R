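# a minimal pulse_hmm-shaped object for method-level tests
fake_fit <- function(posteriors, aims, r = 1.82e-8) {
  structure(list(m = 0.3, t = 120, ci_m = c(NA, NA), ci_t = c(NA, NA),
                 loglik = 0, n_boot = 0, block_aims = 5000,
                 posteriors = posteriors, aims = aims,
                 d = NULL, samples = names(posteriors),
                 r = r, mode = "genotype", error_rate = 0, boot = NULL),
            class = "pulse_hmm")
}

test_that("AIM selection applies frequency, spacing and ordering rules", {
  tab <- make_site_table(pos = c(1000, 6000, 20000, 25000, 40000),
                         p1 = c(0.8, 0.9, 0.69, 0.9, 0.7),
                         p2 = c(0.1, 0.1, 0.2, 0.1, 0.2),
                         p3 = 0.5)
  aims <- select_aims(tab, "p1", "p2")
  ## site at 6000 dropped (within 10 kb of 1000); 20000 dropped
  ## (|diff| = 0.49 < 0.5); 25000 kept; 40000 kept
  expect_equal(aims$pos, c(1000, 25000, 40000))
  expect_equal(attr(aims, "filter_counts")[["freq_diff"]], 1L)
  expect_equal(attr(aims, "filter_counts")[["spacing"]], 1L)
  expect_error(select_aims(make_site_table(1:3 * 1e4, 0.5, 0.4, 0.5),
                           "p1", "p2"), "informative")
})

test_that("AIM selection equals an independent filter scan on simdata", {
  tab <- fix_table()
  aims <- fix_aims()
  ## brute-force oracle: frequency filter then sequential spacing scan
  pA <- tab$p_ancestralA; pB <- tab$p_ancestralB
  cand <- tab[abs(pA - pB) >= 0.5, c("chrom", "pos")]
  kept <- 0L
  for (ch in unique(cand$chrom)) {
    pos <- sort(cand$pos[cand$chrom == ch])
    last <- -Inf
    for (p in pos) if (p - last >= 1e4) { kept <- kept + 1L; last <- p }
  }
  expect_equal(nrow(aims), kept)
  expect_true(all(abs(aims$pA - aims$pB) >= 0.5))
  by_chrom <- split(aims$pos, aims$chrom)
  expect_true(all(vapply(by_chrom, function(p) all(diff(p) >= 1e4), TRUE)))
})

test_that("the forward likelihood matches a hand-computed chain product", {
  ## two markers, hand-set emissions; oracle = explicit 3-state product
  m <- 0.3; t <- 100; r <- 1e-8; d2 <- 5e4
  emis <- rbind(c(0.2, 0.5, 0.3), c(0.6, 0.3, 0.1))
  s <- exp(-r * d2 * t)
  p01 <- (1 - s) * m; p00 <- 1 - p01
  p11 <- s + (1 - s) * m; p10 <- 1 - p11
  T2 <- rbind(c(p00^2, 2 * p00 * p01, p01^2),
              c(p10 * p00, p10 * p01 + p11 * p00, p11 * p01),
              c(p10^2, 2 * p11 * p10, p11^2))
  pi0 <- c((1 - m)^2, 2 * m * (1 - m), m^2)
  expected <- log(sum((pi0 * emis[1, ]) %*% T2 * emis[2, ]))
  got <- admixscan:::.hmm_block_loglik(emis, c(-1, d2), c(0L, 0L), 1L,
                                       m, t, r)
  expect_equal(sum(got), expected, tolerance = 1e-12)
})

test_that("posterior dosage probabilities sum to one everywhere", {
  set.seed(61)
  emis <- matrix(runif(300, 0.01, 1), 100, 3)
  d <- c(-1, sample(c(1e4, 5e4), 99, TRUE))
  d[51] <- -1                                 # second chromosome
  post <- admixscan:::.hmm_posteriors(emis, d, 0.4, 80, 1.82e-8)
  expect_true(all(abs(rowSums(post) - 1) < 1e-9))
  expect_true(all(post >= 0))
})

test_that("fully diagnostic markers give posterior certainty", {
  ## pA = 0, pB = 1: the genotype equals the donor dosage exactly
  set.seed(67)
  n <- 200
  pos <- seq(1e4, by = 1e4, length.out = n)
  truth_dosage <- rep(c(0L, 2L, 1L, 0L), each = 50)
  pop <- c(S1 = "admixed")
  geno <- make_geno(rep("chr1", n), pos,
                    matrix(truth_dosage, ncol = 1), pop,
                    chrom_lengths = c(chr1 = max(pos) + 1e4))
  aims <- data.frame(chrom = "chr1", pos = pos, pA = 0, pB = 1,
                     nA = Inf, nB = Inf, flipped = FALSE)
  fit <- pulse_hmm_fit(geno, aims, samples = "S1", r = 1.82e-8,
                       mode = "genotype")
  post <- fit$posteriors$S1
  picked <- post[cbind(seq_len(n), truth_dosage + 1L)]
  expect_true(all(picked >= 0.999))
})

test_that("parameters are recovered from simulated read counts", {
  fit <- fix_fit()
  sim <- fix_sim()
  cfg <- fix_cfg()
  expect_lt(abs(fit$m - sim$truth$donor_fraction), 0.03)
  expect_lt(abs(fit$t - cfg$t) / cfg$t, 0.25)
  expect_true(fit$ci_t[1] < fit$ci_t[2])
  ## m-hat agrees with mean posterior ancestry proportion
  props <- ancestry_proportions(fit)
  expect_lt(abs(mean(props$genome) - fit$m), 0.02)
  ## likelihood invariant to chromosome processing order
  aims <- fix_aims()
  rev_ord <- order(factor(aims$chrom, levels = rev(unique(aims$chrom))),
                   aims$pos)
  fit_rev <- pulse_hmm_fit(sim$geno, aims[rev_ord, ], r = cfg$r)
  expect_equal(fit_rev$loglik, fit$loglik, tolerance = 1e-6)
})

test_that("tract calling follows run-length semantics with midpoints", {
  aims <- data.frame(chrom = "chr1", pos = c(1e4, 2e4, 3e4, 4e4, 5e4))
  all_donor <- matrix(c(rep(0.02, 5), rep(0.03, 5), rep(0.95, 5)), 5, 3,
                      dimnames = list(NULL, c("P0", "P1", "P2")))
  fit <- fake_fit(list(S1 = all_donor), aims)
  tr <- call_tracts(fit)
  expect_equal(nrow(tr), 1L)
  expect_true(tr$censored_left & tr$censored_right)
  expect_equal(tr$dosage, 2L)

  alt <- all_donor
  alt[, "P2"] <- c(0.9, 0.1, 0.9, 0.1, 0.9)
  alt[, "P0"] <- 1 - alt[, "P2"] - 0.03
  fit <- fake_fit(list(S1 = alt), aims)
  tr <- call_tracts(fit)
  expect_equal(nrow(tr), 3L)
  expect_equal(tr$start[2], (2e4 + 3e4) / 2)
  expect_equal(tr$end[2], (3e4 + 4e4) / 2)
})

test_that("tract-based dating inverts the exponential mean", {
  tr <- data.frame(start = 0, end = 708616,
                   censored_left = FALSE, censored_right = FALSE)
  tr <- tr[rep(1, 40), ]
  est <- tract_time(tr, r = 1.82e-8, m = 0.36)
  expect_equal(est$t, 1 / ((1 - 0.36) * 1.82e-8 * 708616), tolerance = 1e-12)
  expect_equal(est$t, 121.2, tolerance = 0.01)
  tr2 <- tr; tr2$end <- 2 * tr$end
  expect_equal(tract_time(tr2, 1.82e-8, 0.36)$t, est$t / 2)
  expect_error(tract_time(tr[0, ], 1.82e-8, 0.36), "no uncensored")
})

test_that("tract dating recovers the simulated pulse age", {
  sim <- fix_sim()
  cfg <- fix_cfg()
  truth_t <- tract_time(sim$truth$tracts, cfg$r, cfg$m)
  expect_lt(abs(truth_t$t - cfg$t) / cfg$t, 0.15)
  tr <- call_tracts(fix_fit())
  called_t <- tract_time(tr, cfg$r, fix_fit()$m, level = "diploid_union")
  expect_lt(abs(called_t$t - cfg$t) / cfg$t, 0.15)
})

test_that("called tracts recover the true donor segments base-by-base", {
  sim <- fix_sim()
  fit <- fix_fit()
  tr <- call_tracts(fit)
  truth <- sim$truth$tracts
  ## per-sample union of true donor tracts vs called tracts, bp overlap
  tp <- 0; truth_bp <- 0
  for (s in fit$samples) {
    tt <- truth[truth$sample == s & truth$ancestry == "donor", ]
    ct <- tr[tr$sample == s, ]
    if (nrow(tt) == 0) next
    tgr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      tt$chrom, IRanges::IRanges(floor(tt$start) + 1, ceiling(tt$end))))
    truth_bp <- truth_bp + sum(GenomicRanges::width(tgr))
    if (nrow(ct) == 0) next
    cgr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      ct$chrom, IRanges::IRanges(floor(ct$start) + 1, ceiling(ct$end))))
    tp <- tp + sum(GenomicRanges::width(GenomicRanges::intersect(tgr, cgr)))
  }
  expect_gt(tp / truth_bp, 0.80)
})

test_that("ancestry proportions are posterior mean dosage over two", {
  aims <- data.frame(chrom = "chr1", pos = c(1e4, 2e4))
  p_all <- matrix(c(0, 0, 0, 0, 1, 1), 2, 3,
                  dimnames = list(NULL, c("P0", "P1", "P2")))
  p_none <- matrix(c(1, 1, 0, 0, 0, 0), 2, 3,
                   dimnames = list(NULL, c("P0", "P1", "P2")))
  fit <- fake_fit(list(S1 = p_all, S2 = p_none), aims)
  props <- ancestry_proportions(fit)
  expect_equal(unname(props$genome), c(1, 0))
})

test_that("de-introgression masking removes tracts and reconnects flanks", {
  sites <- data.frame(chrom = "chr1", pos = 1:20 * 100)
  tr <- data.frame(chrom = "chr1", start = 450, end = 1050,
                   mean_posterior = 0.95)          # covers sites 5..10
  res <- mask_introgressed(sites, tr)
  expect_equal(length(res$retained), 14L)
  expect_equal(nrow(res$mask_bed), 1L)
  expect_equal(res$masked, 5:10)

  ## a clean gap of only 2 sites between two masked runs is absorbed
  tr2 <- rbind(tr, data.frame(chrom = "chr1", start = 1250, end = 1650,
                              mean_posterior = 0.9))
  res2 <- mask_introgressed(sites, tr2)
  expect_equal(nrow(res2$mask_bed), 1L)
  expect_equal(res2$masked, 5:16)

  ## low-posterior tracts do not mask; no tracts is the identity
  tr3 <- tr; tr3$mean_posterior <- 0.5
  expect_equal(length(mask_introgressed(sites, tr3)$retained), 20L)
  expect_equal(length(mask_introgressed(sites, tr[0, ])$retained), 20L)
})
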