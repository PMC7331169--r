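# Shared fixtures, memoized so expensive simulations run once per session.
.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

fix_cfg <- function() sim_config(
  n_chrom = 2, chrom_length = 10e6, m = 0.36, t = 120, r = 1.82e-8,
  n_per_pop = c(ancestralA = 8, ancestralB = 8, admixed = 8, outgroup = 4),
  mean_depth = 16, seed = 3L)

fix_sim <- function() memo("sim", simulate_admixed_cohort(fix_cfg()))

fix_table <- function() memo("table",
  polarize_and_filter(fix_sim()$geno, "outgroup"))

fix_aims <- function() memo("aims",
  select_aims(fix_table(), "ancestralA", "ancestralB"))

fix_fit <- function() memo("fit",
  pulse_hmm_fit(fix_sim()$geno, fix_aims(), r = fix_cfg()$r,
                n_boot = 200, block_aims = 200, seed = 7))

# Full-scale recovery fixtures (5 x 20 Mb, the generator's default
# admixture conditions), shared between acceptance blocks.
fix_big_cfg <- function() sim_config(
  n_chrom = 5, chrom_length = 20e6, m = 0.36, t = 120, r = 1.82e-8,
  seed = 1L)

fix_big_sim <- function() memo("big_sim", simulate_admixed_cohort(fix_big_cfg()))

fix_big_table <- function() memo("big_table",
  polarize_and_filter(fix_big_sim()$geno, "outgroup"))

fix_big_fit <- function() memo("big_fit", {
  aims <- select_aims(fix_big_table(), "ancestralA", "ancestralB")
  pulse_hmm_fit(fix_big_sim()$geno, aims, r = fix_big_cfg()$r,
                n_boot = 500, block_aims = 500, seed = 11)
})

# Hand-built genotype container for unit tests.
make_geno <- function(chrom, pos, gt, pop, hap = NULL, dp = NULL,
                      ad_alt = NULL, chrom_lengths = NULL) {
  samples <- names(pop)
  colnames(gt) <- samples
  if (is.null(chrom_lengths))
    chrom_lengths <- setNames(tapply(pos, chrom, max) + 1000,
                              unique(chrom))
  structure(list(
    sites = data.frame(chrom = chrom, pos = pos,
                       ref = "A", alt = "C", stringsAsFactors = FALSE),
    samples = samples, pop = pop, gt = gt, hap = hap,
    ad_ref = if (!is.null(ad_alt)) dp - ad_alt else NULL,
    ad_alt = ad_alt, dp = dp, phased = !is.null(hap),
    chrom_lengths = chrom_lengths,
    n_dropped = c(multiallelic = 0L, indel = 0L)), class = "geno_set")
}

# Two-population phased toy dataset from haplotype matrices.
toy_hap_geno <- function(hapA, hapB, pos) {
  hap <- cbind(hapA, hapB)
  nA <- ncol(hapA) / 2; nB <- ncol(hapB) / 2
  samples <- c(sprintf("A%d", seq_len(nA)), sprintf("B%d", seq_len(nB)))
  colnames(hap) <- paste0(rep(samples, each = 2), "_", 1:2)
  gt <- hap[, seq(1, ncol(hap), 2), drop = FALSE] +
        hap[, seq(2, ncol(hap), 2), drop = FALSE]
  make_geno(rep("chr1", length(pos)), pos, gt,
            setNames(rep(c("popA", "popB"), c(nA, nB)), samples),
            hap = hap, chrom_lengths = c(chr1 = max(pos) + 1000))
}

# A site table in the shape produced by polarize_and_filter, from raw
# frequency vectors (populations p1, p2, p3).
make_site_table <- function(pos, p1, p2, p3, pO = 0, chrom = "chr1") {
  n <- length(pos)
  out <- data.frame(chrom = rep(chrom, length.out = n), pos = pos,
                    p_p1 = p1, n_p1 = 16L, p_p2 = p2, n_p2 = 16L,
                    p_p3 = p3, n_p3 = 16L,
                    pO = rep(pO, length.out = n),
                    flipped = FALSE, stringsAsFactors = FALSE)
  attr(out, "pops") <- c("p1", "p2", "p3")
  class(out) <- c("polarized_sites", "data.frame")
  out
}
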