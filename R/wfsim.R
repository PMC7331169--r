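#' Simulate a constant-size Wright-Fisher cohort for LD analyses
#'
#' Runs a forward-in-time Wright-Fisher population of `ne` diploids with
#' crossovers and recurrent mutation for `n_gen` generations (default
#' `4 * ne`, enough for LD at the distances analysed to equilibrate),
#' then samples `n_sample` diploids.  At drift-recombination-mutation
#' equilibrium the expected adjusted r-squared between sites at
#' recombination fraction `c` is approximately `1 / (alpha + 4 Ne c)`,
#' which is what [ldne_trajectory()] inverts.
#'
#' @param ne true diploid effective population size.
#' @param n_sample diploids sampled at the end.
#' @param n_sites number of loci.
#' @param spacing distance between adjacent loci in bp.
#' @param r recombination rate per bp per generation.
#' @param mu per-site per-generation mutation probability.
#' @param n_gen generations simulated.
#' @param maf_min minimum minor-allele frequency retained in the output.
#' @param seed integer seed.
#' @return a `geno_set` with one chromosome (`"chr1"`), phased
#'   haplotypes, genotype dosages and no read counts.
#' @export
simulate_wf_cohort <- function(ne = 100, n_sample = 24, n_sites = 1e4,
                               spacing = 1e3, r = 1e-6, mu = 1e-4,
                               n_gen = 4 * ne, maf_min = 0.05, seed = 1L) {
  set.seed(seed)
  haps <- .wf_sim_haps(as.integer(ne), as.integer(n_sites),
                       as.integer(n_gen), r * spacing, mu)
  pick <- sample.int(ne, n_sample)
  cols <- as.vector(rbind(2 * pick - 1, 2 * pick))
  hap <- haps[, cols, drop = FALSE]
  maf <- rowMeans(hap)
  keep <- pmin(maf, 1 - maf) >= maf_min
  hap <- hap[keep, , drop = FALSE]
  samples <- sprintf("WF%02d", seq_len(n_sample))
  colnames(hap) <- paste0(rep(samples, each = 2), "_", 1:2)
  gt <- hap[, seq(1, ncol(hap), 2), drop = FALSE] +
        hap[, seq(2, ncol(hap), 2), drop = FALSE]
  colnames(gt) <- samples
  pos <- which(keep) * spacing
  structure(list(
    sites = data.frame(chrom = "chr1", pos = as.integer(pos),
                       ref = "A", alt = "C", stringsAsFactors = FALSE),
    samples = samples, pop = setNames(rep("wf", n_sample), samples),
    gt = gt, hap = hap, ad_ref = NULL, ad_alt = NULL, dp = NULL,
    phased = TRUE,
    chrom_lengths = c(chr1 = n_sites * spacing),
    n_dropped = c(multiallelic = 0L, indel = 0L)), class = "geno_set")
}
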