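#' Configuration for the synthetic admixed-cohort simulator
#'
#' Bundles and validates all parameters of the generative model: two
#' diverged ancestral panels drifted from a shared ancestral frequency
#' (Balding-Nichols model), an outgroup fixed for the ancestral allele at
#' most sites, and an admixed population created by a single pulse of
#' donor ancestry `m` at `t` generations before present.  Ancestry along
#' each admixed haplotype is a Markov chain: ancestry switches occur at
#' rate `r * t` per bp and each switch redraws donor ancestry with
#' probability `m`, so donor tract lengths are exponential with rate
#' `(1 - m) * r * t`.
#'
#' @param n_chrom number of autosomes to simulate.
#' @param chrom_length autosome length in bp.
#' @param n_per_pop named integer vector of diploid sample sizes; names
#'   must include `ancestralA`, `ancestralB`, `admixed`, `outgroup`.
#' @param divergence length-2 numeric, Balding-Nichols drift parameter F
#'   in `[0, 1)` for panels A and B.
#' @param m donor (panel B) admixture proportion in `[0, 1]`.
#' @param t pulse age in generations (>= 1).
#' @param r recombination rate per bp per generation.
#' @param mean_depth mean sequencing depth (reads/site).
#' @param error_rate per-read miscall probability.
#' @param site_spacing distance between simulated variant sites in bp.
#' @param x_chrom if `TRUE`, an extra scaffold `"chrX"` is simulated with
#'   donor proportion `m_x` (used for X-versus-autosome contrasts).
#' @param m_x donor proportion on the X scaffold (defaults to `m`).
#' @param par_length length in bp of a terminal pseudo-autosomal region
#'   restored to full male depth in [simulate_depth_profiles()].
#' @param seed integer seed; a fixed seed makes all simulator outputs
#'   byte-identical across runs.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_chrom = 5, chrom_length = 20e6,
                       n_per_pop = c(ancestralA = 8, ancestralB = 8,
                                     admixed = 8, outgroup = 4),
                       divergence = c(0.5, 0.5),
                       m = 0.36, t = 120, r = 1.82e-8,
                       mean_depth = 16, error_rate = 0.01,
                       site_spacing = 1000,
                       x_chrom = FALSE, m_x = m, par_length = 0,
                       seed = 1L) {
  stopifnot(n_chrom >= 1, chrom_length > 0,
            all(c("ancestralA", "ancestralB", "admixed", "outgroup") %in%
                  names(n_per_pop)),
            all(n_per_pop >= 1),
            length(divergence) == 2, all(divergence >= 0), all(divergence < 1),
            m >= 0, m <= 1, t >= 1, r > 0,
            mean_depth > 0, error_rate >= 0, error_rate < 0.5,
            site_spacing >= 1, m_x >= 0, m_x <= 1, par_length >= 0)
  if (chrom_length * r * t >= 1e3)
    stop("chrom_length * r * t must be < 1000 (tract resolution sanity)")
  cfg <- list(n_chrom = as.integer(n_chrom), chrom_length = chrom_length,
              n_per_pop = n_per_pop, divergence = divergence,
              m = m, t = t, r = r, mean_depth = mean_depth,
              error_rate = error_rate, site_spacing = site_spacing,
              x_chrom = isTRUE(x_chrom), m_x = m_x, par_length = par_length,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_chrom, "autosome(s) x",
      format(x$chrom_length, big.mark = ","), "bp",
      if (x$x_chrom) "+ chrX" else "", "\n")
  cat("  pulse: m =", x$m, " t =", x$t, "generations, r =", x$r, "/bp\n")
  cat("  panels: F =", paste(x$divergence, collapse = "/"),
      " depth =", x$mean_depth, " error =", x$error_rate, "\n")
  invisible(x)
}

sim_chrom_names <- function(cfg) {
  ch <- paste0("chr", seq_len(cfg$n_chrom))
  if (cfg$x_chrom) ch <- c(ch, "chrX")
  ch
}

sim_chrom_lengths <- function(cfg) {
  setNames(rep(cfg$chrom_length, length(sim_chrom_names(cfg))),
           sim_chrom_names(cfg))
}

#' Simulate allele frequencies for the ancestral panels and outgroup
#'
#' Draws, at every site, a shared ancestral derived-allele frequency
#' `p ~ Uniform(0.05, 0.95)` and Balding-Nichols panel frequencies
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` for each ancestral panel
#' (`F = 0` returns `p` itself: no drift).  The outgroup is fixed for the
#' ancestral allele (derived frequency 0) at 95% of sites; the remainder
#' are polymorphic or fixed derived so that downstream polarization
#' filters are exercised.  A random 10% of sites encode the derived
#' allele as the VCF REF allele to exercise polarity flips.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns `chrom`, `pos` (1-based), `p_shared`,
#'   `pA`, `pB`, `pO` (derived-allele frequencies) and `ref_is_derived`;
#'   attribute `aim_fraction` holds the realized fraction of sites with
#'   `|pA - pB| >= 0.5`.
#' @export
simulate_panels <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chroms <- sim_chrom_names(cfg)
  per_chrom <- floor(cfg$chrom_length / cfg$site_spacing)
  pos1 <- as.integer(seq_len(per_chrom) * cfg$site_spacing -
                       cfg$site_spacing %/% 2)
  n <- per_chrom * length(chroms)
  p <- runif(n, 0.05, 0.95)
  bn_draw <- function(p, F) {
    if (F == 0) return(p)
    rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  }
  pA <- bn_draw(p, cfg$divergence[1])
  pB <- bn_draw(p, cfg$divergence[2])
  u <- runif(n)
  pO <- numeric(n)                       # fixed ancestral at 95% of sites,
  pO[u >= 0.95] <- runif(sum(u >= 0.95), 0.1, 0.9)   # else polymorphic
  out <- data.frame(chrom = rep(chroms, each = per_chrom),
                    pos = rep(pos1, length(chroms)),
                    p_shared = p, pA = pA, pB = pB, pO = pO,
                    ref_is_derived = runif(n) < 0.10,
                    stringsAsFactors = FALSE)
  attr(out, "aim_fraction") <- mean(abs(pA - pB) >= 0.5)
  attr(out, "config") <- cfg
  out
}

## breakpoint process for one haplotype on one chromosome: switch points at
## rate r*t per bp, ancestry redrawn Bernoulli(m) at each; adjacent segments
## of equal ancestry are merged so tracts are maximal and tile [0, L).
sim_hap_tracts <- function(L, m, t, r) {
  n_bp <- rpois(1, L * r * t)
  bp <- sort(runif(n_bp, 0, L))
  anc <- rbinom(n_bp + 1, 1, m)          # 0 = native (A), 1 = donor (B)
  keep <- c(TRUE, diff(anc) != 0)
  starts <- c(0, bp)[keep]
  data.frame(start = starts,
             end = c(starts[-1], L),
             ancestry = anc[keep])
}

#' Simulate an admixed cohort with read counts and ground-truth tracts
#'
#' Generates diploid genotypes, phased haplotypes and per-site read counts
#' for the two ancestral panels, the outgroup and the admixed population.
#' Each admixed haplotype is an independent ancestry chain along every
#' chromosome (switch rate `r * t` per bp, donor redraw probability `m`);
#' alleles are drawn from the local ancestry's panel frequency.  Read
#' counts are `depth ~ Poisson(mean_depth)` with alt reads
#' `Binomial(depth, dosage/2 adjusted by error_rate)`.
#'
#' @param cfg a [sim_config()].
#' @param panels output of [simulate_panels()] (defaults to generating one
#'   from `cfg`).
#' @return a list with elements `geno` (a `geno_set`: sites, sample
#'   metadata, alt-allele dosage matrix `gt`, phased haplotype matrix
#'   `hap`, read-count matrices `ad_ref`/`ad_alt`/`dp`) and `truth` (class
#'   `sim_truth`: ground-truth tracts per admixed haplotype in bp
#'   (half-open, `ancestry` is `"native"`/`"donor"`), the realized donor
#'   genome fraction, and the panel frequency table).
#' @export
simulate_admixed_cohort <- function(cfg, panels = simulate_panels(cfg)) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  chroms <- sim_chrom_names(cfg)
  n <- cfg$n_per_pop
  samples <- c(paste0("A", seq_len(n[["ancestralA"]])),
               paste0("B", seq_len(n[["ancestralB"]])),
               paste0("ADM", seq_len(n[["admixed"]])),
               paste0("OUT", seq_len(n[["outgroup"]])))
  pop <- setNames(rep(c("ancestralA", "ancestralB", "admixed", "outgroup"),
                      n[c("ancestralA", "ancestralB", "admixed", "outgroup")]),
                  samples)
  n_sites <- nrow(panels)
  n_hap <- 2L * length(samples)
  hap_der <- matrix(0L, n_sites, n_hap)   # derived-allele indicator
  hap_sample <- rep(samples, each = 2)
  freq_of <- c(ancestralA = "pA", ancestralB = "pB", outgroup = "pO")

  ## panel and outgroup haplotypes: iid draws from the panel frequency
  for (p_name in names(freq_of)) {
    idx <- which(pop[hap_sample] == p_name)
    f <- panels[[freq_of[[p_name]]]]
    for (j in idx) hap_der[, j] <- rbinom(n_sites, 1L, f)
  }

  ## admixed haplotypes: ancestry tracts, then alleles from the local panel
  m_chrom <- setNames(rep(cfg$m, length(chroms)), chroms)
  if (cfg$x_chrom) m_chrom["chrX"] <- cfg$m_x
  adm_idx <- which(pop[hap_sample] == "admixed")
  tract_list <- list()
  for (j in adm_idx) {
    smp <- hap_sample[j]
    hap_id <- ((j - 1L) %% 2L) + 1L
    for (ch in chroms) {
      tr <- sim_hap_tracts(cfg$chrom_length, m_chrom[[ch]], cfg$t, cfg$r)
      sel <- panels$chrom == ch
      site_pos0 <- panels$pos[sel] - 1
      anc_at <- tr$ancestry[findInterval(site_pos0, tr$start)]
      f <- ifelse(anc_at == 1L, panels$pB[sel], panels$pA[sel])
      hap_der[sel, j] <- rbinom(sum(sel), 1L, f)
      tract_list[[length(tract_list) + 1L]] <-
        data.frame(chrom = ch, start = tr$start, end = tr$end,
                   sample = smp, hap = hap_id,
                   ancestry = c("native", "donor")[tr$ancestry + 1L],
                   stringsAsFactors = FALSE)
    }
  }
  tracts <- do.call(rbind, tract_list)

  ## REF/ALT encoding: at ref_is_derived sites the ALT allele is ancestral
  flip <- panels$ref_is_derived
  hap_alt <- hap_der
  hap_alt[flip, ] <- 1L - hap_alt[flip, ]
  gt <- hap_alt[, seq(1, n_hap, 2), drop = FALSE] +
        hap_alt[, seq(2, n_hap, 2), drop = FALSE]
  colnames(gt) <- samples

  dp <- matrix(rpois(n_sites * length(samples), cfg$mean_depth),
               n_sites, length(samples), dimnames = list(NULL, samples))
  e <- cfg$error_rate
  f_alt <- (gt / 2) * (1 - e) + (1 - gt / 2) * e
  ad_alt <- matrix(rbinom(length(dp), as.vector(dp), as.vector(f_alt)),
                   n_sites, length(samples), dimnames = list(NULL, samples))
  ad_ref <- dp - ad_alt

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")

  geno <- structure(list(
    sites = data.frame(chrom = panels$chrom, pos = panels$pos,
                       ref = ref, alt = unname(alt),
                       stringsAsFactors = FALSE),
    samples = samples, pop = pop, gt = gt,
    hap = `colnames<-`(hap_alt, paste0(hap_sample, "_", rep(1:2,
                                       length(samples)))),
    ad_ref = ad_ref, ad_alt = ad_alt, dp = dp,
    phased = TRUE,
    chrom_lengths = sim_chrom_lengths(cfg),
    n_dropped = c(multiallelic = 0L, indel = 0L)), class = "geno_set")

  donor_bp <- sum(tracts$end[tracts$ancestry == "donor"] -
                    tracts$start[tracts$ancestry == "donor"])
  total_bp <- sum(tracts$end - tracts$start)
  truth <- structure(list(tracts = tracts, params = cfg,
                          panel_freqs = panels,
                          donor_fraction = donor_bp / total_bp),
                     class = "sim_truth")
  list(geno = geno, truth = truth)
}

#' @export
print.geno_set <- function(x, ...) {
  cat("geno_set:", nrow(x$sites), "sites x", length(x$samples), "samples (",
      paste(sprintf("%s=%d", names(table(x$pop)), table(x$pop)),
            collapse = ", "), ")\n")
  invisible(x)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("sim_truth:", nrow(x$tracts), "tracts; realized donor fraction",
      round(x$donor_fraction, 4), "(m =", x$params$m, ")\n")
  invisible(x)
}

#' Simulate per-scaffold, per-window sequencing depth profiles
#'
#' Emulates the depth summaries used to identify X-linked scaffolds:
#' males carry one X, so designated X scaffolds have male mean depth at
#' half the autosomal level, except within a terminal pseudo-autosomal
#' region (PAR) restored to full depth.  Window depths are Poisson noise
#' around the expected per-window read count.
#'
#' @param cfg a [sim_config()] (with `x_chrom = TRUE` if an X scaffold is
#'   wanted; `par_length` > 0 adds a terminal PAR on the X).
#' @param sex_labels named character vector `"M"`/`"F"` per sample; at
#'   least one of each sex is required.
#' @param window_size depth summarisation window in bp.
#' @return data.frame with columns `scaffold`, `start`, `end` (0-based
#'   half-open), `sample`, `sex`, `depth` (mean depth in the window).
#' @export
simulate_depth_profiles <- function(cfg, sex_labels, window_size = 1e6) {
  stopifnot(inherits(cfg, "sim_config"))
  sex_labels <- toupper(sex_labels)
  if (!any(sex_labels == "M") || !any(sex_labels == "F"))
    stop("need at least one male and one female (sex ratio undefined otherwise)")
  set.seed(cfg$seed + 2L)
  chroms <- sim_chrom_names(cfg)
  out <- list()
  for (ch in chroms) {
    w <- make_windows(setNames(cfg$chrom_length, ch), window_size)
    for (s in names(sex_labels)) {
      expected <- rep(cfg$mean_depth, nrow(w))
      if (ch == "chrX" && sex_labels[[s]] == "M") {
        in_par <- cfg$par_length > 0 &
          (w$end <= cfg$par_length | w$start >= cfg$chrom_length - cfg$par_length)
        expected <- ifelse(in_par, cfg$mean_depth, cfg$mean_depth / 2)
      }
      ## mean of n_reads ~ Poisson over the window, scaled back to depth
      nwin <- pmax(w$end - w$start, 1)
      depth <- rpois(nrow(w), expected * nwin / 100) / (nwin / 100)
      out[[length(out) + 1L]] <-
        data.frame(scaffold = ch, start = w$start, end = w$end,
                   sample = s, sex = sex_labels[[s]], depth = depth,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write ground-truth ancestry tracts as BED
#'
#' @param truth a `sim_truth` from [simulate_admixed_cohort()].
#' @param path output path; BED columns chrom, start, end, name
#'   (`sample:hap:ancestry`), 0-based half-open.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  tr <- truth$tracts
  bed <- data.frame(tr$chrom, as.integer(floor(tr$start)),
                    as.integer(ceiling(tr$end)),
                    paste(tr$sample, tr$hap, tr$ancestry, sep = ":"))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a simulator configuration as a plain key-value file
#'
#' @param cfg a [sim_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  flat <- c(n_chrom = cfg$n_chrom, chrom_length = cfg$chrom_length,
            setNames(cfg$n_per_pop, paste0("n_", names(cfg$n_per_pop))),
            F_A = cfg$divergence[1], F_B = cfg$divergence[2],
            m = cfg$m, t = cfg$t, r = cfg$r,
            mean_depth = cfg$mean_depth, error_rate = cfg$error_rate,
            site_spacing = cfg$site_spacing, x_chrom = as.integer(cfg$x_chrom),
            m_x = cfg$m_x, par_length = cfg$par_length, seed = cfg$seed)
  writeLines(paste(names(flat), flat, sep = "\t"), path)
  invisible(path)
}
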