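#' Select ancestry-informative markers (AIMs)
#'
#' Filters a polarized site table to sites whose derived-allele
#' frequencies differ by at least `min_diff` between the two ancestral
#' panels, then enforces a minimum spacing greedily left-to-right along
#' each chromosome (the first qualifying site is kept, subsequent sites
#' closer than `min_spacing` are dropped).  The depth rule is applied
#' upstream by [polarize_and_filter()]; the counts removed by each
#' filter are recorded.
#'
#' @param table a `polarized_sites` data.frame.
#' @param panelA,panelB population labels of the two ancestral panels.
#' @param min_diff minimum absolute frequency difference (default 0.5).
#' @param min_spacing minimum bp between successive AIMs (default 10 kb).
#' @return data.frame `chrom`, `pos`, `pA`, `pB` of retained AIMs;
#'   attribute `filter_counts` tallies removals.
#' @export
select_aims <- function(table, panelA, panelB, min_diff = 0.5,
                        min_spacing = 1e4) {
  pA <- table[[paste0("p_", panelA)]]
  pB <- table[[paste0("p_", panelB)]]
  if (is.null(pA) || is.null(pB)) stop("panel populations not in table")
  diff_ok <- !is.na(pA) & !is.na(pB) & abs(pA - pB) >= min_diff - 1e-9
  cand <- data.frame(chrom = table$chrom, pos = table$pos,
                     pA = pA, pB = pB,
                     nA = table[[paste0("n_", panelA)]] %||% rep(Inf, nrow(table)),
                     nB = table[[paste0("n_", panelB)]] %||% rep(Inf, nrow(table)),
                     flipped = table$flipped %||% rep(FALSE, nrow(table)),
                     stringsAsFactors = FALSE)[diff_ok, , drop = FALSE]
  cand <- cand[order(cand$chrom, cand$pos), , drop = FALSE]
  keep <- logical(nrow(cand))
  last_chrom <- ""; last_pos <- -Inf
  for (i in seq_len(nrow(cand))) {
    if (cand$chrom[i] != last_chrom || cand$pos[i] - last_pos >= min_spacing) {
      keep[i] <- TRUE
      last_chrom <- cand$chrom[i]; last_pos <- cand$pos[i]
    }
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0)
    stop("no ancestry-informative markers retained: ",
         "panel divergence too low for min_diff = ", min_diff)
  attr(out, "filter_counts") <- c(freq_diff = sum(!diff_ok),
                                  spacing = sum(!keep))
  out
}

## Genotype-dosage distribution given ancestry dosage k (donor copies),
## panel frequencies pA (native) and pB (donor): rows k = 0,1,2 ->
## P(genotype = 0,1,2 derived alleles).
geno_given_dosage <- function(pA, pB) {
  list(
    k0 = cbind((1 - pA)^2, 2 * pA * (1 - pA), pA^2),
    k1 = cbind((1 - pA) * (1 - pB), pA * (1 - pB) + (1 - pA) * pB, pA * pB),
    k2 = cbind((1 - pB)^2, 2 * pB * (1 - pB), pB^2))
}

## Emission matrix (n_aims x 3) for one sample.
## reads mode: P(alt reads | depth, dosage) marginalized over the genotype;
## genotype mode: P(observed genotype | dosage).  Missing observations
## emit 1 in every state.
aim_emissions <- function(pA, pB, obs, mode, error_rate) {
  G <- geno_given_dosage(pA, pB)
  n <- length(pA)
  emis <- matrix(1, n, 3)
  if (mode == "reads") {
    a <- obs$alt; dp <- obs$dp
    ok <- !is.na(a) & !is.na(dp) & dp > 0
    f <- c(error_rate, 0.5, 1 - error_rate)   # alt-read fraction per genotype
    like_g <- vapply(1:3, function(j)
      ifelse(ok, stats::dbinom(a, dp, f[j]), 1), numeric(n))
    for (k in 1:3) {
      v <- rowSums(G[[k]] * like_g)
      emis[, k] <- ifelse(ok, v, 1)
    }
  } else {
    g <- obs$gt
    ok <- !is.na(g)
    idx <- cbind(seq_len(n), g + 1L)
    for (k in 1:3) {
      v <- rep(1, n)
      v[ok] <- G[[k]][idx[ok, , drop = FALSE]]
      emis[, k] <- v
    }
  }
  emis
}

## distance to previous AIM; negative at each chromosome start (chain reset)
aim_distances <- function(aims) {
  d <- c(-1, diff(aims$pos))
  d[c(TRUE, aims$chrom[-1] != aims$chrom[-nrow(aims)])] <- -1
  d
}

#' Fit the single-pulse local-ancestry HMM
#'
#' Jointly estimates the donor admixture proportion `m` and the pulse age
#' `t` (generations) from genotype or read-count observations at
#' ancestry-informative markers, and decodes per-marker donor-dosage
#' posteriors.  The model: each haploid ancestry chain persists between
#' markers `d` bp apart with probability `exp(-r d t)` and otherwise
#' redraws donor ancestry with probability `m`; the diploid dosage chain
#' (states 0/1/2 donor copies) is the lumped product of two independent
#' haploid chains.  `t` is profiled on a log-spaced grid with
#' golden-section refinement, maximizing over `m` at each `t`.
#' Confidence intervals come from resampling contiguous blocks of
#' markers (percentile method).
#'
#' @param geno a `geno_set` holding the admixed samples' observations.
#' @param aims AIM panel from [select_aims()].
#' @param samples character vector of sample names to decode (default:
#'   samples whose population is `"admixed"`).
#' @param r recombination rate per bp per generation.
#' @param mode `"reads"` (default; uses AD/DP) or `"genotype"`.
#' @param error_rate per-read miscall probability used by the read-count
#'   emissions.
#' @param t_range search range for `t` in generations.
#' @param n_t_grid number of log-spaced grid points for the profile.
#' @param n_boot bootstrap replicates for CIs (0 disables).
#' @param block_aims markers per bootstrap block (default 5000).
#' @param seed optional seed for the bootstrap.
#' @return object of class `pulse_hmm` with elements `m`, `t`, `ci_m`,
#'   `ci_t`, `loglik`, `posteriors` (per-sample n_aims x 3 matrices),
#'   `aims`, `boot` (data.frame of bootstrap draws), `samples`, `r`,
#'   `mode`.
#' @export
pulse_hmm_fit <- function(geno, aims, samples = NULL, r,
                          mode = c("reads", "genotype"), error_rate = 0.01,
                          t_range = c(1, 2000), n_t_grid = 25,
                          n_boot = 0, block_aims = 5000, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(geno, "geno_set"), r > 0)
  if (is.null(samples)) samples <- names(geno$pop)[geno$pop == "admixed"]
  if (!length(samples)) stop("no samples to decode")
  key <- paste(geno$sites$chrom, geno$sites$pos)
  site_idx <- match(paste(aims$chrom, aims$pos), key)
  if (anyNA(site_idx)) stop("some AIMs are absent from the genotype set")
  if (mode == "reads" && (is.null(geno$ad_alt) || is.null(geno$dp)))
    stop("read-count mode requires AD and DP in the genotype set")
  flipped <- aims$flipped %||% rep(FALSE, nrow(aims))
  ## Jeffreys-shrunk panel frequencies guard against overconfident
  ## emissions when panel frequencies are estimated from few alleles
  shrink <- function(p, n) ifelse(is.finite(n) & n > 0,
                                  (p * n + 0.5) / (n + 1), p)
  pA <- shrink(aims$pA, aims$nA %||% rep(Inf, nrow(aims)))
  pB <- shrink(aims$pB, aims$nB %||% rep(Inf, nrow(aims)))
  emis <- lapply(samples, function(s) {
    obs <- if (mode == "reads")
      list(alt = ifelse(flipped, geno$ad_ref[site_idx, s],
                        geno$ad_alt[site_idx, s]),
           dp = geno$dp[site_idx, s])
    else {
      g <- geno$gt[site_idx, s]
      list(gt = ifelse(flipped, 2L - g, g))
    }
    aim_emissions(pA, pB, obs, mode, error_rate)
  })
  names(emis) <- samples
  d <- aim_distances(aims)
  one_block <- rep(0L, nrow(aims))

  loglik_mt <- function(m, t)
    sum(vapply(emis, function(e)
      sum(.hmm_block_loglik(e, d, one_block, 1L, m, t, r)), 0))
  profile_t <- function(t) {
    o <- optimize(function(m) loglik_mt(m, t), c(1e-3, 1 - 1e-3),
                  maximum = TRUE, tol = 1e-3)
    list(m = o$maximum, ll = o$objective)
  }
  t_grid <- exp(seq(log(t_range[1]), log(t_range[2]), length.out = n_t_grid))
  prof <- lapply(t_grid, profile_t)
  ll_grid <- vapply(prof, `[[`, 0, "ll")
  i_best <- which.max(ll_grid)
  if (i_best == 1 || i_best == n_t_grid)
    warning("t estimate at the boundary of t_range")
  lo <- t_grid[max(i_best - 1, 1)]
  hi <- t_grid[min(i_best + 1, n_t_grid)]
  o_t <- optimize(function(t) profile_t(t)$ll, c(lo, hi), maximum = TRUE,
                  tol = max(0.01, 1e-4 * t_grid[i_best]))
  t_hat <- o_t$maximum
  m_hat <- profile_t(t_hat)$m
  ll_hat <- o_t$objective

  ci_m <- ci_t <- c(NA_real_, NA_real_)
  boot <- NULL
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    n_aims <- nrow(aims)
    block <- as.integer((seq_len(n_aims) - 1) %/% block_aims)
    B <- max(block) + 1L
    if (B < 2) {
      warning("fewer than 2 bootstrap blocks; reduce block_aims. CIs skipped")
    } else {
      bt <- exp(seq(log(max(t_range[1], t_hat / 3)),
                    log(min(t_range[2], t_hat * 3)), length.out = 41))
      bm <- seq(max(1e-3, m_hat - 0.12), min(1 - 1e-3, m_hat + 0.12),
                length.out = 25)
      grid <- expand.grid(m = bm, t = bt)
      bl_ll <- matrix(0, B, nrow(grid))
      for (g in seq_len(nrow(grid))) {
        for (e in emis)
          bl_ll[, g] <- bl_ll[, g] +
            .hmm_block_loglik(e, d, block, B, grid$m[g], grid$t[g], r)
      }
      counts <- matrix(0, B, n_boot)
      for (b in seq_len(n_boot)) {
        i <- sample.int(B, B, replace = TRUE)
        counts[, b] <- tabulate(i, B)
      }
      rep_ll <- crossprod(bl_ll, counts)          # grid x reps
      best <- apply(rep_ll, 2, which.max)
      boot <- data.frame(m = grid$m[best], t = grid$t[best])
      ci_m <- unname(quantile(boot$m, c(0.025, 0.975)))
      ci_t <- unname(quantile(boot$t, c(0.025, 0.975)))
    }
  }
  posteriors <- lapply(emis, function(e) {
    p <- .hmm_posteriors(e, d, m_hat, t_hat, r)
    colnames(p) <- c("P0", "P1", "P2")
    p
  })
  structure(list(m = m_hat, t = t_hat, ci_m = ci_m, ci_t = ci_t,
                 loglik = ll_hat, n_boot = n_boot, block_aims = block_aims,
                 posteriors = posteriors, aims = aims, d = d,
                 samples = samples, r = r, mode = mode,
                 error_rate = error_rate, boot = boot),
            class = "pulse_hmm")
}

#' @export
print.pulse_hmm <- function(x, ...) {
  cat("Single-pulse ancestry HMM fit\n")
  cat(sprintf("  m = %.4f", x$m))
  if (!anyNA(x$ci_m)) cat(sprintf(" (95%% CI %.4f-%.4f)", x$ci_m[1], x$ci_m[2]))
  cat(sprintf("\n  t = %.2f generations", x$t))
  if (!anyNA(x$ci_t)) cat(sprintf(" (95%% CI %.2f-%.2f)", x$ci_t[1], x$ci_t[2]))
  cat(sprintf("\n  %d AIMs, %d samples, log-likelihood %.2f\n",
              nrow(x$aims), length(x$samples), x$loglik))
  invisible(x)
}

#' @export
summary.pulse_hmm <- function(object, ...) {
  props <- ancestry_proportions(object)
  out <- list(m = object$m, t = object$t, ci_m = object$ci_m,
              ci_t = object$ci_t, loglik = object$loglik,
              n_aims = nrow(object$aims), samples = object$samples,
              donor_fraction = props$genome)
  class(out) <- "summary.pulse_hmm"
  out
}

#' @export
print.summary.pulse_hmm <- function(x, ...) {
  cat(sprintf("m = %.4f, t = %.2f generations (loglik %.2f, %d AIMs)\n",
              x$m, x$t, x$loglik, x$n_aims))
  cat("Per-sample donor fractions:\n")
  print(round(x$donor_fraction, 4))
  invisible(x)
}

#' @export
coef.pulse_hmm <- function(object, ...) c(m = object$m, t = object$t)

#' @export
logLik.pulse_hmm <- function(object, ...) {
  structure(object$loglik, df = 2, class = "logLik")
}

#' Call donor-ancestry tracts from HMM posteriors
#'
#' Finds, per sample and chromosome, maximal runs of markers whose donor
#' posterior (probability of carrying at least one donor copy) meets the
#' threshold.  Tract boundaries are placed at the midpoint between the
#' flanking markers; runs touching the first or last marker of a
#' chromosome are flagged censored.
#'
#' @param fit a `pulse_hmm` fit.
#' @param threshold posterior threshold (default 0.8).
#' @return data.frame `chrom`, `start`, `end` (bp, half-open), `sample`,
#'   `dosage` (argmax donor-copy class over the run), `mean_posterior`,
#'   `n_aims`, `censored_left`, `censored_right`.
#' @export
call_tracts <- function(fit, threshold = 0.8) {
  stopifnot(inherits(fit, "pulse_hmm"))
  aims <- fit$aims
  out <- list()
  for (s in fit$samples) {
    post <- fit$posteriors[[s]]
    q <- post[, "P1"] + post[, "P2"]
    for (ch in unique(aims$chrom)) {
      ci <- which(aims$chrom == ch)
      pos <- aims$pos[ci]
      qc <- q[ci]
      rl <- rle(qc >= threshold)
      ends <- cumsum(rl$lengths)
      starts <- ends - rl$lengths + 1
      for (k in which(rl$values)) {
        i <- starts[k]; j <- ends[k]
        cl <- i == 1; cr <- j == length(ci)
        start_bp <- if (cl) pos[i] - 1 else (pos[i - 1] + pos[i]) / 2
        end_bp <- if (cr) pos[j] else (pos[j] + pos[j + 1]) / 2
        sub <- post[ci[i:j], , drop = FALSE]
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = start_bp, end = end_bp, sample = s,
          dosage = which.max(colSums(sub[, 2:3, drop = FALSE])),
          mean_posterior = mean(qc[i:j]), n_aims = j - i + 1L,
          censored_left = cl, censored_right = cr,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), sample = character(),
                      dosage = integer(), mean_posterior = numeric(),
                      n_aims = integer(), censored_left = logical(),
                      censored_right = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Date the admixture pulse from tract lengths
#'
#' Method-of-moments inversion of the exponential tract-length model.
#' For haploid tracts (e.g. simulator truth tracts) the donor tract
#' length is exponential with rate `(1 - m) r t`, so
#' `t = 1 / ((1 - m) r mean_length)`.  Tracts called from diploid dosage
#' posteriors are unions of two haploid chains; their mean length is
#' `(2 - m) / (2 (1 - m)^2 r t)` (the busy period of the lumped on/off
#' chain), inverted by `level = "diploid_union"`.  Chromosome-end
#' truncated (censored) tracts are excluded.
#'
#' @param tracts data.frame with `start`, `end` and optionally
#'   `censored_left`/`censored_right` (from [call_tracts()]) or
#'   `ancestry` (truth tracts; only `"donor"` rows are used).
#' @param r recombination rate per bp per generation.
#' @param m donor admixture proportion.
#' @param level `"haploid"` or `"diploid_union"`.
#' @return list with `t`, `mean_length`, `n_tracts`.
#' @export
tract_time <- function(tracts, r, m, level = c("haploid", "diploid_union")) {
  level <- match.arg(level)
  if ("ancestry" %in% names(tracts))
    tracts <- tracts[tracts$ancestry == "donor", , drop = FALSE]
  if ("censored_left" %in% names(tracts))
    tracts <- tracts[!tracts$censored_left & !tracts$censored_right, ,
                     drop = FALSE]
  if (nrow(tracts) == 0) stop("no uncensored donor tracts to date")
  if (nrow(tracts) < 30)
    warning("fewer than 30 donor tracts; estimate will be noisy")
  L <- mean(tracts$end - tracts$start)
  t_hat <- if (level == "haploid") 1 / ((1 - m) * r * L)
           else (2 - m) / (2 * (1 - m)^2 * r * L)
  list(t = t_hat, mean_length = L, n_tracts = nrow(tracts))
}

#' Per-sample donor-ancestry proportions
#'
#' Mean posterior donor dosage over markers, divided by 2: the fraction
#' of each sample's genome inferred to be donor-derived, genome-wide and
#' per chromosome.
#'
#' @param fit a `pulse_hmm` fit.
#' @return list with `genome` (named vector per sample) and `per_chrom`
#'   (chromosome x sample matrix).
#' @export
ancestry_proportions <- function(fit) {
  stopifnot(inherits(fit, "pulse_hmm"))
  dose <- vapply(fit$samples, function(s) {
    p <- fit$posteriors[[s]]
    (p[, "P1"] + 2 * p[, "P2"]) / 2
  }, numeric(nrow(fit$aims)))
  genome <- colMeans(dose)
  per_chrom <- apply(dose, 2, function(v) tapply(v, fit$aims$chrom, mean))
  list(genome = genome, per_chrom = per_chrom)
}

#' Mask introgressed regions from a site table
#'
#' Removes sites inside donor tracts whose mean posterior reaches the
#' threshold (union over samples), then reconnects flanking regions only
#' across gaps supported by at least `reconnect_min` contiguous
#' non-introgressed sites: shorter clean gaps between two masked runs
#' are absorbed into a single mask interval.
#'
#' @param sites data.frame with `chrom` and `pos` (1-based).
#' @param tracts tract calls from [call_tracts()].
#' @param threshold minimum tract mean posterior for masking.
#' @param reconnect_min minimum run of clean sites that keeps a gap open.
#' @return list with `retained` (row indices of `sites` kept), `masked`
#'   (indices removed) and `mask_bed` (data.frame `chrom`, `start`,
#'   `end`, 0-based half-open, one row per merged mask interval).
#' @export
mask_introgressed <- function(sites, tracts, threshold = 0.8,
                              reconnect_min = 3) {
  n <- nrow(sites)
  masked <- rep(FALSE, n)
  qual <- tracts[is.na(tracts$mean_posterior) |
                   tracts$mean_posterior >= threshold, , drop = FALSE]
  if (nrow(qual) > 0) {
    gr <- GenomicRanges::reduce(to_granges(qual))
    sgr <- GenomicRanges::GRanges(sites$chrom,
                                  IRanges::IRanges(sites$pos, sites$pos))
    hits <- GenomicRanges::findOverlaps(sgr, gr)
    masked[S4Vectors::queryHits(hits)] <- TRUE
  }
  ## reconnect rule: clean runs shorter than reconnect_min between two
  ## masked runs are merged into the mask
  for (ch in unique(sites$chrom)) {
    ci <- which(sites$chrom == ch)
    rl <- rle(masked[ci])
    if (length(rl$lengths) < 3) next
    for (k in seq(2, length(rl$lengths) - 1)) {
      if (!rl$values[k] && rl$lengths[k] < reconnect_min &&
          rl$values[k - 1] && rl$values[k + 1])
        rl$values[k] <- TRUE
    }
    masked[ci] <- inverse.rle(rl)
  }
  mask_bed <- data.frame(chrom = character(), start = numeric(),
                         end = numeric())
  for (ch in unique(sites$chrom)) {
    ci <- which(sites$chrom == ch)
    rl <- rle(masked[ci])
    ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1
    for (k in which(rl$values))
      mask_bed <- rbind(mask_bed, data.frame(
        chrom = ch, start = sites$pos[ci[starts[k]]] - 1,
        end = sites$pos[ci[ends[k]]]))
  }
  list(retained = which(!masked), masked = which(masked),
       mask_bed = mask_bed)
}

#' De-introgress a genotype set sample by sample
#'
#' Applies [mask_introgressed()] per sample, using each sample's own
#' tract calls: genotypes (and read counts) inside a sample's qualifying
#' donor tracts are set missing, with the same reconnect rule.  Samples
#' without tracts are untouched.  This is the masking used before
#' downstream demographic or phylogenetic inference.
#'
#' @param geno a `geno_set`.
#' @param tracts tract calls from [call_tracts()] (with a `sample`
#'   column).
#' @param threshold minimum tract mean posterior for masking.
#' @param reconnect_min minimum run of clean sites that keeps a gap open.
#' @return list with `geno` (masked copy) and `mask_bed` (per-sample
#'   mask intervals; BED columns plus `sample`).
#' @export
mask_genotypes <- function(geno, tracts, threshold = 0.8,
                           reconnect_min = 3) {
  stopifnot(inherits(geno, "geno_set"))
  out <- geno
  beds <- list()
  for (s in intersect(unique(tracts$sample), geno$samples)) {
    res <- mask_introgressed(geno$sites, tracts[tracts$sample == s, ,
                                                drop = FALSE],
                             threshold = threshold,
                             reconnect_min = reconnect_min)
    if (length(res$masked)) {
      out$gt[res$masked, s] <- NA_integer_
      if (!is.null(out$dp)) out$dp[res$masked, s] <- NA_integer_
      if (nrow(res$mask_bed))
        beds[[s]] <- data.frame(res$mask_bed, sample = s)
    }
  }
  list(geno = out,
       mask_bed = if (length(beds)) do.call(rbind, beds) else
         data.frame(chrom = character(), start = numeric(),
                    end = numeric(), sample = character()))
}

#' Write tracts or masks as BED
#'
#' @param tracts data.frame with `chrom`, `start`, `end` and optional
#'   `sample`/`dosage` columns (used for the BED name field).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tracts_bed <- function(tracts, path) {
  name <- if ("sample" %in% names(tracts))
    paste0(tracts$sample, ":", tracts$dosage) else "."
  bed <- data.frame(tracts$chrom, as.integer(floor(tracts$start)),
                    as.integer(ceiling(tracts$end)), name)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
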