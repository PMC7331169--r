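## Per-site Weir & Cockerham (1984) variance components a, b, c for two
## populations, from diploid sample sizes n_i, alt frequencies p_i and
## observed heterozygote frequencies h_i.
wc84_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

pop_site_stats <- function(geno, pop) {
  cols <- names(geno$pop)[geno$pop == pop]
  g <- geno$gt[, cols, drop = FALSE]
  n <- rowSums(!is.na(g))
  list(n = n, p = rowSums(g, na.rm = TRUE) / (2 * n),
       h = rowSums(g == 1, na.rm = TRUE) / n)
}

assign_windows <- function(chrom, pos, windows) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(gr, to_granges(windows))
  wi <- rep(NA_integer_, length(chrom))
  wi[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  wi
}

#' Windowed F_ST between two populations
#'
#' Per-site Weir & Cockerham (1984) variance components summed per
#' window: `F_ST = sum(a) / sum(a + b + c)`.  The Hudson estimator
#' (ratio-of-sums of Hudson numerator/denominator) is available as an
#' alternative.  Negative window values are retained, windows without
#' polymorphic sites are missing.
#'
#' @param geno a `geno_set`.
#' @param popA,popB population labels (>= 2 samples each).
#' @param windows window tiling; default 100-kb tiling of
#'   `geno$chrom_lengths`.
#' @param window window size in bp when `windows` is `NULL`.
#' @param estimator `"wc84"` or `"hudson"`.
#' @return data.frame of window statistics (`stat = "fst"`); attributes
#'   `genome_mean` and `genome_sd` hold the across-window summary.
#' @export
fst_windows <- function(geno, popA, popB, windows = NULL, window = 1e5,
                        estimator = c("wc84", "hudson")) {
  estimator <- match.arg(estimator)
  sA <- pop_site_stats(geno, popA)
  sB <- pop_site_stats(geno, popB)
  if (max(sA$n) < 2 || max(sB$n) < 2)
    stop("need at least 2 samples per population")
  if (is.null(windows))
    windows <- make_windows(geno$chrom_lengths, window)
  ok <- sA$n >= 2 & sB$n >= 2
  poly <- ok & (sA$p > 0 | sB$p > 0) & (sA$p < 1 | sB$p < 1)
  wi <- assign_windows(geno$sites$chrom, geno$sites$pos, windows)
  use <- poly & !is.na(wi)
  if (estimator == "wc84") {
    comp <- wc84_components(sA$n[use], sB$n[use], sA$p[use], sB$p[use],
                            sA$h[use], sB$h[use])
    num <- comp$a
    den <- comp$a + comp$b + comp$c
  } else {
    n1 <- 2 * sA$n[use]; n2 <- 2 * sB$n[use]
    p1 <- sA$p[use]; p2 <- sB$p[use]
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
  }
  sum_w <- function(x) {
    s <- rep(NA_real_, nrow(windows))
    t <- tapply(x, wi[use], sum)
    s[as.integer(names(t))] <- t
    s
  }
  val <- sum_w(num) / sum_w(den)
  nst <- rep(0L, nrow(windows))
  cnt <- table(wi[use])
  nst[as.integer(names(cnt))] <- as.integer(cnt)
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, stat = "fst", value = val,
                    n_sites = nst, stringsAsFactors = FALSE)
  out$quantile <- rank_quantile(out$value)
  attr(out, "genome_mean") <- mean(val, na.rm = TRUE)
  attr(out, "genome_sd") <- sd(val, na.rm = TRUE)
  out
}

#' Windowed nucleotide diversity
#'
#' Per-site expected heterozygosity with the small-sample correction,
#' `2 p (1 - p) n / (n - 1)` (`n` = called alleles), summed per window;
#' reported both as the mean per variant site and per bp.
#'
#' @param geno a `geno_set`.
#' @param pop population label.
#' @inheritParams fst_windows
#' @return data.frame of window statistics (`stat = "pi"`; `value` is
#'   the per-variant-site mean, `pi_per_bp` the window sum divided by
#'   window length).
#' @export
pi_windows <- function(geno, pop, windows = NULL, window = 1e5) {
  s <- pop_site_stats(geno, pop)
  if (is.null(windows))
    windows <- make_windows(geno$chrom_lengths, window)
  ok <- s$n >= 2
  n_al <- 2 * s$n
  pi_site <- ifelse(ok, 2 * s$p * (1 - s$p) * n_al / (n_al - 1), NA_real_)
  wi <- assign_windows(geno$sites$chrom, geno$sites$pos, windows)
  use <- ok & !is.na(wi)
  tot <- rep(0, nrow(windows)); nst <- rep(0L, nrow(windows))
  t1 <- tapply(pi_site[use], wi[use], sum)
  tot[as.integer(names(t1))] <- t1
  cnt <- table(wi[use])
  nst[as.integer(names(cnt))] <- as.integer(cnt)
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, stat = "pi",
                    value = ifelse(nst > 0, tot / nst, 0),
                    pi_per_bp = tot / (windows$end - windows$start),
                    n_sites = nst, stringsAsFactors = FALSE)
  out$quantile <- rank_quantile(out$value)
  out
}

## EHH decay on one side of a core SNP for a haplotype matrix
## (sites x haplotypes).  Returns the integrated EHH (trapezoid in bp)
## or NA when the decay is truncated by the chromosome end or a gap.
ihh_one_side <- function(hap, pos, core, step, ehh_cutoff, max_gap) {
  n <- ncol(hap)
  pairs_tot <- n * (n - 1) / 2
  cls <- rep(1L, n)      # EHH of the extension: 1 at the core by definition
  ehh_prev <- 1
  ihh <- 0
  i <- core
  repeat {
    j <- i + step
    if (j < 1 || j > nrow(hap)) return(NA_real_)   # hit chromosome end
    if (abs(pos[j] - pos[i]) > max_gap) return(NA_real_)
    cls <- paste(cls, hap[j, ])
    ehh <- sum(vapply(split(seq_len(n), cls), function(ix)
      length(ix) * (length(ix) - 1) / 2, 0)) / pairs_tot
    ihh <- ihh + (ehh_prev + ehh) / 2 * abs(pos[j] - pos[i])
    if (ehh < ehh_cutoff) return(ihh)
    ehh_prev <- ehh
    i <- j
  }
}

#' Cross-population extended haplotype homozygosity (XP-EHH) scan
#'
#' For each core SNP and each population, the extended haplotype
#' homozygosity `EHH(x) = sum_h C(n_h, 2) / C(n, 2)` (over haplotype
#' classes of the extension from the core out to `x`; EHH is 1 at the
#' core itself) is
#' integrated outward by the trapezoid rule in physical distance until
#' it drops below `ehh_cutoff` on each side, giving iHH.  The raw score
#' is `ln(iHH_A / iHH_B)`; standardized scores subtract the genome mean
#' and divide by the genome SD.  Cores whose decay is truncated by a
#' chromosome end or an inter-SNP gap larger than `max_gap` are missing.
#'
#' @param geno a phased `geno_set` (haplotypes required).
#' @param popA,popB population labels (A is the candidate selected
#'   population; positive scores mean longer haplotypes in A).
#' @param maf_min minimum pooled minor-allele frequency at core SNPs.
#' @param ehh_cutoff EHH level at which integration stops.
#' @param max_gap inter-SNP distance treated as an assembly gap (bp).
#' @param quantile standardized scores at or above this empirical
#'   quantile are flagged significant.
#' @return data.frame `chrom`, `pos`, `ihh_a`, `ihh_b`, `raw`, `std`,
#'   `significant`.
#' @export
xpehh_scan <- function(geno, popA, popB, maf_min = 0.05, ehh_cutoff = 0.05,
                       max_gap = 2e5, quantile = 0.99) {
  stopifnot(inherits(geno, "geno_set"))
  if (is.null(geno$hap) || !isTRUE(geno$phased))
    stop("XP-EHH requires phased haplotypes")
  hap_sample <- sub("_[12]$", "", colnames(geno$hap))
  colsA <- which(geno$pop[hap_sample] == popA)
  colsB <- which(geno$pop[hap_sample] == popB)
  if (!length(colsA) || !length(colsB)) stop("populations not found")
  pool <- geno$hap[, c(colsA, colsB), drop = FALSE]
  maf <- rowMeans(pool)
  maf <- pmin(maf, 1 - maf)
  res <- data.frame(chrom = geno$sites$chrom, pos = geno$sites$pos,
                    ihh_a = NA_real_, ihh_b = NA_real_,
                    stringsAsFactors = FALSE)
  for (ch in unique(geno$sites$chrom)) {
    ci <- which(geno$sites$chrom == ch)
    hapA <- geno$hap[ci, colsA, drop = FALSE]
    hapB <- geno$hap[ci, colsB, drop = FALSE]
    pos <- geno$sites$pos[ci]
    for (k in seq_along(ci)) {
      if (is.na(maf[ci[k]]) || maf[ci[k]] < maf_min) next
      ia <- c(ihh_one_side(hapA, pos, k, -1L, ehh_cutoff, max_gap),
              ihh_one_side(hapA, pos, k, 1L, ehh_cutoff, max_gap))
      ib <- c(ihh_one_side(hapB, pos, k, -1L, ehh_cutoff, max_gap),
              ihh_one_side(hapB, pos, k, 1L, ehh_cutoff, max_gap))
      res$ihh_a[ci[k]] <- sum(ia)
      res$ihh_b[ci[k]] <- sum(ib)
    }
  }
  res$raw <- ifelse(!is.na(res$ihh_a) & !is.na(res$ihh_b) & res$ihh_b > 0 &
                      res$ihh_a > 0, log(res$ihh_a / res$ihh_b), NA_real_)
  mu <- mean(res$raw, na.rm = TRUE); sg <- sd(res$raw, na.rm = TRUE)
  res$std <- (res$raw - mu) / sg
  ok <- !is.na(res$std)
  thr <- if (any(ok)) stats::quantile(res$std[ok], quantile, names = FALSE)
         else Inf
  res$significant <- ok & res$std >= thr
  res
}

#' Merge significant SNPs into selection regions
#'
#' Integrates runs of significant SNPs into regions, tolerating at most
#' one embedded non-significant SNP between consecutive significant
#' ones; region bounds extend by half the physical distance to the
#' nearest flanking non-significant marker.  Isolated single significant
#' SNPs are discarded (long-haplotype signals should span several
#' markers).
#'
#' @param scores data.frame of all scored SNPs with `chrom`, `pos` and a
#'   logical significance column.
#' @param sig_col name of the significance column.
#' @param method label stored on the output regions.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open),
#'   `method`, `n_snps` (significant SNPs), `peak` (max `std` if
#'   present).
#' @export
merge_regions <- function(scores, sig_col = "significant",
                          method = "XPEHH") {
  out <- list()
  for (ch in unique(scores$chrom)) {
    sc <- scores[scores$chrom == ch, , drop = FALSE]
    sc <- sc[order(sc$pos), , drop = FALSE]
    sig_idx <- which(sc[[sig_col]] %in% TRUE)
    if (length(sig_idx) < 2) next
    grp <- cumsum(c(1, diff(sig_idx) > 2))   # > 1 non-sig marker breaks a run
    for (g in unique(grp)) {
      members <- sig_idx[grp == g]
      if (length(members) < 2) next          # isolated SNPs discarded
      first <- members[1]; last <- members[length(members)]
      start <- if (first > 1)
        sc$pos[first] - (sc$pos[first] - sc$pos[first - 1]) / 2
      else sc$pos[first] - 1
      end <- if (last < nrow(sc))
        sc$pos[last] + (sc$pos[last + 1] - sc$pos[last]) / 2
      else sc$pos[last]
      peak <- if ("std" %in% names(sc))
        max(sc$std[members], na.rm = TRUE) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = start, end = end, method = method,
        n_snps = length(members), peak = peak, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), method = character(),
                      n_snps = integer(), peak = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Overlap of F_ST outlier windows and XP-EHH regions
#'
#' Interval intersection of two region sets; the overlapping pieces are
#' returned tagged `method = "both"`.
#'
#' @param fst_regions,xpehh_regions data.frames with `chrom`, `start`,
#'   `end` (0-based half-open).
#' @return data.frame of intersection intervals with `method = "both"`.
#' @export
overlap_selection <- function(fst_regions, xpehh_regions) {
  if (nrow(fst_regions) == 0 || nrow(xpehh_regions) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), method = character()))
  ga <- GenomicRanges::reduce(to_granges(fst_regions))
  gb <- GenomicRanges::reduce(to_granges(xpehh_regions))
  lv <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- lv
  GenomeInfoDb::seqlevels(gb) <- lv
  gr <- GenomicRanges::intersect(ga, gb)
  if (!length(gr))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), method = character()))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr), method = "both",
             stringsAsFactors = FALSE)
}
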