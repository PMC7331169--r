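## Per-site ABBA/BABA weights from derived-allele frequencies.
## ABBA = (1-p1) p2 p3 (1-pO); BABA = p1 (1-p2) p3 (1-pO).
abba_baba_terms <- function(p1, p2, p3, pO) {
  list(abba = (1 - p1) * p2 * p3 * (1 - pO),
       baba = p1 * (1 - p2) * p3 * (1 - pO))
}

site_blocks <- function(chrom, pos, block_size) {
  paste(chrom, (pos - 1) %/% block_size)
}

#' Patterson's D with block-resampled standard errors
#'
#' Computes the four-taxon ABBA-BABA statistic from per-population
#' derived-allele frequencies (frequency weights rather than binary
#' fixed-site counts), `D = (sum ABBA - sum BABA) / (sum ABBA + sum
#' BABA)`.  The standard error comes from resampling contiguous genomic
#' blocks: bootstrap (default) or delete-one block jackknife.  A z-test
#' against `D = 0` uses the normal approximation.
#'
#' @param table a `polarized_sites` table from [polarize_and_filter()].
#' @param trio character vector `c(P1, P2, P3)` of population labels; P3
#'   is the candidate donor lineage.
#' @param block_size resampling block length in bp (default 30 Mb).
#' @param n_boot number of bootstrap replicates.
#' @param method `"bootstrap"` or `"jackknife"`.
#' @param seed optional seed for the bootstrap resampling.
#' @return object of class `dstat`: list with `D`, `SE`, `z`, `p`,
#'   `n_blocks`, `block_size`, `ABBA_sum`, `BABA_sum`, `method`.
#' @export
patterson_d <- function(table, trio, block_size = 30e6, n_boot = 1000,
                        method = c("bootstrap", "jackknife"), seed = NULL) {
  method <- match.arg(method)
  p1 <- table[[paste0("p_", trio[1])]]
  p2 <- table[[paste0("p_", trio[2])]]
  p3 <- table[[paste0("p_", trio[3])]]
  if (is.null(p1) || is.null(p2) || is.null(p3))
    stop("trio populations not all present in the site table")
  tm <- abba_baba_terms(p1, p2, p3, table$pO)
  ok <- complete.cases(tm$abba, tm$baba)
  abba <- tm$abba[ok]; baba <- tm$baba[ok]
  blk <- site_blocks(table$chrom[ok], table$pos[ok], block_size)
  ab_b <- tapply(abba, blk, sum); ba_b <- tapply(baba, blk, sum)
  B <- length(ab_b)
  if (B < 2) stop("need at least 2 non-empty blocks for resampling")
  tot_ab <- sum(ab_b); tot_ba <- sum(ba_b)
  D <- if (tot_ab + tot_ba == 0) NA_real_ else
    (tot_ab - tot_ba) / (tot_ab + tot_ba)
  if (!is.null(seed)) set.seed(seed)
  if (method == "bootstrap") {
    Dstar <- replicate(n_boot, {
      i <- sample.int(B, B, replace = TRUE)
      s_ab <- sum(ab_b[i]); s_ba <- sum(ba_b[i])
      if (s_ab + s_ba == 0) NA_real_ else (s_ab - s_ba) / (s_ab + s_ba)
    })
    SE <- sd(Dstar, na.rm = TRUE)
  } else {
    Dj <- vapply(seq_len(B), function(i) {
      s_ab <- tot_ab - ab_b[i]; s_ba <- tot_ba - ba_b[i]
      if (s_ab + s_ba == 0) NA_real_ else (s_ab - s_ba) / (s_ab + s_ba)
    }, 0)
    SE <- sqrt((B - 1) / B * sum((Dj - mean(Dj, na.rm = TRUE))^2,
                                 na.rm = TRUE))
  }
  z <- if (is.na(D) || SE == 0) NA_real_ else D / SE
  structure(list(D = D, SE = SE, z = z,
                 p = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)),
                 n_blocks = B, block_size = block_size,
                 ABBA_sum = tot_ab, BABA_sum = tot_ba, trio = trio,
                 method = method), class = "dstat")
}

#' @export
print.dstat <- function(x, ...) {
  cat(sprintf("Patterson's D (%s; %s): D = %.4f +/- %.4f (z = %.2f, p = %.3g)\n",
              paste(x$trio, collapse = ","), x$method, x$D, x$SE, x$z, x$p))
  cat(sprintf("  ABBA = %.1f, BABA = %.1f over %d blocks of %g bp\n",
              x$ABBA_sum, x$BABA_sum, x$n_blocks, x$block_size))
  invisible(x)
}

## f_d site terms: the denominator replaces both P2 and P3 by the donor
## frequency pD = max(p2, p3), the value the numerator would take under
## complete introgression.
fd_site_terms <- function(p1, p2, p3, pO) {
  tm <- abba_baba_terms(p1, p2, p3, pO)
  pD <- pmax(p2, p3)
  tmD <- abba_baba_terms(p1, pD, pD, pO)
  list(num = tm$abba - tm$baba, den = tmD$abba - tmD$baba,
       abba = tm$abba, baba = tm$baba)
}

#' Windowed f_d introgression-fraction scan
#'
#' Computes, per genomic window, the f_d estimator: the ABBA-BABA
#' numerator normalized by its value under complete introgression (both
#' P2 and P3 set to the donor frequency `max(p2, p3)` per site).
#' Windows with fewer than `min_sites` informative sites, a window-level
#' D below zero, or a zero denominator are reported missing.
#'
#' @inheritParams patterson_d
#' @param windows window tiling from [make_windows()]; default builds
#'   100-kb windows from `chrom_lengths`.
#' @param chrom_lengths named scaffold lengths (used when `windows` is
#'   `NULL`).
#' @param window window size in bp.
#' @param min_sites minimum informative sites per window.
#' @return data.frame of window statistics: `chrom`, `start`, `end`,
#'   `stat` (`"fd"`), `value`, `n_sites`, `quantile` (empirical, among
#'   non-missing windows).
#' @export
fd_windows <- function(table, trio, windows = NULL, chrom_lengths = NULL,
                       window = 1e5, min_sites = 10) {
  if (is.null(windows)) {
    if (is.null(chrom_lengths))
      chrom_lengths <- tapply(table$pos, table$chrom, max)
    windows <- make_windows(setNames(as.numeric(chrom_lengths),
                                     names(chrom_lengths)), window)
  }
  p1 <- table[[paste0("p_", trio[1])]]
  p2 <- table[[paste0("p_", trio[2])]]
  p3 <- table[[paste0("p_", trio[3])]]
  tm <- fd_site_terms(p1, p2, p3, table$pO)
  use <- (tm$abba + tm$baba) > 0 & !is.na(tm$num)
  sites_gr <- GenomicRanges::GRanges(table$chrom[use],
                IRanges::IRanges(table$pos[use], table$pos[use]))
  hits <- GenomicRanges::findOverlaps(sites_gr, to_granges(windows))
  wi <- S4Vectors::subjectHits(hits)
  si <- which(use)[S4Vectors::queryHits(hits)]
  sum_by <- function(x) {
    s <- numeric(nrow(windows))
    t <- tapply(x[si], wi, sum)
    s[as.integer(names(t))] <- t
    s
  }
  nst <- integer(nrow(windows))
  cnt <- table(wi)
  nst[as.integer(names(cnt))] <- as.integer(cnt)
  num <- sum_by(tm$num); den <- sum_by(tm$den)
  s_abba <- sum_by(tm$abba); s_baba <- sum_by(tm$baba)
  wD <- ifelse(s_abba + s_baba == 0, NA_real_,
               (s_abba - s_baba) / (s_abba + s_baba))
  val <- ifelse(nst < min_sites | is.na(wD) | wD < 0 | den == 0,
                NA_real_, num / den)
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, stat = "fd", value = val,
                    n_sites = nst, stringsAsFactors = FALSE)
  out$quantile <- rank_quantile(out$value)
  out
}

rank_quantile <- function(v) {
  q <- rep(NA_real_, length(v))
  ok <- !is.na(v)
  if (any(ok)) q[ok] <- rank(v[ok], ties.method = "average") / sum(ok)
  q
}

#' Upper-quantile outlier windows
#'
#' Returns windows whose statistic reaches the empirical upper
#' `1 - quantile` tail (default top 1%); ties at the threshold are all
#' included.
#'
#' @param stats window-statistic data.frame (e.g. from [fd_windows()]).
#' @param quantile lower bound of the retained upper tail (0.99 = top 1%).
#' @return the outlier subset of `stats`.
#' @export
outlier_windows <- function(stats, quantile = 0.99) {
  v <- stats$value
  ok <- !is.na(v)
  if (!any(ok)) return(stats[integer(), , drop = FALSE])
  thr <- stats::quantile(v[ok], quantile, names = FALSE)
  if (length(unique(v[ok])) == 1)
    warning("all window values identical; returning every window")
  stats[ok & v >= thr, , drop = FALSE]
}

to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' Intersect two window/region sets
#'
#' Symmetric interval intersection: any overlap of at least one bp
#' counts.  Rows of `setA` overlapping `setB` are returned.
#'
#' @param setA,setB data.frames with `chrom`, `start`, `end` (0-based,
#'   half-open).
#' @return the subset of `setA` with at least 1 bp overlap in `setB`.
#' @export
overlap_windows <- function(setA, setB) {
  if (nrow(setA) == 0 || nrow(setB) == 0) return(setA[integer(), ])
  hits <- GenomicRanges::findOverlaps(to_granges(setA), to_granges(setB))
  setA[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
}

#' X-versus-autosome contrast of window statistics
#'
#' Compares a window statistic (D or f_d) between X-linked windows and
#' autosomal windows with a Welch two-sample t-test.  Windows on PAR or
#' Y-like scaffolds (or overlapping PAR windows) are excluded from the X
#' group.
#'
#' @param stats window-statistic data.frame.
#' @param chrom_class output of [identify_x_scaffolds()] (or a
#'   data.frame with `scaffold` and `class`).
#' @return list with per-group `mean`, `sd`, `n`, plus `t`, `df`, `p`.
#' @export
x_autosome_contrast <- function(stats, chrom_class) {
  sc <- if (is.list(chrom_class) && !is.data.frame(chrom_class))
    chrom_class$scaffolds else chrom_class
  par_w <- if (is.list(chrom_class) && !is.data.frame(chrom_class))
    chrom_class$par_windows else NULL
  cls <- setNames(sc$class, sc$scaffold)
  stats <- stats[!is.na(stats$value), , drop = FALSE]
  on_x <- cls[stats$chrom] == "X"
  on_auto <- cls[stats$chrom] == "autosome"
  if (!is.null(par_w) && nrow(par_w) > 0) {
    pw <- data.frame(chrom = par_w$scaffold, start = par_w$start,
                     end = par_w$end)
    in_par <- rep(FALSE, nrow(stats))
    hits <- GenomicRanges::findOverlaps(to_granges(stats), to_granges(pw))
    in_par[S4Vectors::queryHits(hits)] <- TRUE
    on_x <- on_x & !in_par
  }
  x_vals <- stats$value[which(on_x)]
  a_vals <- stats$value[which(on_auto)]
  if (length(x_vals) < 2 || length(a_vals) < 2)
    stop("need at least 2 windows in each of the X and autosome groups")
  if (sd(x_vals) == 0 && sd(a_vals) == 0) {
    eq <- isTRUE(all.equal(mean(x_vals), mean(a_vals)))
    tt <- list(statistic = if (eq) 0 else sign(mean(x_vals) - mean(a_vals)) * Inf,
               parameter = NA_real_, p.value = if (eq) 1 else 0)
  } else {
    tt <- t.test(x_vals, a_vals)
  }
  list(x_mean = mean(x_vals), x_sd = sd(x_vals), x_n = length(x_vals),
       auto_mean = mean(a_vals), auto_sd = sd(a_vals),
       auto_n = length(a_vals),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
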