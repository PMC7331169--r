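map_dist_to_c <- function(d, r, mapping) {
  switch(mapping,
         sved = d * r / (1 + d * r),
         haldane = 0.5 * (1 - exp(-2 * d * r)))
}

#' Recent effective population size from LD decay
#'
#' Estimates an Ne trajectory from pairwise genotypic r-squared binned
#' by physical distance: each distance class maps to a recombination
#' fraction `c` (Sved mapping `c = d r / (1 + d r)` by default, Haldane
#' optional), to generations before present `t = 1 / (2 c)`, and to
#' `Ne = (1 / E[r2_adj] - alpha) / (4 c)` where `r2_adj` subtracts the
#' sample-size expectation (`1/n` for unphased genotypic r-squared,
#' `1/(2n)` phased) and `alpha` is the mutation adjustment (2.2 when
#' mutation is modeled, 2 otherwise).
#'
#' @param geno a `geno_set` (ignored when `r2_table` is supplied).
#' @param pop population label to analyse (default: all samples).
#' @param r assumed recombination rate per bp per generation.
#' @param distance_bins numeric break points in bp; default 20
#'   log-spaced bins between `min_dist` and `max_dist`.
#' @param alpha mutation adjustment (2.2 default).
#' @param mapping `"sved"` or `"haldane"` distance-to-c mapping.
#' @param phased use the phased (`1/(2n)`) sample-size adjustment.
#' @param min_dist,max_dist distance range for SNP pairs, bp.
#' @param min_pairs bins with fewer pairs are reported missing.
#' @param max_pairs_per_chrom random cap on pairs sampled per
#'   chromosome.
#' @param r2_table optional precomputed data.frame with `dist` and
#'   `r2_adj` per SNP pair (bypasses the genotype computation).
#' @param seed seed for pair subsampling.
#' @return data.frame of class `ne_trajectory`: `dist`, `c`, `t`,
#'   `n_pairs`, `r2_adj` (bin mean), `Ne` (missing where undefined).
#' @export
ldne_trajectory <- function(geno = NULL, pop = NULL, r,
                            distance_bins = NULL, alpha = 2.2,
                            mapping = c("sved", "haldane"),
                            phased = FALSE, min_dist = 5e3, max_dist = 5e6,
                            min_pairs = 100, max_pairs_per_chrom = 5e4,
                            r2_table = NULL, seed = NULL) {
  mapping <- match.arg(mapping)
  stopifnot(r > 0)
  if (is.null(r2_table)) {
    stopifnot(inherits(geno, "geno_set"))
    if (!is.null(seed)) set.seed(seed)
    cols <- if (is.null(pop)) geno$samples else
      names(geno$pop)[geno$pop == pop]
    g <- geno$gt[, cols, drop = FALSE]
    n <- length(cols)
    pairs <- list()
    for (ch in unique(geno$sites$chrom)) {
      ci <- which(geno$sites$chrom == ch)
      pos <- geno$sites$pos[ci]
      ## sample random site pairs within the distance range
      n_try <- min(max_pairs_per_chrom * 4, length(ci)^2)
      i <- sample(ci, n_try, replace = TRUE)
      j <- sample(ci, n_try, replace = TRUE)
      d <- abs(geno$sites$pos[j] - geno$sites$pos[i])
      keep <- which(d >= min_dist & d <= max_dist)
      keep <- keep[!duplicated(paste(pmin(i[keep], j[keep]),
                                     pmax(i[keep], j[keep])))]
      keep <- head(keep, max_pairs_per_chrom)
      if (!length(keep)) next
      r2 <- vapply(keep, function(k) {
        suppressWarnings(cor(g[i[k], ], g[j[k], ],
                             use = "complete.obs"))^2
      }, 0)
      pairs[[ch]] <- data.frame(dist = d[keep], r2 = r2)
    }
    tab <- do.call(rbind, pairs)
    tab <- tab[!is.na(tab$r2), , drop = FALSE]
    adj <- if (phased) 1 / (2 * n) else 1 / n
    tab$r2_adj <- tab$r2 - adj
  } else {
    tab <- r2_table
    stopifnot(all(c("dist", "r2_adj") %in% names(tab)))
  }
  if (is.null(distance_bins))
    distance_bins <- exp(seq(log(max(min(tab$dist), 1)),
                             log(max(tab$dist) + 1), length.out = 21))
  bin <- cut(tab$dist, distance_bins, include.lowest = TRUE)
  agg_mean <- tapply(tab$r2_adj, bin, mean)
  agg_dist <- tapply(tab$dist, bin, mean)
  agg_n <- tapply(tab$dist, bin, length)
  agg_n[is.na(agg_n)] <- 0
  d_mid <- as.numeric(agg_dist)
  cc <- map_dist_to_c(d_mid, r, mapping)
  e_r2 <- as.numeric(agg_mean)
  ne <- (1 / e_r2 - alpha) / (4 * cc)
  ne[!is.finite(ne) | ne <= 0] <- NA_real_
  ne[agg_n < min_pairs] <- NA_real_
  out <- data.frame(dist = d_mid, c = cc, t = 1 / (2 * cc),
                    n_pairs = as.integer(agg_n), r2_adj = e_r2, Ne = ne)
  out <- out[!is.na(out$dist), , drop = FALSE]
  out <- out[order(out$c), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ne_trajectory", "data.frame")
  out
}

#' Slope-change analysis of an Ne trajectory
#'
#' Fits the overall least-squares slope of Ne against time toward the
#' present and reports, per interval between consecutive time bins, the
#' local finite-difference slope minus the overall slope.  A constant
#' rate of change gives deviations near 0; values below 0 mark intervals
#' where the decline steepens, values above 0 where it slows.
#'
#' @param traj an `ne_trajectory` (or data.frame with `t` and `Ne`).
#' @return data.frame `t_mid` (generations before present at the
#'   interval midpoint), `local_slope`, `deviation`; attribute
#'   `overall_slope`.
#' @export
nes_slopes <- function(traj) {
  d <- traj[!is.na(traj$Ne), c("t", "Ne")]
  if (nrow(d) < 3) stop("need at least 3 trajectory points")
  d <- d[order(-d$t), ]                  # past -> present
  u <- -d$t                              # time toward the present
  overall <- unname(coef(lm(d$Ne ~ u))[2])
  local <- diff(d$Ne) / diff(u)
  out <- data.frame(t_mid = (d$t[-1] + d$t[-nrow(d)]) / 2,
                    local_slope = local,
                    deviation = local - overall)
  attr(out, "overall_slope") <- overall
  out
}

#' Convert an admixture date in generations to calendar years
#'
#' `years = round-half-up(t * g)` for each candidate generation length.
#'
#' @param t_generations admixture time in generations (> 0).
#' @param gen_lengths candidate generation lengths in years.
#' @param reference_year year to anchor `year_bp` against (optional).
#' @return data.frame `gen_length`, `years_exact`, `years` (rounded),
#'   and `event_year` when `reference_year` is given.
#' @export
generations_to_years <- function(t_generations, gen_lengths = c(3, 4, 5, 6, 7),
                                 reference_year = NULL) {
  stopifnot(t_generations > 0)
  exact <- t_generations * gen_lengths
  out <- data.frame(gen_length = gen_lengths, years_exact = exact,
                    years = floor(exact + 0.5))
  if (!is.null(reference_year)) out$event_year <- reference_year - out$years
  out
}

#' Infer a generation length from an anchored historical event
#'
#' Given a dated event assumed to coincide with the admixture pulse,
#' `g = (reference_year - event_year) / t` years per generation.
#'
#' @param t_generations admixture time in generations (> 0).
#' @param event_year calendar year of the anchoring event.
#' @param reference_year present-day reference year.
#' @return list with `years_per_generation` and `rounded`.
#' @export
infer_generation_length <- function(t_generations, event_year = 1529,
                                    reference_year = 2020) {
  if (t_generations <= 0) stop("t must be positive")
  stopifnot(reference_year > event_year)
  g <- (reference_year - event_year) / t_generations
  list(years_per_generation = g, rounded = round(g))
}
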