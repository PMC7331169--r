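#' Pairwise uncorrected P-distances between diploid genotypes
#'
#' Generalizes the uncorrected P-distance to diploid genotypes:
#' `d(i, j) = sum |g_i - g_j| / (2 * n_called)` over sites called in
#' both samples (allele-sharing distance, in `[0, 1]`).
#'
#' @param gt sites x samples matrix of allele dosages (0/1/2, NA
#'   allowed).
#' @return symmetric distance matrix with zero diagonal.
#' @export
p_distance <- function(gt) {
  ns <- ncol(gt)
  D <- matrix(0, ns, ns, dimnames = list(colnames(gt), colnames(gt)))
  for (i in seq_len(ns - 1)) {
    for (j in seq(i + 1, ns)) {
      ok <- !is.na(gt[, i]) & !is.na(gt[, j])
      if (!any(ok))
        stop("samples ", colnames(gt)[i], " and ", colnames(gt)[j],
             " share no called sites")
      D[i, j] <- D[j, i] <- sum(abs(gt[ok, i] - gt[ok, j])) / (2 * sum(ok))
    }
  }
  D
}

#' Neighbor-joining SNP tree with site-bootstrap support
#'
#' Builds a Saitou-Nei neighbor-joining tree from genotype P-distances
#' (ideally on thinned SNPs, see [thin_snps()]) and attaches bootstrap
#' support: sites are resampled with replacement, the tree rebuilt, and
#' each internal edge labelled with the percentage of replicates
#' containing its bipartition.
#'
#' @param gt sites x samples dosage matrix.
#' @param n_bootstrap bootstrap replicates (0 disables support values).
#' @param seed seed for the bootstrap resampling.
#' @return list with `tree` (an `ape` `phylo`; node labels hold percent
#'   support), `dist` (the P-distance matrix).
#' @export
nj_tree <- function(gt, n_bootstrap = 100, seed = NULL) {
  if (ncol(gt) < 4) stop("need at least 4 samples for a meaningful NJ tree")
  D <- p_distance(gt)
  tree <- ape::nj(as.dist(D))
  if (n_bootstrap > 0) {
    if (!is.null(seed)) set.seed(seed)
    bp <- ape::prop.part(tree)
    boot_fun <- function(x) ape::nj(as.dist(p_distance(t(x))))
    counts <- ape::boot.phylo(tree, t(gt), boot_fun, B = n_bootstrap,
                              quiet = TRUE, rooted = FALSE)
    counts[is.na(counts)] <- n_bootstrap   # the trivial (root) bipartition
    tree$node.label <- round(100 * counts / n_bootstrap)
  }
  list(tree = tree, dist = D)
}

taxon_freq_dist <- function(pX, pY) {
  ## expected per-site mismatch of haploid draws from the two taxa
  mean(pX * (1 - pY) + pY * (1 - pX))
}

#' Per-window quartet topology tally
#'
#' A light-weight gene-tree discordance summary for four taxa: in each
#' genomic window the six between-taxon allele-frequency distances are
#' combined into the three quartet pair sums and the four-point
#' condition picks the supported unrooted topology (the pairing with the
#' smallest sum).  Windows where the margin between the two smallest
#' sums is below `margin` (relative) are reported ambiguous.  Genome
#' proportions of the three topologies estimate concordant and
#' discordant (lineage sorting or admixture) fractions; under admixture
#' the two minor topologies are asymmetric, with an excess of the
#' donor-pairing topology.
#'
#' @param geno a `geno_set`.
#' @param taxa character vector of four population labels (A, B, C, D);
#'   topologies are reported as `"AB|CD"`, `"AC|BD"`, `"AD|BC"` in terms
#'   of these labels.
#' @param window window size in bp.
#' @param min_sites minimum polymorphic sites per window.
#' @param margin relative four-point margin below which a window is
#'   ambiguous.
#' @return list with `proportions` (named: the three topologies and
#'   `ambiguous`), `n_windows`, and `windows` (per-window data.frame).
#' @export
quartet_ils <- function(geno, taxa, window = 1e5, min_sites = 50,
                        margin = 0.01) {
  stopifnot(length(taxa) == 4, all(taxa %in% geno$pop))
  fr <- pop_freq(geno, taxa)
  p <- vapply(taxa, function(x) fr[[x]]$freq, numeric(nrow(geno$sites)))
  poly <- rowSums(p > 0, na.rm = TRUE) > 0 &
    rowSums(p < 1, na.rm = TRUE) > 0 & complete.cases(p)
  windows <- make_windows(if (!is.null(geno$chrom_lengths))
    geno$chrom_lengths else
      setNames(tapply(geno$sites$pos, geno$sites$chrom, max),
               unique(geno$sites$chrom)), window)
  wi <- assign_windows(geno$sites$chrom, geno$sites$pos, windows)
  labs <- c(paste0(taxa[1], taxa[2], "|", taxa[3], taxa[4]),
            paste0(taxa[1], taxa[3], "|", taxa[2], taxa[4]),
            paste0(taxa[1], taxa[4], "|", taxa[2], taxa[3]))
  topo <- character(nrow(windows))
  for (w in seq_len(nrow(windows))) {
    idx <- which(wi == w & poly)
    if (length(idx) < min_sites) { topo[w] <- NA_character_; next }
    d <- function(i, j) taxon_freq_dist(p[idx, i], p[idx, j])
    sums <- c(d(1, 2) + d(3, 4), d(1, 3) + d(2, 4), d(1, 4) + d(2, 3))
    o <- order(sums)
    rel <- (sums[o[2]] - sums[o[1]]) / max(sums[o[1]], .Machine$double.eps)
    topo[w] <- if (rel < margin) "ambiguous" else labs[o[1]]
  }
  used <- !is.na(topo)
  props <- setNames(numeric(4), c(labs, "ambiguous"))
  if (any(used)) {
    tb <- table(factor(topo[used], levels = names(props)))
    props[] <- as.numeric(tb) / sum(tb)
  }
  list(proportions = props, n_windows = sum(used),
       windows = data.frame(windows[, c("chrom", "start", "end")],
                            topology = topo, stringsAsFactors = FALSE))
}
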