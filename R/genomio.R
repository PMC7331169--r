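#' Write a genotype dataset as VCF v4.2
#'
#' Emits plain-text VCF v4.2 with per-sample GT (phased when haplotypes
#' are available), AD and DP fields, suitable for round-tripping through
#' [load_genotypes()].
#'
#' @param geno a `geno_set` (e.g. from [simulate_admixed_cohort()]).
#' @param path output file path (plain text, not compressed).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "geno_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(geno$chrom_lengths),
            as.integer(geno$chrom_lengths)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples), collapse = "\t")), con)
  n_sites <- nrow(geno$sites)
  ns <- length(geno$samples)
  if (!is.null(geno$hap) && isTRUE(geno$phased)) {
    a1 <- geno$hap[, seq(1, 2 * ns, 2), drop = FALSE]
    a2 <- geno$hap[, seq(2, 2 * ns, 2), drop = FALSE]
    gt_str <- matrix(paste0(a1, "|", a2), n_sites, ns)
  } else {
    g <- geno$gt
    gt_str <- matrix("./.", n_sites, ns)
    gt_str[!is.na(g) & g == 0] <- "0/0"
    gt_str[!is.na(g) & g == 1] <- "0/1"
    gt_str[!is.na(g) & g == 2] <- "1/1"
  }
  fmt <- matrix(paste0(gt_str, ":", geno$ad_ref, ",", geno$ad_alt, ":",
                       geno$dp), n_sites, ns)
  body <- paste(geno$sites$chrom, geno$sites$pos, ".", geno$sites$ref,
                geno$sites$alt, ".", "PASS", ".", "GT:AD:DP",
                apply(fmt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Load biallelic SNP genotypes from a VCF
#'
#' Reads a VCF v4.2 (via `vcfR`), keeps biallelic SNPs only (multiallelic
#' records and indels are dropped, with counts recorded), and extracts
#' per-sample alt-allele dosages, allelic depths and read depths.
#' Missing genotypes are preserved as `NA`.
#'
#' @param path VCF file path.
#' @param pop_map named character vector mapping sample name to
#'   population; every mapped sample must be present in the VCF.
#' @return a `geno_set` (see [simulate_admixed_cohort()] for fields);
#'   `n_dropped` records the multiallelic/indel counts; `hap` is present
#'   when all genotypes are phased.
#' @export
load_genotypes <- function(path, pop_map) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    empty <- structure(list(
      sites = data.frame(chrom = character(), pos = integer(),
                         ref = character(), alt = character()),
      samples = names(pop_map), pop = pop_map,
      gt = matrix(NA_integer_, 0, length(pop_map),
                  dimnames = list(NULL, names(pop_map))),
      hap = NULL, ad_ref = NULL, ad_alt = NULL, dp = NULL, phased = FALSE,
      chrom_lengths = NULL,
      n_dropped = c(multiallelic = 0L, indel = 0L)), class = "geno_set")
    return(empty)
  }
  vcf_samples <- colnames(v@gt)[-1]
  missing <- setdiff(names(pop_map), vcf_samples)
  if (length(missing))
    stop("sample(s) in population map absent from VCF: ",
         paste(missing, collapse = ", "))
  multi <- grepl(",", fix$ALT)
  indel <- !multi & (nchar(fix$REF) != 1 | nchar(fix$ALT) != 1 |
                       fix$ALT == "." | fix$ALT == "*")
  keep <- !multi & !indel
  n_dropped <- c(multiallelic = sum(multi), indel = sum(indel))
  v <- v[keep, ]
  fix <- fix[keep, , drop = FALSE]

  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gt_raw <- gt_raw[, names(pop_map), drop = FALSE]
  phased <- nrow(fix) > 0 && all(grepl("\\|", gt_raw) | gt_raw %in% c(".", "./."),
                                 na.rm = TRUE) && any(grepl("\\|", gt_raw))
  a1 <- substr(gt_raw, 1, 1); a2 <- substr(gt_raw, 3, 3)
  to_int <- function(x) { x[!x %in% c("0", "1")] <- NA; as.integer(x) }
  a1 <- matrix(to_int(a1), nrow(fix)); a2 <- matrix(to_int(a2), nrow(fix))
  gt <- a1 + a2
  colnames(gt) <- names(pop_map)
  hap <- NULL
  if (phased) {
    hap <- matrix(0L, nrow(fix), 2L * length(pop_map))
    hap[, seq(1, ncol(hap), 2)] <- a1
    hap[, seq(2, ncol(hap), 2)] <- a2
    colnames(hap) <- paste0(rep(names(pop_map), each = 2), "_", 1:2)
  }
  dp <- suppressWarnings(vcfR::extract.gt(v, "DP", as.numeric = TRUE))
  if (!is.null(dp)) dp <- dp[, names(pop_map), drop = FALSE]
  ad <- vcfR::extract.gt(v, "AD")
  ad_ref <- ad_alt <- NULL
  if (!is.null(ad)) {
    ad <- ad[, names(pop_map), drop = FALSE]
    ad_ref <- matrix(as.integer(sub(",.*", "", ad)), nrow(fix),
                     dimnames = list(NULL, names(pop_map)))
    ad_alt <- matrix(as.integer(sub(".*,", "", ad)), nrow(fix),
                     dimnames = list(NULL, names(pop_map)))
  }
  ## contig lengths from the header, if declared
  ctg <- grep("^##contig", v@meta, value = TRUE)
  chrom_lengths <- NULL
  if (length(ctg)) {
    ids <- sub('.*ID=([^,>]+).*', "\\1", ctg)
    lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", ctg)))
    if (!anyNA(lens)) chrom_lengths <- setNames(lens, ids)
  }
  structure(list(
    sites = data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                       ref = fix$REF, alt = fix$ALT,
                       stringsAsFactors = FALSE),
    samples = names(pop_map), pop = pop_map, gt = gt, hap = hap,
    ad_ref = ad_ref, ad_alt = ad_alt, dp = dp, phased = phased,
    chrom_lengths = chrom_lengths, n_dropped = n_dropped),
    class = "geno_set")
}

pop_freq <- function(geno, pops = unique(geno$pop)) {
  ## alt-allele frequency and called-allele count per population
  out <- list()
  for (p in pops) {
    cols <- names(geno$pop)[geno$pop == p]
    g <- geno$gt[, cols, drop = FALSE]
    n_called <- rowSums(!is.na(g))
    out[[p]] <- list(freq = rowSums(g, na.rm = TRUE) / (2 * n_called),
                     n = 2L * n_called)
  }
  out
}

#' Polarize sites against an outgroup and apply depth filters
#'
#' Determines the derived allele at every biallelic site as the allele
#' absent (or rare, up to a fixedness tolerance) in the outgroup, drops
#' sites where the outgroup is polymorphic or entirely missing, and
#' drops sites failing the per-site depth rule (a minimum fraction of
#' samples at or above a minimum read depth).
#'
#' @param geno a `geno_set`.
#' @param outgroup population label of the outgroup in `geno$pop`.
#' @param min_depth per-sample read depth required at a site.
#' @param min_called_frac minimum fraction of samples meeting `min_depth`.
#' @param fixed_tol outgroup alt frequency `<= fixed_tol` (or
#'   `>= 1 - fixed_tol`) counts as fixed.
#' @return a `polarized_sites` data.frame: `chrom`, `pos`, one derived
#'   frequency column `p_<pop>` and allele count `n_<pop>` per non-outgroup
#'   population, and `pO` (outgroup derived frequency, recorded even when
#'   0).  Attributes: `pops`, `drop_reasons` (named counts).
#' @export
polarize_and_filter <- function(geno, outgroup, min_depth = 10,
                                min_called_frac = 0.9, fixed_tol = 0.05) {
  stopifnot(inherits(geno, "geno_set"), outgroup %in% geno$pop)
  n_sites <- nrow(geno$sites)
  depth_ok <- rep(TRUE, n_sites)
  if (!is.null(geno$dp) && n_sites > 0)
    depth_ok <- rowMeans(!is.na(geno$dp) & geno$dp >= min_depth) >=
      min_called_frac
  fr <- pop_freq(geno)
  pO_alt <- fr[[outgroup]]$freq
  og_missing <- fr[[outgroup]]$n == 0
  og_fixed_ref <- !og_missing & pO_alt <= fixed_tol
  og_fixed_alt <- !og_missing & pO_alt >= 1 - fixed_tol
  og_poly <- !og_missing & !og_fixed_ref & !og_fixed_alt
  keep <- depth_ok & (og_fixed_ref | og_fixed_alt)
  drop_reasons <- c(depth = sum(!depth_ok),
                    outgroup_missing = sum(og_missing & depth_ok),
                    outgroup_polymorphic = sum(og_poly & depth_ok))
  pops <- setdiff(unique(geno$pop), outgroup)
  out <- geno$sites[keep, c("chrom", "pos"), drop = FALSE]
  flip <- og_fixed_alt[keep]             # derived allele is REF there
  for (p in pops) {
    f <- fr[[p]]$freq[keep]
    out[[paste0("p_", p)]] <- ifelse(flip, 1 - f, f)
    out[[paste0("n_", p)]] <- fr[[p]]$n[keep]
  }
  out$pO <- ifelse(flip, 1 - pO_alt[keep], pO_alt[keep])
  out$flipped <- flip                    # derived allele is REF at these sites
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("all sites removed by polarization/depth filters")
  attr(out, "pops") <- pops
  attr(out, "drop_reasons") <- drop_reasons
  attr(out, "site_index") <- which(keep)
  class(out) <- c("polarized_sites", "data.frame")
  out
}

#' Tile chromosomes into genomic windows
#'
#' @param chrom_lengths named numeric vector of scaffold lengths in bp.
#' @param size window size in bp.
#' @param step step between window starts (defaults to `size`: tiling).
#' @return data.frame `chrom`, `start`, `end` (0-based half-open),
#'   `partial` (`TRUE` for a trailing window shorter than `size`).
#' @export
make_windows <- function(chrom_lengths, size, step = size) {
  stopifnot(size > 0, step > 0, !is.null(names(chrom_lengths)))
  out <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0, max(L - 1, 0), by = step)
    starts <- starts[starts < L]
    ends <- pmin(starts + size, L)
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            partial = ends - starts < size,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Thin SNPs to at most one per fixed-width bin
#'
#' Slides non-overlapping bins (default 250 bp) along each chromosome and
#' keeps the first SNP in each occupied bin — a deterministic, order-stable
#' rule for reducing linked redundancy before tree building.
#'
#' @param sites data.frame with `chrom` and `pos` (1-based), sorted.
#' @param window bin width in bp.
#' @return integer vector of retained row indices into `sites`.
#' @export
thin_snps <- function(sites, window = 250) {
  stopifnot(window > 0, all(c("chrom", "pos") %in% names(sites)))
  if (nrow(sites) == 0) return(integer())
  o <- order(sites$chrom, sites$pos)
  bin <- paste(sites$chrom[o], (sites$pos[o] - 1) %/% window)
  sort(o[!duplicated(bin)])
}

#' Classify scaffolds as autosome, X, PAR or Y-like from sexed depth
#'
#' Computes, per scaffold, the male/female depth ratio normalized by each
#' sex's modal (autosomal) depth, and classifies: X when the ratio falls
#' in `[0.35, 0.65]`, autosome in `[0.85, 1.15]`, Y-like when female
#' depth is near zero, otherwise unknown.  Within X scaffolds, terminal
#' windows whose ratio is autosome-like are flagged as pseudo-autosomal
#' (PAR).
#'
#' @param depth_table data.frame from [simulate_depth_profiles()] or
#'   equivalent: `scaffold`, `start`, `end`, `sample`, `depth`.
#' @param sex_labels named `"M"`/`"F"` vector per sample (at least one of
#'   each).
#' @return list with `scaffolds` (data.frame: `scaffold`, `class`,
#'   `ratio`) and `par_windows` (data.frame of PAR-flagged windows on X
#'   scaffolds, possibly empty).
#' @export
identify_x_scaffolds <- function(depth_table, sex_labels) {
  sex_labels <- toupper(sex_labels)
  if (anyNA(match(unique(depth_table$sample), names(sex_labels))))
    stop("missing sex label for at least one sample in the depth table")
  if (!any(sex_labels == "M") || !any(sex_labels == "F"))
    stop("need at least one male and one female")
  depth_table$sex <- sex_labels[depth_table$sample]
  mode_depth <- function(x) {            # modal depth = autosomal level
    if (length(x) < 5) return(median(x))
    d <- density(x)
    d$x[which.max(d$y)]
  }
  sc_mean <- aggregate(depth ~ scaffold + sex, depth_table, mean)
  norm <- c(M = mode_depth(sc_mean$depth[sc_mean$sex == "M"]),
            F = mode_depth(sc_mean$depth[sc_mean$sex == "F"]))
  wide <- reshape(sc_mean, idvar = "scaffold", timevar = "sex",
                  direction = "wide")
  ratio <- (wide$depth.M / norm[["M"]]) / (wide$depth.F / norm[["F"]])
  cls <- rep("unknown", nrow(wide))
  cls[ratio >= 0.35 & ratio <= 0.65] <- "X"
  cls[ratio >= 0.85 & ratio <= 1.15] <- "autosome"
  cls[wide$depth.F < 0.05 * norm[["F"]]] <- "Y-like"
  scaffolds <- data.frame(scaffold = wide$scaffold, class = cls,
                          ratio = as.numeric(ratio),
                          stringsAsFactors = FALSE)
  ## PAR: autosome-like terminal windows on X scaffolds
  par_windows <- data.frame(scaffold = character(), start = numeric(),
                            end = numeric(), ratio = numeric())
  for (x_sc in scaffolds$scaffold[scaffolds$class == "X"]) {
    dt <- depth_table[depth_table$scaffold == x_sc, ]
    wm <- aggregate(depth ~ start + end + sex, dt, mean)
    ww <- reshape(wm, idvar = c("start", "end"), timevar = "sex",
                  direction = "wide")
    ww <- ww[order(ww$start), ]
    wr <- (ww$depth.M / norm[["M"]]) / (ww$depth.F / norm[["F"]])
    auto_like <- wr >= 0.85 & wr <= 1.15
    ## contiguous runs touching either scaffold end
    n <- nrow(ww)
    lead <- cumprod(auto_like) > 0
    trail <- rev(cumprod(rev(auto_like)) > 0)
    sel <- (lead | trail) & auto_like
    if (any(sel))
      par_windows <- rbind(par_windows,
        data.frame(scaffold = x_sc, start = ww$start[sel],
                   end = ww$end[sel], ratio = wr[sel]))
  }
  list(scaffolds = scaffolds, par_windows = par_windows)
}

#' Genome-average recombination rate from chromosome count
#'
#' Assumes one crossover per chromosome per generation, the standard
#' fallback when no genetic map exists: `r = n_chromosomes /
#' mapped_length` per bp per generation.
#'
#' @param n_chromosomes haploid chromosome number.
#' @param mapped_length total mapped genome length in bp.
#' @return recombination rate per bp per generation.
#' @export
genome_recombination_rate <- function(n_chromosomes, mapped_length) {
  stopifnot(n_chromosomes > 0, mapped_length > 0)
  n_chromosomes / mapped_length
}

#' Write a polarized site table as TSV
#'
#' @param table a `polarized_sites` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
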