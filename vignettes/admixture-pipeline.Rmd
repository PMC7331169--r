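---
title: "Models and methods behind admixscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind admixscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

admixscan implements the statistical machinery needed to detect a
recent pulse of gene flow between diverged populations, date it, mask
its traces, and separate it from signatures of selection and
demographic change. This vignette explains the models, the assumptions
they make, the tunable parameters, and the design choices taken where
the methodology was genuinely open.

## The single-pulse admixture model

All dating machinery rests on one generative model: an admixed
population received a fraction $m$ of its ancestry from a donor
population in a single generation, $t$ generations before present.
Recombination (rate $r$ per bp per generation) has since broken donor
haplotypes into tracts. Along a haploid genome, ancestry then behaves
as a two-state Markov chain: over a distance $d$ bp ancestry persists
with probability $e^{-r d t}$ and otherwise is redrawn Bernoulli($m$)
toward the donor. Donor tract lengths are therefore exponential with
rate $(1-m)\,r\,t$, which gives the method-of-moments inversion
$t = 1/((1-m)\,r\,\bar L)$ for the mean uncensored haploid donor tract
length $\bar L$.

Assumptions worth keeping in mind: a single pulse (continuous migration
produces a mixture of tract ages and biases $t$ downward); a uniform
recombination rate (no map exists for the target taxa, so $r$ comes
from `genome_recombination_rate()`, i.e. one crossover per chromosome
per generation); and free recombination between chromosomes.

### The local-ancestry HMM

`pulse_hmm_fit()` turns the chain above into a hidden Markov model over
ancestry-informative markers (AIMs). Haplotypes are not observed, so
the hidden state is the diploid donor **dosage** $\{0,1,2\}$, the
lumped product of two independent haploid chains — lumpability holds
because the two chains are exchangeable. Phase switching is not
modeled; this matches the pulse model and keeps the state space at
three.

Emissions come in two modes:

* **read counts** (default): alt reads $\sim$ Binomial(depth, $f_g$)
  with $f_g = \varepsilon + (g/2)(1-2\varepsilon)$ for genotype $g$,
  marginalized over $P(g \mid \text{dosage})$ from the panel
  frequencies; $\varepsilon$ is the per-read miscall probability
  (default 0.01);
* **genotypes**, when read counts are unavailable.

Panel frequencies estimated from finite panels are shrunk with a
Jeffreys prior, $(np + 0.5)/(n + 1)$, before entering the emissions;
raw frequencies of exactly 0 or 1 estimated from 16 alleles would
otherwise make single miscalls look like ancestry switches.

$t$ is profiled on a log-spaced grid over $[1, 2000]$ generations
(25 points) followed by golden-section refinement, maximizing over $m$
at each $t$ with a 1-D optimizer; the 1-D profile is robust and
reproducible, and the forward pass (Rcpp) makes it cheap. Confidence
intervals resample contiguous blocks of AIMs (default 5000 per block,
1000 replicates, percentile method) over a precomputed per-block
log-likelihood grid; treating blocks as independent is the usual block
bootstrap approximation. On down-scaled genomes the block size should
be reduced proportionally — the tests use 150–500 AIMs per block so
that 10–20 blocks exist.

### Tract calling and dating

`call_tracts()` reports maximal runs of markers with donor posterior
($P_1 + P_2$) at or above 0.8, with boundaries at inter-marker
midpoints (deterministic; the truth is unknowable between markers) and
censoring flags at chromosome ends. Because these tracts are unions of
two haploid chains, their mean length is the busy period of the lumped
on/off chain, $(2-m)/(2(1-m)^2 r t)$; `tract_time(level =
"diploid_union")` inverts that closed form, while `level = "haploid"`
applies the plain exponential inversion appropriate for haploid tracts
(e.g. simulator truth tracts).

### De-introgression

`mask_introgressed()` removes sites inside qualifying tracts and
absorbs clean gaps shorter than 3 sites between masked runs
(reconnection rule); `mask_genotypes()` applies this per sample, which
is the operation that precedes phylogenetic or demographic re-analysis
— each genome loses its own donor segments.

## Frequency-based ABBA-BABA statistics

`patterson_d()` uses derived-allele frequencies rather than binary
fixed patterns, which keeps low-frequency informative sites. Standard
errors resample contiguous 30-Mb blocks (bootstrap by default; the
delete-one block jackknife is provided as a cross-check and the test
suite verifies the two agree). Significance uses the normal
approximation for $z = D/\mathrm{SE}$, standard for this statistic.

`fd_windows()` normalizes the window-level numerator by its value under
complete introgression, substituting the donor frequency
$p_D = \max(p_2, p_3)$ per site. Windows with fewer than 10 informative
sites, window-level $D < 0$, or a zero denominator are *missing*, not
zero: the statistic is defined for the excess-sharing direction, and
zeros would dilute outlier quantiles.

One property of $f_d$ matters for interpretation and is quantified by
the acceptance run: with panel frequencies estimated from 8 diploids
per population, the expected value of $\max(\hat p_2, \hat p_3)$
exceeds the true maximum, inflating the denominator. The genome-mean
$f_d$ on the default synthetic conditions ($m = 0.36$) therefore comes
out around 0.30 — about 15% proportionally conservative — while at
$m = 0.1$ the estimator is nearly unbiased. The effect is a sample-size
property of the estimator, not of the implementation: rerunning the
statistic with the simulator's exact frequencies removes most of it.
Comparisons of $f_d$ between window sets (outlier scans, X-autosome
contrasts) are unaffected, because the bias is shared.

## Selection scans

Windowed $F_{ST}$ uses the Weir–Cockerham (1984) variance components
summed per window (ratio of sums, negative values retained); the Hudson
estimator is available and the suite checks the two correlate on
balanced designs. θπ uses $2p(1-p) \cdot n/(n-1)$ per site, reported
per variant site and per bp.

XP-EHH integrates the EHH decay outward from each core SNP by the
trapezoid rule in physical distance (no genetic map exists for the
target taxa), stopping at EHH < 0.05. EHH is defined as the haplotype
homozygosity of the *extension* — it equals 1 at the core — and the
decay is truncated (score missing) at chromosome ends and across
inter-SNP gaps larger than 200 kb, the standard guard against assembly
gaps inflating iHH. Scores are standardized genome-wide, not
frequency-binned. Core SNPs require pooled MAF ≥ 0.05. Region merging
follows the scan-specific rule: runs of significant SNPs tolerate one
embedded non-significant SNP, bounds extend half the distance to the
nearest flanking non-significant marker, and isolated significant SNPs
are discarded because genuine long-haplotype signals span several
markers.

## LD-based recent Ne and slope changes

`ldne_trajectory()` bins pairwise genotypic $r^2$ by physical distance,
subtracts the sample-size expectation ($1/n$ unphased, $1/(2n)$
phased), maps distance to recombination fraction $c$ with the Sved
formula $c = dr/(1+dr)$ (Haldane optional), and inverts
$E[r^2_{adj}] = 1/(\alpha + 4 N_e c)$ with $\alpha = 2.2$ when mutation
is modeled (2 otherwise). Each bin reports $t = 1/(2c)$ generations
before present; bins with fewer than 100 pairs, or where the estimator
is at/beyond its $1/\alpha$ boundary, are missing.

`nes_slopes()` regresses Ne on time-toward-present for the overall
slope and reports per-interval finite-difference slopes minus the
overall slope, so that a steady decline sits at 0, and intervals where
the decline steepens fall below 0. The suite validates localization by
injecting a one-bin acceleration into an otherwise linear trajectory.

`generations_to_years()` rounds half-up; `infer_generation_length()`
divides the elapsed years to an anchoring event (default 1529, with
2020 as the reference year — the publication-era present) by the
estimated generations.

## Phylogeny and discordance

P-distances generalize the uncorrected proportion-of-differences to
diploid genotypes: $d(i,j) = \sum |g_i - g_j| / (2 n_{called})$.
Neighbor joining and the site bootstrap come from `ape`; inputs should
be thinned to one SNP per 250-bp bin (`thin_snps()` keeps the *first*
SNP per bin — deterministic and order-stable).

`quartet_ils()` is deliberately a light proxy for full coalescent-HMM
discordance analysis: per window it applies the four-point condition to
taxon-level frequency distances and tallies the three unrooted
topologies (windows with a relative margin below 1% are ambiguous).
Its proportions are comparable in *sign and ordering* — an excess of
the donor-pairing minor topology indicates admixture — but not in
absolute value to coalescent-model posteriors.

## The synthetic-data generator

`simulate_panels()` draws a shared ancestral derived-allele frequency
$p \sim U(0.05, 0.95)$ per site and panel frequencies from the
Balding–Nichols model $\mathrm{Beta}(p(1-F)/F, (1-p)(1-F)/F)$ with
drift $F = 0.5$ per panel by default, which yields a realized fraction
of strongly differentiated sites (|Δp| ≥ 0.5) of about 0.27 — dense
enough to emulate AIM panels between long-separated wild progenitors.
The outgroup is fixed ancestral at 95% of sites and polymorphic at the
rest, exercising the polarization filters. `simulate_admixed_cohort()`
simulates ancestry-switch breakpoints as a Poisson process at rate
$rt$ per bp with Bernoulli($m$) redraws — exactly the process the HMM
assumes — records merged truth tracts, then draws alleles from the
local ancestry's panel frequency and read counts as Poisson depth with
binomial alt reads. Haplotypes within a diploid are independent
chains, matching the HMM's composite-dosage assumption.

What the generator does **not** emulate: linkage disequilibrium within
panels (sites are independent given frequencies), a proper coalescent
genealogy (so absolute quartet-discordance levels are not meaningful,
only their asymmetry), selection, gene conversion, variable
recombination, or genotype-calling error beyond read miscalls. Passing
parameter-recovery tests therefore demonstrates correctness of the
inference machinery under its own model assumptions, not robustness to
everything real data can do. The Wright–Fisher forward simulator
(`simulate_wf_cohort()`) fills one of those gaps for the LD analyses:
it produces genuine drift-recombination-mutation LD from a
constant-size population, which `ldne_trajectory()` must recover within
broad tolerance.

## Problem sizes and numerical choices

The test and acceptance runs use a 5 × 20 Mb genome with 8 diploids
per population (about 100k sites, 7–8k AIMs) for the headline recovery,
3 × 10 Mb genomes across 20 seeds for bootstrap-coverage checks, a
600-SNP/6-Mb toy for sweep recovery, and $N_e = 100$ Wright–Fisher
populations of 5000 sites for LD recovery — sizes chosen so the whole
validation runs in minutes while every statistic still has enough
support to be meaningfully tested. Forward-backward recursions are
scaled (not log-space) for speed, with per-site renormalization;
posterior rows sum to 1 within 1e−9. Zero-emission sites raise an
error naming the marker rather than silently propagating `-Inf`.
Frequency comparisons against the 0.5 AIM threshold use a 1e−9
tolerance so that decimal inputs behave as written. The outgroup
"fixedness" tolerance is 0.05 on either side, tolerating outgroup
sequencing error.

## Known limitations

* Single-pulse only; no multi-pulse or continuous-migration models.
* No statistical phasing: phased input is used when present (the
  simulator provides truth phase); XP-EHH requires it.
* $f_d$ is conservative at small panel sizes (quantified above).
* Bootstrap CIs for $t$ are percentile intervals over a finite
  (m, t) grid; with very few blocks they undercover, so block size
  should scale with the genome analysed.
* PAR detection requires windowed depth input; only terminal
  autosome-like runs on X scaffolds are flagged.
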