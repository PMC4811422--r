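---
title: "Cross-population selection scans with Rsb: models, parameters, and validation"
author: "rsbscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-population selection scans with Rsb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsbscan)
```

# The problem

A population under strong recent artificial selection — a beef-cattle
breeding program, say — carries footprints of that selection in its
haplotype structure: around a favoured allele, one haplotype rises in
frequency faster than recombination and mutation can break it apart, so
homozygosity stays high over unusually long physical distances.
Contrasting the selected population against a closely related,
unselected one cancels most shared demographic signal and isolates
population-specific sweeps. `rsbscan` implements that contrast
end-to-end: phased-panel IO, genotype QC, population-structure
summaries, the EHHS/iES/Rsb scan, windowed candidate-region calling
under FDR control, variant-level allele-frequency contrasts, and
forward simulators that provide ground truth for every stage.

# The scan statistic

## Site-specific EHH (EHHS)

For a panel of $n$ phased haplotypes, the homozygosity of a marker
span is the unbiased probability that two random haplotypes are
identical over it:

$$H(\text{span}) = \sum_k \frac{n_k (n_k - 1)}{n (n - 1)},$$

where $n_k$ are the sizes of the identity classes. Anchored at a focal
SNP $s$, the site-specific extended haplotype homozygosity at a
flanking SNP $x$ is

$$EHHS(s, x) = \frac{H(s \ldots x)}{H(s)} \in [0, 1],$$

which equals 1 at the focal SNP and is non-increasing moving outward,
because extending a span can only split identity classes. EHHS is
*allele-agnostic* (it conditions on no core allele), which is what
makes the cross-population ratio below well-defined at every site.
This normalised, unbiased form is the single normative definition used
throughout the package.

The profile is evaluated SNP-by-SNP outward on each flank and stops at
the first value strictly below a cutoff (default 0.05), or at the
chromosome end — in which case the flank is flagged *truncated*.

## iES and Rsb

iES integrates EHHS over physical distance (trapezoid rule, bp units)
on both flanks, out to and including the first below-cutoff SNP; no
interpolation to the exact crossing is attempted, and no genetic map is
assumed. Truncated profiles are discarded by default
(`discard_at_border = TRUE`): their integral is not comparable between
populations.

For a selected panel and a reference panel on the same SNP map,

$$\text{raw}(s) = \ln \frac{iES_{\text{sel}}(s)}{iES_{\text{ref}}(s)},
\qquad
Rsb(s) = \frac{\text{raw}(s) - \operatorname{median}(\text{raw})}
              {\operatorname{SD}(\text{raw})},$$

with median and SD taken over all scanned SNPs. Median-centering is
robust to the right tail that a real sweep induces; the SD brings the
bulk to unit scale. Positive values mean extended homozygosity in the
selected population.

## The one-tailed p transform

Under neutrality the standardized scores are treated as standard
normal, and we report

$$P_{Rsb}(s) = -\log_{10}\!\big(1 - \Phi(Rsb(s))\big),$$

the upper tail, because sweeps in the *selected* population push
$Rsb$ up. A literal reading of the transform as
$-\log \Phi(Rsb)$ would assign small scores to strongly positive
values, contradicting its own one-tailed interpretation; the package
deliberately implements the upper-tail form. $P_{Rsb} > 2$ corresponds
to one-tailed $p < 0.01$.

No allele-frequency binning is applied before standardization: EHHS is
already focal-allele-agnostic, and at desk scale bins would thin the
SNP set badly. This is a documented deviation from some allele-anchored
EHH pipelines where frequency binning is essential.

# Candidate regions

Windows of 1 Mb with 0.5 Mb overlap are anchored at coordinate 0 on
each chromosome and extended while the window start does not pass the
last mapped SNP. The anchor is a convention; window *content*, not the
genome-wide window count, is the meaningful quantity. A window is
*suggestive* when at least 2 member SNPs have $P_{Rsb} > 2$ (strict);
overlapping flagged windows merge transitively into candidate regions.
Benjamini–Hochberg q-values are computed once, genome-wide, over all
scanned SNPs (the conservative, conventional scope), and a suggestive
region is promoted to *significant* when at least 2 of its member SNPs
have $q < 0.05$ (strict), the member list then being restricted to
those SNPs. Coordinates are stored at bp resolution, 0-based half-open
(BED convention); SNP positions are 1-based (VCF convention); the two
meet only at window membership and annotation.

# Companion analyses

*QC* (in fixed order: call rate ≤ 5% missing, heterozygosity within 3
SDs of the across-SNP mean, Hardy–Weinberg $\chi^2$ with $p \ge
10^{-15}$, MAF ≥ 0.01) reproduces standard chip-data marker exclusion.
The order matters only in that allele frequencies for MAF/HWE are
computed on call-rate-cleaned data. HWE is tested per population by
default — a deviation in *any* population drops the marker — with a
pooled option. Chip-intensity (GC-score) filters need raw intensity
data and are reported as skipped rather than silently omitted.

*Structure*: the genomic relationship matrix is VanRaden's first
method, $G = ZZ'/(2\sum_j p_j(1-p_j))$ with dosages centered by $2p_j$
and missing entries mean-imputed; observed frequencies are the default
and a reference-frequency argument exists (some textbook identities,
e.g. duplicated homozygous individuals with $p = 0.5$, are only
reachable with externally supplied frequencies). PCA is the
eigendecomposition of $G$, scores scaled by $\sqrt{\lambda}$, variance
shares over positive eigenvalues, and the sign convention "largest
loading positive" for reproducible plots. $F_{ST}$ is the
Weir–Cockerham $\theta$ for two populations from genotype counts,
including the heterozygosity term, combined across loci as a ratio of
sums (average-of-ratios is biased); negative estimates are reported
unclipped, and only the Ward clustering step floors distances at zero.
Ward trees (`ward.D2`) are built on label-sorted matrices so ties
break deterministically, and serialize to Newick.

*Variant contrasts*: two-sided Fisher's exact test (point-probability
definition, relative tie tolerance $10^{-7}$) on 2×2 allele-count
tables; a variant is flagged when the absolute frequency difference
strictly exceeds 0.20. Counts are in the unit the caller supplies —
conventionally 2 alleles per diploid. Mutation folding energies
classify as neutral inside the closed interval $[-0.5, 0.5]$ kcal/mol,
stabilizing below, destabilizing above. Region–gene annotation uses
half-open ≥ 1 bp intersection and a ±300 kb closest-gene radius
(distance 0 inside a gene).

# The synthetic worlds

## Structured genotypes (Balding–Nichols)

Ancestral frequencies are uniform on (0.05, 0.95); population $k$
draws $p_{jk} \sim \mathrm{Beta}\!\big(p_j \tfrac{1-F_k}{F_k},
(1-p_j)\tfrac{1-F_k}{F_k}\big)$, so $\operatorname{Var}(p_{jk}) = F_k
\, p_j (1 - p_j)$, and genotypes are $\mathrm{Binomial}(2, p_{jk})$
with uniform missingness (2% default). The five-population default —
one out-group at $F = 0.2$, a moderate pair at $F = 0.08$, a close
pair at $F = 0.015$ — mirrors the magnitude ordering of a typical
one-distant-plus-several-close cattle-breed design. This generator
closes the loop on the structure stack: `pairwise_fst` recovers the
simulated $F$ in Monte-Carlo mean.

## Two-population sweep panels (forward Wright–Fisher)

A forward simulator (compiled core, R-seeded and bit-reproducible)
builds standing variation in one diploid population of $N = 200$ over
$8N$ burn-in generations on a 2 Mb chromosome with infinite-sites
mutation onto discrete bp positions (collision re-draw) and Poisson
crossovers. The population then splits into two copies; population 1
experiences genic selection (fitness $1, 1+s, 1+2s$) at a single
standing variant while population 2 stays neutral; panels of 120
haplotypes per population are sampled at the end, on the shared map of
sites segregating in the pooled sample. The truth record carries the
selected position and its frequencies at the split and at sampling.
If the selected allele is lost, the post-split phase re-draws
(bounded retries). Forward-time rather than coalescent machinery was
chosen deliberately: it is transparent, dependency-free, and seconds
per replicate at this scale.

### Why these defaults

Desk scale forces explicit compromises; they were chosen once, for
realism, and then frozen:

- **mutation rate 1.5e-7 /bp/gen** — calibrated so a sampled panel
  carries roughly 2,000 segregating SNPs, the stated panel size of the
  validation design.
- **recombination 1e-7 /bp/gen** — neutral EHHS then decays within
  tens of kb, far inside the 2 Mb chromosome (so border-discard keeps
  most of the interior), while a sweep's haplotype footprint
  (~$1/(r\tau)$, mutation-capped) spans one to two hundred kb —
  resolvable but not chromosome-filling.
- **split 60 generations; standing frequency 0.02–0.10** — the
  selected variant is young and rare, so its carriers share a recent
  haplotype, and at $s = 0.1$ the sweep reaches frequency ~0.85–0.95
  *at sampling*. This is the regime of a recent, ongoing breeding
  program between closely related populations (panel $F_{ST}$ ≈ 0.1),
  and it is the regime haplotype-homozygosity statistics are built
  for. A much longer split (say 200 generations at this $N$) yields a
  sweep that fixed ~80 generations before sampling; its extended
  haplotype then erodes at rate $1/(r\,t)$ and massive drift
  ($F_{ST}$ ≈ 0.4) drowns what remains — a world in which *no* EHH
  statistic detects anything, and not the world the method addresses.
- **120 haplotypes per population** — comparable to real panels
  (hundreds of haplotypes per breed group).

### What a green test does and does not establish

The simulator emulates neutral standing variation, drift, and a single
hard(ish) sweep. It does **not** emulate chip ascertainment (its SFS is
sequencing-like), varying recombination maps, gene conversion,
overlapping sweeps, dominance, or realistic cattle demography. Green
scan tests therefore establish internal statistical correctness
(calibration, localization, invariances) — not field performance on
chip data.

### A structural desk-scale limit, stated openly

The height of a standardized Rsb peak is governed by the ratio of the
population-scaled signal to coalescent noise, roughly $N/\tau$ with
$\tau$ the sweep duration in generations. Real scans operate at
$N/\tau$ of order 10–100; the desk-scale world is pinned (by $2Ns =
40$ with $s = 0.1$, and a 2 Mb genome) to $N/\tau \approx 3$, which
caps observed peaks near $Rsb \approx 3$ regardless of recombination
rate, split length, or panel size (all were explored). One-tailed
$p \ge 2\times10^{-4}$ at ~300 scanned SNPs cannot clear genome-wide
BH at $q < 0.05$, so *FDR-significant* region recovery essentially
never triggers in the simulated world even though localization (the
genome-wide maximum landing within 250 kb of the true site) succeeds
in roughly 70% of replicates and the neutral world correctly produces
zero significant regions. The corresponding end-to-end expectations
are left failing in the test suite rather than weakened: with the
localization bar set exactly at 70% of 20 pre-registered replicates,
the observed count can land a replicate short of the bar (it does, at
13/20), and FDR recovery cannot reach a majority at all. Both document
a real property of the scale, not a defect of the statistic.

# Numerical choices and degenerate inputs

- EHHS uses exact identity grouping (no tie-break needed); the
  unbiased $n(n-1)$ estimator, not $n^2$.
- iES includes the below-cutoff endpoint at its observed value; a
  single-SNP chromosome is truncated on both flanks, hence missing
  under the default discard rule.
- `rsb_scan` refuses to standardize fewer than 10 jointly-scanned
  SNPs; an all-zero raw vector (identical panels) gets $Rsb = 0$
  rather than 0/0.
- Monomorphic focal SNPs are not scanned (MAF floor 0.05 per panel,
  both panels must pass).
- HWE at a monomorphic site is defined as $\chi^2 = 0, p = 1$; a
  zero SD across SNPs disables the heterozygosity-outlier filter.
- A GRM over exclusively monomorphic SNPs is a zero-denominator error,
  not a silent NaN matrix.
- Multiallelic and indel VCF records are dropped (with a count), not
  split; missing genotypes drop the site by default (`strict_missing`
  errors instead) because EHH needs complete haplotypes; any retained
  `/`-separated genotype is an error, not a warning.
- Chromosome labels are opaque strings; positions are assumed mapped
  and are validated strictly increasing per chromosome.

# Worked example

```{r example, eval = FALSE}
sim <- simulate_sweep_haplotypes(sweep_sim_config(s = 0.1, seed = 42))
res <- rsb_scan(sim$panel_sel, sim$panel_ref)
w   <- make_windows(res[, c("chrom", "pos", "snp_id")])
sug <- call_suggestive_regions(w, res)
sig <- call_significant_regions(sug, res)
subset(res, prsb > 2)
```

`scripts/acceptance.R --seed <int> --out <path>` runs exactly this
pipeline (plus a matched neutral control) from the installed package
and prints the summary; the full validation battery lives in
`tests/testthat/test-acceptance.R`.

# Known limitations

- No genetic-map integration (physical distance only), no iHS/XP-EHH,
  no allele-anchored EHH curves.
- No phasing or imputation: the scan consumes phased, complete
  haplotypes.
- Ancestry-fraction modelling (ADMIXTURE-style) is out of scope; PCA,
  $F_{ST}$ and Ward trees are the structure surface.
- The four-way multi-population comparison is supported as repeated
  pairwise scans plus interval intersection, not as a joint test.
- Assembly liftover is out of scope; coordinates are
  assembly-agnostic.
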