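## Marker quality control: call rate, heterozygosity outliers,
## Hardy-Weinberg, minor allele frequency.
##
## Filter order in the composite is fixed (call-rate -> het-outlier ->
## HWE -> MAF) so that allele frequencies entering MAF/HWE are computed
## on call-rate-cleaned data.  Chip-intensity (GC score) filters are not
## applicable without raw intensity data and are reported as skipped.

site_missing_frac <- function(g) colMeans(is.na(g$dosage))

site_alt_freq <- function(g) colMeans(g$dosage, na.rm = TRUE) / 2

site_het_frac <- function(g) colMeans(g$dosage == 1, na.rm = TRUE)

#' Call-rate filter
#'
#' Keep SNPs whose fraction of missing genotypes is at most
#' `max_missing` (boundary inclusive).
#'
#' @param g a [genotype_matrix()].
#' @param max_missing maximum tolerated missing fraction (default 0.05,
#'   i.e. drop SNPs failing in more than 5% of individuals).
#' @return Integer vector of kept SNP column indices.
#' @export
site_call_rate_filter <- function(g, max_missing = 0.05) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  unname(which(site_missing_frac(g) <= max_missing))
}

#' Minor-allele-frequency filter
#'
#' Keep SNPs with MAF (over non-missing alleles) at least `min_maf`;
#' monomorphic SNPs are dropped for any positive threshold.
#'
#' @param g a [genotype_matrix()].
#' @param min_maf minimum minor allele frequency (default 0.01).
#' @return Integer vector of kept SNP column indices.
#' @export
maf_filter <- function(g, min_maf = 0.01) {
  stopifnot(min_maf >= 0, min_maf <= 0.5)
  p <- site_alt_freq(g)
  maf <- pmin(p, 1 - p)
  unname(which(!is.na(maf) & maf >= min_maf))
}

#' Hardy-Weinberg chi-square test
#'
#' 1-df goodness-of-fit of observed genotype counts against
#' Hardy-Weinberg expectations at the observed allele frequency.
#' Monomorphic sites are defined as perfectly conforming (statistic 0,
#' p = 1).
#'
#' @param nAA,nAa,naa genotype counts (hom ref, het, hom alt).
#' @return `list(chi2 = , p = )`.
#' @export
hwe_chi2_test <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  stopifnot(n >= 1, nAA >= 0, nAa >= 0, naa >= 0)
  p <- (2 * nAA + nAa) / (2 * n)
  if (p == 0 || p == 1) return(list(chi2 = 0, p = 1))
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(nAA, nAa, naa) - e)^2 / e)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Heterozygosity-outlier filter
#'
#' Keep SNPs whose observed heterozygote fraction lies within `k_sd`
#' standard deviations of the mean heterozygosity across all SNPs.
#'
#' @param g a [genotype_matrix()] (at least 2 SNPs).
#' @param k_sd SD multiplier (default 3); with zero SD across SNPs all
#'   SNPs are kept.
#' @return Integer vector of kept SNP column indices.
#' @export
het_outlier_filter <- function(g, k_sd = 3) {
  stopifnot(ncol(g$dosage) >= 2)
  h <- site_het_frac(g)
  s <- sd(h, na.rm = TRUE)
  if (is.na(s) || s == 0) return(seq_along(h))
  unname(which(abs(h - mean(h, na.rm = TRUE)) <= k_sd * s))
}

subset_snps <- function(g, idx) {
  m <- g$map[idx, , drop = FALSE]
  class(m) <- c("snp_map", "data.frame")
  structure(list(dosage = g$dosage[, idx, drop = FALSE], map = m,
                 sample_pop = g$sample_pop),
            class = "genotype_matrix")
}

subset_inds <- function(g, keep) {
  structure(list(dosage = g$dosage[keep, , drop = FALSE], map = g$map,
                 sample_pop = g$sample_pop[keep]),
            class = "genotype_matrix")
}

hwe_p_per_site <- function(g) {
  d <- g$dosage
  vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(1)
    hwe_chi2_test(sum(x == 0), sum(x == 1), sum(x == 2))$p
  }, numeric(1))
}

#' Composite marker QC
#'
#' Applies, in order: call-rate, heterozygosity-outlier, Hardy-Weinberg
#' and MAF filters, each on the survivors of the previous step.  HWE is
#' tested per population by default (a SNP failing in any population is
#' dropped); `pooled = TRUE` tests all individuals jointly.
#'
#' @param g a [genotype_matrix()].
#' @param max_missing,min_maf,hwe_p,het_sd filter thresholds; defaults
#'   0.05, 0.01, 1e-15 and 3.
#' @param pooled test HWE on the pooled sample instead of per population.
#' @return `list(kept = integer indices into the original map,
#'   report = data.frame(snp_id, reason) for dropped SNPs,
#'   skipped = character vector of filters that could not run)`.
#' @export
qc_filter <- function(g, max_missing = 0.05, min_maf = 0.01,
                      hwe_p = 1e-15, het_sd = 3, pooled = FALSE) {
  report <- list()
  idx <- seq_len(ncol(g$dosage))

  k <- site_call_rate_filter(g, max_missing)
  report$call_rate <- g$map$snp_id[setdiff(seq_along(idx), k)]
  idx <- idx[k]
  gk <- subset_snps(g, k)

  k <- het_outlier_filter(gk, het_sd)
  report$het_outlier <- gk$map$snp_id[setdiff(seq_len(ncol(gk$dosage)), k)]
  idx <- idx[k]
  gk <- subset_snps(gk, k)

  if (pooled) {
    fail <- hwe_p_per_site(gk) < hwe_p
  } else {
    fail <- rep(FALSE, ncol(gk$dosage))
    for (pop in unique(gk$sample_pop))
      fail <- fail | hwe_p_per_site(subset_inds(gk, gk$sample_pop == pop)) < hwe_p
  }
  k <- which(!fail)
  report$hwe <- gk$map$snp_id[fail]
  idx <- idx[k]
  gk <- subset_snps(gk, k)

  k <- maf_filter(gk, min_maf)
  report$maf <- gk$map$snp_id[setdiff(seq_len(ncol(gk$dosage)), k)]
  idx <- idx[k]

  rep_df <- data.frame(
    snp_id = unlist(report, use.names = FALSE),
    reason = rep(names(report), lengths(report)),
    stringsAsFactors = FALSE)
  list(kept = idx, report = rep_df,
       skipped = "gc_score (chip intensity data unavailable)")
}
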