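## Variant-level follow-up: population allele-frequency contrasts with
## Fisher's exact test, mutation-energy classification, and
## region/feature annotation (>= 1 bp intersections and closest genes
## within a bp radius).

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p by the point-probability method: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose point probability does not exceed that of the observed table
#' (relative tolerance 1e-7 for floating-point ties).
#'
#' @param a,b,c,d non-negative integer cell counts, `rbind(c(a, b),
#'   c(c, d))`; total must be positive.
#' @return Two-sided p-value in `(0, 1]`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) == 0) stop("table total must be positive")
  fisher.test(matrix(cells, nrow = 2L, byrow = TRUE))$p.value
}

#' Allele-frequency contrast between two populations
#'
#' Builds the 2x2 alt/ref allele-count table per variant, computes alt
#' frequencies, their absolute difference, the two-sided Fisher exact
#' p-value, and flags variants whose frequency difference strictly
#' exceeds `freq_threshold`.  Counts are in whatever unit the caller
#' supplies -- conventionally alleles (two per diploid individual);
#' passing carrier counts instead yields the genotype-based variant of
#' the test.
#'
#' @param altA,totalA alt-allele count and total allele count in
#'   population A (vectors allowed).
#' @param altB,totalB same for population B.
#' @param freq_threshold flagging threshold on the absolute frequency
#'   difference (default 0.20, strict: "more than 20%").
#' @param variant_id optional identifiers.
#' @return A `data.frame` of class `variant_contrast`: `variant_id`,
#'   `alt_A`, `total_A`, `freq_A`, `alt_B`, `total_B`, `freq_B`,
#'   `freq_diff`, `p`, `flagged`.
#' @export
allele_contrast <- function(altA, totalA, altB, totalB,
                            freq_threshold = 0.20, variant_id = NULL) {
  stopifnot(length(altA) == length(altB), totalA >= 2, totalB >= 2,
            altA <= totalA, altB <= totalB)
  n <- length(altA)
  totalA <- rep_len(totalA, n)
  totalB <- rep_len(totalB, n)
  if (is.null(variant_id)) variant_id <- paste0("variant", seq_len(n))
  fA <- altA / totalA
  fB <- altB / totalB
  p <- vapply(seq_len(n), function(i)
    fisher_exact_2x2(altA[i], totalA[i] - altA[i],
                     altB[i], totalB[i] - altB[i]), numeric(1))
  out <- data.frame(variant_id = variant_id,
                    alt_A = altA, total_A = totalA, freq_A = fA,
                    alt_B = altB, total_B = totalB, freq_B = fB,
                    freq_diff = abs(fA - fB), p = p,
                    flagged = abs(fA - fB) > freq_threshold,
                    stringsAsFactors = FALSE)
  class(out) <- c("variant_contrast", "data.frame")
  out
}

#' Classify a mutation's folding-energy effect
#'
#' Total folding free-energy difference (mutant minus wild type) in
#' kcal/mol: `neutral` within the closed interval [-0.5, 0.5],
#' `stabilizing` below -0.5, `destabilizing` above 0.5.
#'
#' @param energy mutation energy value(s) in kcal/mol.
#' @return Character vector of `"stabilizing"`, `"neutral"` or
#'   `"destabilizing"`.
#' @export
classify_mutation_energy <- function(energy) {
  stopifnot(is.finite(energy))
  ifelse(energy < -0.5, "stabilizing",
         ifelse(energy > 0.5, "destabilizing", "neutral"))
}

#' Intersect two interval sets (>= 1 bp overlap)
#'
#' All region/feature pairs overlapping by at least one base under
#' 0-based half-open semantics (touching intervals do not overlap).
#'
#' @param regions,features [feature_set()]s (a `candidate_regions`
#'   data frame is accepted for `regions`).
#' @return `data.frame` with `region_idx`, `feature_idx` (row indices
#'   into the inputs), `region_name`, `feature_name`, `overlap_bp`.
#' @export
intersect_features <- function(regions, features) {
  if (!inherits(regions, "feature_set") && "status" %in% names(regions))
    regions <- regions_to_features(regions)
  empty <- data.frame(region_idx = integer(), feature_idx = integer(),
                      region_name = character(), feature_name = character(),
                      overlap_bp = numeric(), stringsAsFactors = FALSE)
  if (nrow(regions) == 0L || nrow(features) == 0L) return(empty)
  gr_r <- fs_to_granges(regions)
  gr_f <- fs_to_granges(features)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr_r, gr_f, minoverlap = 1L))
  if (length(hits) == 0L) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(IRanges::pintersect(gr_r[qi], gr_f[si]))
  data.frame(region_idx = qi, feature_idx = si,
             region_name = regions$name[qi],
             feature_name = features$name[si],
             overlap_bp = ov, stringsAsFactors = FALSE)
}

#' Features within a distance of each SNP
#'
#' For each SNP, the features whose interval lies within `max_dist` bp
#' of the SNP position (distance 0 if the SNP falls inside the
#' feature).
#'
#' @param snps a [snp_map()].
#' @param features a [feature_set()].
#' @param max_dist inclusion radius in bp (default 300 kb).
#' @return `data.frame` with `snp_id`, `feature_idx`, `feature_name`,
#'   `distance`.
#' @export
closest_features_within <- function(snps, features, max_dist = 3e5) {
  stopifnot(max_dist >= 0)
  empty <- data.frame(snp_id = character(), feature_idx = integer(),
                      feature_name = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(snps) == 0L || nrow(features) == 0L) return(empty)
  gr_s <- GenomicRanges::GRanges(
    seqnames = snps$chrom,
    ranges = IRanges::IRanges(start = snps$pos, end = snps$pos))
  gr_f <- fs_to_granges(features)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr_s, gr_f, maxgap = max_dist))
  if (length(hits) == 0L) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  d <- suppressWarnings(GenomicRanges::distance(gr_s[qi], gr_f[si]))
  keep <- !is.na(d) & d <= max_dist
  data.frame(snp_id = snps$snp_id[qi][keep], feature_idx = si[keep],
             feature_name = features$name[si][keep],
             distance = d[keep], stringsAsFactors = FALSE)
}
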