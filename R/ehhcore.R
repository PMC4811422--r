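## The scan statistic: site-specific EHH decay (EHHS), its
## physical-distance integral per population (iES), the standardized
## cross-population log-ratio Rsb and its one-tailed -log10 p transform.
##
## EHHS here is the allele-agnostic (site-specific) homozygosity ratio:
## the probability that two random haplotypes are identical over the
## span anchored at the focal SNP, normalised by the same probability at
## the focal SNP alone, with the unbiased n(n-1) pairwise estimator.
## This is the single normative definition used throughout; Rsb is
## built on it.

#' Haplotype homozygosity over a SNP span
#'
#' Groups haplotypes by exact identity over the inclusive index span and
#' returns the unbiased pairwise identity probability
#' `sum_k n_k (n_k - 1) / (n (n - 1))`.
#'
#' @param panel a [haplotype_panel()] with at least 2 haplotypes.
#' @param snp_span inclusive SNP index range `c(from, to)` (or a single
#'   index).
#' @return Value in `[0, 1]`.
#' @export
haplotype_homozygosity <- function(panel, snp_span) {
  a <- panel$alleles
  n <- nrow(a)
  stopifnot(n >= 2)
  if (length(snp_span) == 1L) snp_span <- c(snp_span, snp_span)
  idx <- seq(min(snp_span), max(snp_span))
  if (length(idx) == 0L || min(idx) < 1L || max(idx) > ncol(a))
    stop("empty or out-of-range SNP span")
  key <- apply(a[, idx, drop = FALSE], 1L, paste, collapse = "")
  cnt <- table(key)
  sum(cnt * (cnt - 1)) / (n * (n - 1))
}

#' Site-specific EHH decay profile
#'
#' Evaluates `EHHS(focal, x) = H(focal..x) / H(focal)` at successive
#' flanking SNPs outward from the focal SNP, stopping on each flank when
#' the value drops strictly below `cutoff` (that point is kept) or the
#' chromosome end is reached (which sets the flank's truncation flag).
#'
#' @param panel a [haplotype_panel()] on a single chromosome.
#' @param focal focal SNP column index (must be polymorphic).
#' @param cutoff EHHS stopping threshold (default 0.05).
#' @return An object of class `ehhs_profile`: `focal_index`, `positions`
#'   (ascending bp over both flanks, focal included), `ehhs` aligned to
#'   `positions`, and `truncated_left`/`truncated_right` flags.
#' @export
ehhs_profile <- function(panel, focal, cutoff = 0.05) {
  a <- panel$alleles
  stopifnot(focal >= 1, focal <= ncol(a))
  if (length(unique(panel$map$chrom)) > 1L)
    stop("ehhs_profile expects a single-chromosome panel")
  f <- mean(a[, focal])
  if (f == 0 || f == 1) stop("focal SNP is monomorphic")
  w <- .ehhs_walk_cpp(a, focal - 1L, cutoff)
  idx <- c(rev(w$left_idx), focal - 1L, w$right_idx) + 1L
  vals <- c(rev(w$left_ehhs), 1, w$right_ehhs)
  structure(list(focal_index = focal,
                 snp_index = idx,
                 positions = panel$map$pos[idx],
                 ehhs = vals,
                 truncated_left = w$truncated_left,
                 truncated_right = w$truncated_right),
            class = "ehhs_profile")
}

#' @export
print.ehhs_profile <- function(x, ...) {
  cat("ehhs_profile: focal SNP", x$focal_index, "at",
      x$positions[x$snp_index == x$focal_index], "bp;",
      length(x$positions), "evaluated SNPs; truncated L/R:",
      x$truncated_left, "/", x$truncated_right, "\n")
  invisible(x)
}

#' Integrate an EHHS profile into iES
#'
#' Trapezoid rule over bp positions on each flank, from the focal SNP
#' out to the first SNP strictly below `cutoff` (that endpoint
#' contributes with its observed EHHS value; no interpolation to the
#' crossing).  Left and right areas are summed.  A profile that hit a
#' chromosome end while still above the cutoff is discarded (returns
#' `NA`) when `discard_at_border` is set.
#'
#' @param profile an [ehhs_profile()].
#' @param cutoff same threshold used to build the profile.
#' @param discard_at_border drop border-truncated profiles (default
#'   `TRUE`).
#' @return iES in bp-weighted EHHS units, or `NA`.
#' @export
integrate_ies <- function(profile, cutoff = 0.05, discard_at_border = TRUE) {
  if (discard_at_border &&
      (profile$truncated_left || profile$truncated_right))
    return(NA_real_)
  p <- profile$positions
  e <- profile$ehhs
  k <- which(profile$snp_index == profile$focal_index)
  area <- 0
  for (side in list(rev(seq_len(k)), seq(k, length(p)))) {
    pp <- p[side]; ee <- e[side]
    below <- which(ee < cutoff)
    last <- if (length(below)) below[1L] else length(ee)
    if (last >= 2L) {
      i <- seq_len(last - 1L)
      area <- area + sum((ee[i] + ee[i + 1L]) / 2 * abs(pp[i + 1L] - pp[i]))
    }
  }
  area
}

ies_track_one_chrom <- function(alleles, pos, cutoff, maf_floor,
                                discard_at_border) {
  .ies_scan_cpp(alleles, as.numeric(pos), cutoff, maf_floor,
                discard_at_border)
}

#' Per-SNP iES track for one panel
#'
#' @param panel a [haplotype_panel()].
#' @param cutoff EHHS stopping threshold (default 0.05).
#' @param maf_floor minimum focal minor allele frequency to evaluate a
#'   SNP (default 0.05).
#' @param discard_at_border drop border-truncated profiles (default
#'   `TRUE`).
#' @return Numeric vector of iES per SNP (`NA` where not evaluated).
#' @export
ies_track <- function(panel, cutoff = 0.05, maf_floor = 0.05,
                      discard_at_border = TRUE) {
  out <- rep(NA_real_, nrow(panel$map))
  for (ch in unique(panel$map$chrom)) {
    j <- which(panel$map$chrom == ch)
    out[j] <- ies_track_one_chrom(panel$alleles[, j, drop = FALSE],
                                  panel$map$pos[j], cutoff, maf_floor,
                                  discard_at_border)
  }
  out
}

#' One-tailed -log10 p transform of standardized Rsb
#'
#' `P = 1 - Phi(rsb_std)` (upper tail: positive scores mean extended
#' homozygosity in the selected population), reported as `-log10(P)`.
#'
#' @param rsb_std standardized Rsb value(s).
#' @return `prsb` value(s), `>= 0`.
#' @export
prsb_transform <- function(rsb_std) {
  -pnorm(rsb_std, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Cross-population Rsb scan
#'
#' Computes per-SNP iES in the selected and reference panels, the raw
#' log-ratio `ln(iES_sel / iES_ref)`, its median-centered SD-scaled
#' standardization `rsb_std`, the one-tailed `prsb` transform and
#' Benjamini-Hochberg q-values over all scanned SNPs.  Positive
#' `rsb_std` indicates extended haplotype homozygosity in the selected
#' population.
#'
#' @param panel_sel,panel_ref [haplotype_panel()]s sharing an identical
#'   SNP map.
#' @param cutoff,maf_floor,discard_at_border scan parameters, see
#'   [ies_track()].
#' @return A `data.frame` of class `rsb_result` with one row per mapped
#'   SNP: `chrom`, `pos`, `snp_id`, `ies_sel`, `ies_ref`, `raw`,
#'   `rsb_std`, `prsb`, `q` (`NA` at SNPs not scanned in both panels).
#' @export
rsb_scan <- function(panel_sel, panel_ref, cutoff = 0.05, maf_floor = 0.05,
                     discard_at_border = TRUE) {
  m1 <- panel_sel$map; m2 <- panel_ref$map
  if (!identical(m1$chrom, m2$chrom) || !identical(m1$pos, m2$pos) ||
      !identical(m1$snp_id, m2$snp_id))
    stop("panels must share an identical SNP map")
  ies1 <- ies_track(panel_sel, cutoff, maf_floor, discard_at_border)
  ies2 <- ies_track(panel_ref, cutoff, maf_floor, discard_at_border)
  ok <- !is.na(ies1) & !is.na(ies2) & ies1 > 0 & ies2 > 0
  if (sum(ok) < 10L)
    stop("fewer than 10 SNPs with defined iES in both panels; ",
         "standardization would be unreliable")
  raw <- rsb_std <- prsb <- q <- rep(NA_real_, nrow(m1))
  raw[ok] <- log(ies1[ok] / ies2[ok])
  s <- sd(raw[ok])
  rsb_std[ok] <- if (s > 0) (raw[ok] - median(raw[ok])) / s else 0
  prsb[ok] <- prsb_transform(rsb_std[ok])
  q[ok] <- bh_fdr(10^(-prsb[ok]))
  out <- data.frame(chrom = m1$chrom, pos = m1$pos, snp_id = m1$snp_id,
                    ies_sel = ies1, ies_ref = ies2, raw = raw,
                    rsb_std = rsb_std, prsb = prsb, q = q,
                    stringsAsFactors = FALSE)
  class(out) <- c("rsb_result", "data.frame")
  out
}

#' Write an Rsb scan result as TSV
#'
#' @param result an `rsb_result` from [rsb_scan()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rsb_tsv <- function(result, path) {
  write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
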