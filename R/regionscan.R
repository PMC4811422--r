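## Windowed candidate-region calling: overlapping windows across each
## chromosome, suggestive calls from P_Rsb counts, promotion to
## significant under genome-wide BH-FDR, and merging of overlapping
## windows into candidate regions.
##
## Windows are anchored at coordinate 0 on every chromosome (the exact
## anchor is a convention; region content, not window count, is the
## meaningful output).  Intervals are BED-style 0-based half-open; a
## 1-based SNP at `pos` belongs to window [start, end) iff
## start < pos <= end.

#' Overlapping windows across a SNP map
#'
#' Per chromosome, windows `[k*step, k*step + width)` for k = 0, 1, ...
#' while the window start does not exceed the last SNP position.
#'
#' @param map a [snp_map()] (non-empty).
#' @param width window width in bp (default 1 Mb).
#' @param step window step in bp (default 0.5 Mb, i.e. half-overlap);
#'   `0 < step <= width`.
#' @return `data.frame` with columns `chrom`, `start`, `end` and a list
#'   column `snps` of member SNP row indices into `map`.
#' @export
make_windows <- function(map, width = 1e6, step = 5e5) {
  stopifnot(width > 0, step > 0, step <= width)
  if (nrow(map) == 0L) stop("empty SNP map")
  out <- list()
  for (ch in unique(map$chrom)) {
    j <- which(map$chrom == ch)
    last <- max(map$pos[j])
    starts <- seq(0, last, by = step)
    members <- lapply(starts, function(s)
      j[map$pos[j] > s & map$pos[j] <= s + width])
    out[[ch]] <- data.frame(chrom = ch, start = starts,
                            end = starts + width,
                            stringsAsFactors = FALSE)
    out[[ch]]$snps <- members
  }
  w <- do.call(rbind, out)
  rownames(w) <- NULL
  w
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment `q_(i) = min_{j>=i}(p_(j) m / j)`, capped
#' at 1, returned in input order.
#'
#' @param p_values p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

empty_regions <- function() {
  r <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                  status = character(), n_snps = integer(),
                  stringsAsFactors = FALSE)
  r$snps <- list()
  class(r) <- c("candidate_regions", "data.frame")
  r
}

#' Merge overlapping or touching candidate regions
#'
#' Transitive union per chromosome; member SNP tables are concatenated
#' and de-duplicated.  Idempotent and invariant to input order.
#'
#' @param regions a `candidate_regions` data frame.
#' @return Merged `candidate_regions`.
#' @export
merge_regions <- function(regions) {
  if (nrow(regions) == 0L) return(regions)
  out <- list()
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    r <- r[order(r$start, r$end), , drop = FALSE]
    cur_start <- r$start[1L]; cur_end <- r$end[1L]
    cur_snps <- list(r$snps[[1L]])
    flush <- function(acc, s, e, snp_list) {
      snps <- do.call(rbind, snp_list)
      snps <- snps[!duplicated(snps$snp_id), , drop = FALSE]
      snps <- snps[order(snps$pos), , drop = FALSE]
      rownames(snps) <- NULL
      row <- data.frame(chrom = ch, start = s, end = e,
                        status = r$status[1L], n_snps = nrow(snps),
                        stringsAsFactors = FALSE)
      row$snps <- list(snps)
      c(acc, list(row))
    }
    acc <- list()
    for (i in seq_len(nrow(r))[-1L]) {
      if (r$start[i] <= cur_end) {  # overlapping or touching
        cur_end <- max(cur_end, r$end[i])
        cur_snps <- c(cur_snps, list(r$snps[[i]]))
      } else {
        acc <- flush(acc, cur_start, cur_end, cur_snps)
        cur_start <- r$start[i]; cur_end <- r$end[i]
        cur_snps <- list(r$snps[[i]])
      }
    }
    acc <- flush(acc, cur_start, cur_end, cur_snps)
    out[[ch]] <- do.call(rbind, acc)
  }
  m <- do.call(rbind, out)
  rownames(m) <- NULL
  class(m) <- c("candidate_regions", "data.frame")
  m
}

#' Call suggestive candidate regions
#'
#' Flags windows containing at least `min_snps` member SNPs with
#' `prsb` strictly above `prsb_threshold`, then merges overlapping
#' flagged windows into candidate regions with status `"suggestive"`.
#' Member SNPs of a region are the threshold-exceeding SNPs of its
#' windows.
#'
#' @param windows output of [make_windows()].
#' @param result an `rsb_result` from [rsb_scan()] (row order must match
#'   the map the windows were built from).
#' @param prsb_threshold strict P_Rsb threshold (default 2, i.e.
#'   one-tailed p < 0.01).
#' @param min_snps minimum qualifying SNPs per window (default 2).
#' @return A `candidate_regions` data frame.
#' @export
call_suggestive_regions <- function(windows, result, prsb_threshold = 2,
                                    min_snps = 2L) {
  stopifnot(prsb_threshold > 0, min_snps > 0)
  hits <- !is.na(result$prsb) & result$prsb > prsb_threshold
  rows <- list()
  for (i in seq_len(nrow(windows))) {
    members <- windows$snps[[i]]
    qual <- members[hits[members]]
    if (length(qual) >= min_snps) {
      row <- data.frame(chrom = windows$chrom[i], start = windows$start[i],
                        end = windows$end[i], status = "suggestive",
                        n_snps = length(qual), stringsAsFactors = FALSE)
      row$snps <- list(result[qual, c("snp_id", "pos", "prsb", "q"),
                              drop = FALSE])
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) return(empty_regions())
  flagged <- do.call(rbind, rows)
  class(flagged) <- c("candidate_regions", "data.frame")
  merge_regions(flagged)
}

#' Promote suggestive regions to FDR-significant
#'
#' A suggestive region becomes `"significant"` iff at least `min_snps`
#' of its member SNPs have BH q-values strictly below `fdr_alpha`
#' (q-values computed genome-wide over all scanned SNPs by
#' [rsb_scan()]).  The reported member list is restricted to those
#' SNPs.
#'
#' @param suggestive_regions output of [call_suggestive_regions()].
#' @param result the same `rsb_result` used for the suggestive call.
#' @param fdr_alpha FDR threshold (default 0.05).
#' @param min_snps minimum significant member SNPs (default 2).
#' @return A `candidate_regions` data frame with status `"significant"`.
#' @export
call_significant_regions <- function(suggestive_regions, result,
                                     fdr_alpha = 0.05, min_snps = 2L) {
  if (nrow(suggestive_regions) == 0L) return(empty_regions())
  rows <- list()
  for (i in seq_len(nrow(suggestive_regions))) {
    snps <- suggestive_regions$snps[[i]]
    sig <- snps[!is.na(snps$q) & snps$q < fdr_alpha, , drop = FALSE]
    if (nrow(sig) >= min_snps) {
      row <- suggestive_regions[i, , drop = FALSE]
      row$status <- "significant"
      row$n_snps <- nrow(sig)
      row$snps <- list(sig)
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) return(empty_regions())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("candidate_regions", "data.frame")
  out
}

#' @export
print.candidate_regions <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("candidate_regions: none\n")
    return(invisible(x))
  }
  cat("candidate_regions:", nrow(x), "region(s)\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %s %.1f-%.1f Mb  %s  (%d SNPs)\n", x$chrom[i],
                x$start[i] / 1e6, x$end[i] / 1e6, x$status[i], x$n_snps[i]))
  invisible(x)
}

#' Candidate regions as a feature set
#'
#' @param regions a `candidate_regions` data frame.
#' @return A [feature_set()] with the region status as name.
#' @export
regions_to_features <- function(regions) {
  if (nrow(regions) == 0L) return(feature_set())
  feature_set(regions$chrom, regions$start, regions$end, regions$status)
}
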