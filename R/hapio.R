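## Data model + readers/writers for phased haplotypes, genotypes and
## feature intervals.
##
## Coordinate conventions (fixed across the package): SNP positions are
## 1-based bp as in VCF; all region/feature intervals are 0-based
## half-open as in BED.  Conversions happen only where the two meet
## (window membership, annotation).  Chromosome labels are opaque
## strings; no "chr" normalisation is attempted.

#' SNP map
#'
#' Marker coordinates shared by haplotype panels and genotype matrices.
#'
#' @param chrom character vector of chromosome labels (opaque strings).
#' @param pos integer vector of 1-based bp positions, strictly
#'   increasing within each chromosome.
#' @param snp_id unique marker identifiers.
#' @param ref_allele,alt_allele single-character alleles.
#' @return A `data.frame` of class `snp_map` with columns `chrom`,
#'   `pos`, `snp_id`, `ref_allele`, `alt_allele`.
#' @export
snp_map <- function(chrom, pos, snp_id,
                    ref_allele = rep("A", length(pos)),
                    alt_allele = rep("C", length(pos))) {
  m <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                  snp_id = as.character(snp_id),
                  ref_allele = as.character(ref_allele),
                  alt_allele = as.character(alt_allele),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(m$snp_id))
    stop("snp_id values must be unique")
  for (ch in unique(m$chrom)) {
    p <- m$pos[m$chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  class(m) <- c("snp_map", "data.frame")
  m
}

#' Phased haplotype panel
#'
#' Binary allele matrix with two haplotype rows per diploid sample,
#' the substrate of the EHHS/iES/Rsb scan.
#'
#' @param alleles matrix of 0/1 with rows = haplotypes (2 per sample,
#'   sample order then haplotype index) and columns aligned with `map`.
#' @param map a [snp_map()].
#' @param sample_pop named character vector mapping sample id to
#'   population label (one entry per diploid sample).
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, map, sample_pop) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) %% 2L != 0L)
    stop("haplotype count must be even (two per diploid sample)")
  if (ncol(alleles) != nrow(map))
    stop("allele columns must align with the SNP map")
  if (!all(alleles %in% c(0L, 1L)))
    stop("alleles must be 0/1 with no missing entries")
  n_s <- nrow(alleles) / 2L
  if (length(sample_pop) != n_s)
    stop("sample_pop must have one entry per diploid sample")
  if (is.null(names(sample_pop)))
    names(sample_pop) <- paste0("sample", seq_len(n_s))
  rownames(alleles) <- paste0(rep(names(sample_pop), each = 2L), "_",
                              rep(1:2, n_s))
  colnames(alleles) <- map$snp_id
  structure(list(alleles = alleles, map = map,
                 sample_pop = sample_pop, phased = TRUE),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", nrow(x$alleles), "haplotypes x",
      ncol(x$alleles), "SNPs;",
      length(unique(x$sample_pop)), "population(s)\n")
  invisible(x)
}

#' Diploid genotype dosage matrix
#'
#' @param dosage matrix of 0/1/2 (alt-allele dosage) or `NA`, rows =
#'   individuals, columns aligned with `map`.
#' @param map a [snp_map()].
#' @param sample_pop named character vector, individual id -> population.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, map, sample_pop) {
  dosage <- as.matrix(dosage)
  if (ncol(dosage) != nrow(map))
    stop("dosage columns must align with the SNP map")
  if (!all(dosage %in% c(0, 1, 2) | is.na(dosage)))
    stop("dosages must be 0, 1, 2 or NA")
  if (length(sample_pop) != nrow(dosage))
    stop("sample_pop must have one entry per individual")
  if (is.null(names(sample_pop)))
    names(sample_pop) <- paste0("ind", seq_len(nrow(dosage)))
  rownames(dosage) <- names(sample_pop)
  colnames(dosage) <- map$snp_id
  structure(list(dosage = dosage, map = map, sample_pop = sample_pop),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "SNPs;",
      length(unique(x$sample_pop)), "population(s)\n")
  invisible(x)
}

#' Feature interval set (BED convention)
#'
#' 0-based half-open intervals, sorted by start within chromosome.
#'
#' @param chrom,start,end,name interval columns; `start < end` required.
#' @return A `data.frame` of class `feature_set`.
#' @export
feature_set <- function(chrom = character(), start = numeric(),
                        end = numeric(), name = NULL) {
  if (is.null(name)) name <- rep(NA_character_, length(chrom))
  f <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                  end = as.numeric(end), name = as.character(name),
                  stringsAsFactors = FALSE)
  if (any(f$start >= f$end))
    stop("malformed interval: start must be < end (0-based half-open)")
  f <- f[order(f$chrom, f$start, f$end), , drop = FALSE]
  rownames(f) <- NULL
  class(f) <- c("feature_set", "data.frame")
  f
}

valid_snp_gt <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
}

#' Read a phased diploid VCF into a haplotype panel
#'
#' Only the GT field is interpreted.  Multiallelic and indel records are
#' dropped (with a message); retained records must be phased (`|`
#' separator).  Missing genotypes are dropped sites by default, or an
#' error under `strict_missing` (EHH needs complete haplotypes).
#'
#' @param path VCF 4.x file (uncompressed or bgzipped).
#' @param sample_pop optional named character vector sample -> population
#'   label; defaults to a single population `"pop1"`.
#' @param strict_missing error on missing GT instead of dropping the site.
#' @return A [haplotype_panel()] with two haplotype rows per sample in
#'   VCF sample order.
#' @export
read_phased_vcf <- function(path, sample_pop = NULL, strict_missing = FALSE) {
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt) || ncol(gt) == 0L)
    stop("VCF has no GT genotypes")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt_l <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(alt_l)
  alt <- rep(NA_character_, length(ref))
  alt[n_alt == 1L] <- as.character(unlist(alt_l[n_alt == 1L]))
  biallelic <- n_alt == 1L & !is.na(alt) & valid_snp_gt(ref, alt)
  n_drop <- sum(!biallelic)
  if (n_drop > 0L)
    message("read_phased_vcf: dropped ", n_drop,
            " non-biallelic-SNP record(s)")
  if (!any(biallelic))
    stop("no biallelic SNP records in ", path)

  gt <- gt[biallelic, , drop = FALSE]
  miss <- array(grepl(".", gt, fixed = TRUE), dim = dim(gt))
  miss_site <- apply(miss, 1L, any)
  if (any(miss_site)) {
    if (strict_missing)
      stop("missing genotypes at ", sum(miss_site),
           " site(s); phased scan input must be complete")
    warning("read_phased_vcf: dropped ", sum(miss_site),
            " site(s) with missing genotypes")
  }
  unphased <- grepl("/", gt[!miss_site, , drop = FALSE], fixed = TRUE)
  if (any(unphased))
    stop("unphased genotype ('/' separator) found; input must be phased")

  keep <- which(biallelic)[!miss_site]
  if (length(keep) == 0L)
    stop("no usable phased biallelic SNP records in ", path)
  gt <- gt[!miss_site, , drop = FALSE]

  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  if (!all(c(a1, a2) %in% c("0", "1")))
    stop("GT alleles outside {0,1} in retained biallelic records")

  n_snp <- nrow(gt)
  n_s <- ncol(gt)
  alleles <- matrix(0L, nrow = 2L * n_s, ncol = n_snp)
  for (s in seq_len(n_s)) {
    alleles[2L * s - 1L, ] <- as.integer(a1[, s])
    alleles[2L * s, ] <- as.integer(a2[, s])
  }

  map <- snp_map(chrom = as.character(GenomicRanges::seqnames(rr))[keep],
                 pos = GenomicRanges::start(rr)[keep],
                 snp_id = names(rr)[keep],
                 ref_allele = ref[keep], alt_allele = alt[keep])
  samples <- colnames(gt)
  if (is.null(sample_pop)) {
    sample_pop <- stats::setNames(rep("pop1", n_s), samples)
  } else {
    if (!all(samples %in% names(sample_pop)))
      stop("sample_pop is missing labels for some VCF samples")
    sample_pop <- sample_pop[samples]
  }
  haplotype_panel(alleles, map, sample_pop)
}

#' Write a haplotype panel as a phased VCF
#'
#' Inverse of [read_phased_vcf()]: biallelic SNP records with phased GT
#' fields; round-trips alleles, positions and phase.
#'
#' @param panel a [haplotype_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  map <- panel$map
  n_s <- length(panel$sample_pop)
  samples <- names(panel$sample_pop)
  header <- c("##fileformat=VCFv4.2",
              "##source=rsbscan",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  gt_cols <- vapply(seq_len(n_s), function(s) {
    paste0(panel$alleles[2L * s - 1L, ], "|", panel$alleles[2L * s, ])
  }, character(nrow(map)))
  if (nrow(map) == 1L) gt_cols <- matrix(gt_cols, nrow = 1L)
  body <- paste(map$chrom, format(map$pos, scientific = FALSE, trim = TRUE),
                map$snp_id, map$ref_allele, map$alt_allele, ".", "PASS", ".",
                "GT", apply(gt_cols, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a BED3/BED4 file as a feature set
#'
#' Intervals are kept verbatim in BED's 0-based half-open convention.
#'
#' @param path BED file (3+ columns; extra columns ignored).
#' @return A [feature_set()].
#' @export
read_feature_bed <- function(path) {
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines == 0L) return(feature_set())
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) return(feature_set())
  if (any(GenomicRanges::width(gr) < 1L))
    stop("malformed interval: start must be < end (0-based half-open)")
  nm <- gr$name
  if (is.null(nm)) nm <- rep(NA_character_, length(gr))
  feature_set(chrom = as.character(GenomicRanges::seqnames(gr)),
              start = GenomicRanges::start(gr) - 1L,
              end = GenomicRanges::end(gr),
              name = nm)
}

#' Write candidate regions to BED
#'
#' One 0-based half-open BED line per region; the name column carries
#' the region status (`suggestive`/`significant`).  Round-trips through
#' [read_feature_bed()].
#'
#' @param regions a `candidate_regions` object (see
#'   [call_suggestive_regions()]) or a [feature_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(regions, path) {
  if (nrow(regions) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  nm <- if ("status" %in% names(regions)) regions$status else regions$name
  nm[is.na(nm)] <- "."
  writeLines(paste(regions$chrom,
                   format(regions$start, scientific = FALSE, trim = TRUE),
                   format(regions$end, scientific = FALSE, trim = TRUE),
                   nm, sep = "\t"), path)
  invisible(path)
}

## feature_set -> GRanges (1-based closed, as GenomicRanges expects)
fs_to_granges <- function(f) {
  GenomicRanges::GRanges(
    seqnames = f$chrom,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    name = f$name)
}
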