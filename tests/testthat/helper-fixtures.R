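# In-code fixtures shared across test files.

# panel from a character vector of haplotype strings ("0110...")
make_panel <- function(haps, pos = NULL, chrom = "chr1", pops = NULL) {
  a <- do.call(rbind, lapply(strsplit(haps, ""), as.integer))
  m <- ncol(a)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  map <- snp_map(chrom = rep(chrom, m), pos = pos,
                 snp_id = paste0("s", seq_len(m)))
  n_s <- nrow(a) / 2
  if (is.null(pops)) pops <- stats::setNames(rep("pop1", n_s),
                                             paste0("ind", seq_len(n_s)))
  haplotype_panel(a, map, pops)
}

make_gmat <- function(dosage, pops = NULL, pos = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  map <- snp_map(chrom = rep("chr1", m), pos = pos,
                 snp_id = paste0("s", seq_len(m)))
  if (is.null(pops)) pops <- stats::setNames(rep("popA", nrow(dosage)),
                                             paste0("i", seq_len(nrow(dosage))))
  genotype_matrix(dosage, map, pops)
}

# minimal phased VCF writer for reader tests
write_test_vcf <- function(records, path, samples = c("s1", "s2", "s3")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

vcf_rec <- function(pos, id, ref, alt, gts, chrom = "chr1") {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# desk-scale-but-small sweep world for unit tests (seconds, not minutes)
small_sweep_cfg <- function(seed, s = 0.1, ...) {
  sweep_sim_config(N = 80L, chrom_len = 5e5, mu = 8e-7, rec = 3e-7,
                   burnin_gens = 640L, split_gens = 40L, s = s,
                   n_sample = 40L, seed = seed, ...)
}

# independent all-pairs homozygosity oracle
hh_oracle <- function(a, idx) {
  key <- apply(a[, idx, drop = FALSE], 1, paste, collapse = "")
  n <- length(key)
  same <- 0
  for (i in seq_len(n - 1))
    for (j in seq(i + 1, n)) same <- same + (key[i] == key[j])
  same / (n * (n - 1) / 2)
}

# independent two-sided Fisher oracle by hypergeometric enumeration
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  supp <- lo:hi
  pr <- dhyper(supp, m, n, k)
  p0 <- dhyper(a, m, n, k)
  sum(pr[pr <= p0 * (1 + 1e-7)])
}

# independent BH step-up oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(sort(p)[i:m] * m / (i:m)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# all permutations of 1..n (for the BH step-up oracle suite)
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i)
    lapply(combinat_perms(n - 1L), function(p) c(i, p + (p >= i)))))
}
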