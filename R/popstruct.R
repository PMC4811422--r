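## Population structure and divergence: VanRaden GRM, PCA by
## eigendecomposition, Weir-Cockerham F_ST, Ward clustering on F_ST
## distances.

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 sum_j p_j (1 - p_j))` with `Z` the 0/1/2 dosage matrix
#' column-centered by `2 p_j`.  Missing dosages are mean-imputed per SNP
#' (equivalently, centered entries set to 0).
#'
#' @param g a [genotype_matrix()] with at least 2 individuals.
#' @param allele_freq optional vector of reference alt-allele
#'   frequencies per SNP; defaults to the observed frequencies.
#' @return An object of class `grm`: `list(matrix, sample_pop)`.
#' @export
compute_grm <- function(g, allele_freq = NULL) {
  d <- g$dosage
  stopifnot(nrow(d) >= 2)
  p <- if (is.null(allele_freq)) site_alt_freq(g) else allele_freq
  if (length(p) != ncol(d)) stop("allele_freq must have one entry per SNP")
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all SNPs monomorphic: zero denominator in GRM scaling")
  z <- sweep(d, 2L, 2 * p, "-")
  z[is.na(z)] <- 0
  mat <- tcrossprod(z) / denom
  dimnames(mat) <- list(rownames(d), rownames(d))
  structure(list(matrix = mat, sample_pop = g$sample_pop), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x$matrix), "individuals,",
      length(unique(x$sample_pop)), "population(s)\n")
  invisible(x)
}

#' Mean within-population relationship
#'
#' Mean of the off-diagonal GRM entries among members of one population.
#'
#' @param G a `grm` from [compute_grm()].
#' @param pop population label (at least 2 members).
#' @return Scalar mean relationship.
#' @export
average_within_group_relationship <- function(G, pop) {
  i <- which(G$sample_pop == pop)
  if (length(i) < 2L)
    stop("population '", pop, "' has fewer than 2 members")
  m <- G$matrix[i, i, drop = FALSE]
  mean(m[upper.tri(m)])
}

#' Mean between-population relationship
#'
#' Mean of the GRM block linking two populations (the between-breed
#' summary conventionally shown opposite pairwise F_ST).
#'
#' @param G a `grm`.
#' @param popA,popB population labels.
#' @return Scalar mean relationship.
#' @export
average_between_group_relationship <- function(G, popA, popB) {
  i <- which(G$sample_pop == popA)
  j <- which(G$sample_pop == popB)
  if (length(i) == 0L || length(j) == 0L) stop("unknown population label")
  mean(G$matrix[i, j])
}

#' Principal components of a GRM
#'
#' Eigendecomposition of the relationship matrix; scores are
#' eigenvectors scaled by the square root of their eigenvalue, and each
#' component's variance share is its eigenvalue over the sum of positive
#' eigenvalues.  For reproducible plots each eigenvector's
#' largest-magnitude entry is made positive.
#'
#' @param G a `grm`.
#' @param k number of components (`k <= n`).
#' @return `list(scores = n x k matrix, pct_variance = length-k vector,
#'   eigenvalues = all eigenvalues)`.
#' @export
pca_from_grm <- function(G, k = 2L) {
  m <- G$matrix
  if (!isSymmetric(unname(m), tol = 1e-8)) stop("GRM must be symmetric")
  stopifnot(k >= 1, k <= nrow(m))
  e <- eigen(m, symmetric = TRUE)
  pos <- sum(e$values[e$values > 0])
  v <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(v[, j]))
    if (v[i_max, j] < 0) v[, j] <- -v[, j]
  }
  scores <- sweep(v, 2L, sqrt(pmax(e$values[seq_len(k)], 0)), "*")
  rownames(scores) <- rownames(m)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores,
       pct_variance = e$values[seq_len(k)] / pos * 100,
       eigenvalues = e$values)
}

## Weir-Cockerham (1984) per-locus variance components for r = 2
## populations from genotype counts, including the heterozygosity term.
## Returns a 3 x L matrix of (a, b, c); loci with < 2 genotyped
## individuals in either population get NA columns.
wc_components <- function(dA, dB) {
  comp <- function(d) {
    n <- colSums(!is.na(d))
    p <- colMeans(d, na.rm = TRUE) / 2
    h <- colMeans(d == 1, na.rm = TRUE)
    list(n = n, p = p, h = h)
  }
  A <- comp(dA); B <- comp(dB)
  r <- 2
  usable <- A$n >= 2 & B$n >= 2
  nbar <- (A$n + B$n) / r
  nc <- (r * nbar - (A$n^2 + B$n^2) / (r * nbar)) / (r - 1)
  pbar <- (A$n * A$p + B$n * B$p) / (r * nbar)
  s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (A$n * A$h + B$n * B$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  out <- rbind(a = a, b = b, c = cc)
  out[, !usable] <- NA_real_
  out
}

#' Pairwise Weir-Cockerham F_ST
#'
#' Multi-locus theta for two populations as a ratio of sums of the
#' per-locus variance components, `theta = sum(a) / sum(a + b + c)`
#' (ratio-of-sums, not average-of-ratios).  Negative estimates are
#' reported as computed, not truncated.
#'
#' @param g a [genotype_matrix()].
#' @param popA,popB population labels, each with at least 2 genotyped
#'   individuals at at least one polymorphic shared SNP.
#' @return Scalar theta estimate.
#' @export
pairwise_fst <- function(g, popA, popB) {
  dA <- g$dosage[g$sample_pop == popA, , drop = FALSE]
  dB <- g$dosage[g$sample_pop == popB, , drop = FALSE]
  if (nrow(dA) < 2L || nrow(dB) < 2L)
    stop("each population needs at least 2 individuals")
  comp <- wc_components(dA, dB)
  ok <- !is.na(comp[1L, ])
  denom <- sum(comp[, ok])
  if (!any(ok) || denom == 0)
    stop("no usable (polymorphic, genotyped) loci for F_ST")
  sum(comp["a", ok]) / denom
}

#' All pairwise F_ST values
#'
#' @param g a [genotype_matrix()].
#' @param populations labels to include (default: all, in first-seen
#'   order).
#' @return Symmetric matrix of class `fst_matrix` with zero diagonal.
#' @export
fst_matrix <- function(g, populations = unique(g$sample_pop)) {
  k <- length(populations)
  m <- matrix(0, k, k, dimnames = list(populations, populations))
  if (k >= 2L)
    for (i in seq_len(k - 1L))
      for (j in seq(i + 1L, k)) {
        m[i, j] <- m[j, i] <- pairwise_fst(g, populations[i], populations[j])
      }
  class(m) <- c("fst_matrix", "matrix")
  m
}

#' Ward clustering of populations on F_ST distances
#'
#' Ward minimum-variance clustering (`hclust`, "ward.D2") of the
#' population F_ST distance matrix.  Negative distances are floored at
#' zero (with a warning) before clustering; populations are ordered by
#' label so ties break deterministically.
#'
#' @param F symmetric F_ST matrix with population dimnames (at least 2
#'   populations).
#' @return `list(hclust = , newick = )`, the dendrogram and its Newick
#'   serialization (via [ape::as.phylo]).
#' @export
fst_ward_tree <- function(F) {
  m <- unclass(F)
  if (nrow(m) < 2L) stop("need at least 2 populations")
  if (any(m < 0)) {
    warning("negative F_ST distances floored at 0 before clustering")
    m[m < 0] <- 0
  }
  ord <- order(rownames(m))
  m <- m[ord, ord]
  hc <- hclust(as.dist(m), method = "ward.D2")
  list(hclust = hc, newick = ape::write.tree(ape::as.phylo(hc)))
}
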