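# GRM, PCA, Weir-Cockerham F_ST, Ward clustering.

test_that("GRM matches hand values for reference frequencies 0.5", {
  # two identical fully homozygous individuals; with p_j = 0.5 the
  # centered entries are +/-1 and G = Z Z' / (m/2) = 2 everywhere
  d <- rbind(c(0, 2, 0, 2), c(0, 2, 0, 2))
  g <- make_gmat(d)
  G <- compute_grm(g, allele_freq = rep(0.5, 4))
  expect_equal(unname(G$matrix), matrix(2, 2, 2))
})

test_that("GRM off-diagonals vanish under HWE and duplicates coincide", {
  set.seed(7)
  m <- 10000
  d <- matrix(rbinom(20 * m, 2, 0.5), nrow = 20)
  d <- rbind(d, d[1, ])  # duplicate of individual 1
  g <- make_gmat(d)
  G <- compute_grm(g)
  off <- G$matrix[1:20, 1:20][upper.tri(matrix(0, 20, 20))]
  expect_lt(mean(abs(off)), 0.05)
  expect_equal(G$matrix[21, ], G$matrix[1, ], tolerance = 1e-12)
  # column-order invariance
  perm <- sample(m)
  g2 <- make_gmat(d[, perm])
  expect_equal(compute_grm(g2)$matrix, G$matrix, tolerance = 1e-12)
})

test_that("GRM errors when all SNPs are monomorphic", {
  expect_error(compute_grm(make_gmat(matrix(2L, 4, 3))), "monomorphic")
})

test_that("within/between group relationship summaries", {
  d <- rbind(c(0, 2), c(0, 2), c(2, 0))
  g <- make_gmat(d, pops = stats::setNames(c("A", "A", "B"), paste0("i", 1:3)))
  G <- compute_grm(g, allele_freq = c(0.5, 0.5))
  expect_equal(average_within_group_relationship(G, "A"), G$matrix[1, 2])
  expect_error(average_within_group_relationship(G, "B"), "fewer than 2")
  expect_equal(average_between_group_relationship(G, "A", "B"),
               mean(G$matrix[1:2, 3]))
})

test_that("PCA limits: identity, rank-1, sign convention, variance shares", {
  G <- structure(list(matrix = diag(5),
                      sample_pop = stats::setNames(rep("p", 5),
                                                   paste0("i", 1:5))),
                 class = "grm")
  r <- pca_from_grm(G, k = 5)
  expect_equal(r$pct_variance, rep(20, 5))
  expect_equal(sum(r$pct_variance), 100)

  v <- c(3, -1, 2, 0.5)
  G1 <- structure(list(matrix = tcrossprod(v),
                       sample_pop = stats::setNames(rep("p", 4),
                                                    paste0("i", 1:4))),
                  class = "grm")
  r1 <- pca_from_grm(G1, k = 1)
  expect_equal(r1$pct_variance[1], 100)
  # largest-magnitude loading made positive
  expect_gt(r1$scores[which.max(abs(r1$scores[, 1])), 1], 0)

  Gbad <- G
  Gbad$matrix[1, 2] <- 5
  expect_error(pca_from_grm(Gbad, 2), "symmetric")
})

test_that("PC1 separates two diverged simulated populations", {
  g <- simulate_structured_genotypes(
    structure_sim_config(n_pops = 2, n_per_pop = 30, n_snps = 2000,
                         F = c(0.2, 0.2), missing_rate = 0, seed = 5))
  G <- compute_grm(g)
  pc <- pca_from_grm(G, k = 2)
  lab <- G$sample_pop
  x <- pc$scores[, 1]
  # silhouette-style check: populations occupy disjoint PC1 ranges
  expect_true(min(x[lab == "pop2"]) > max(x[lab == "pop1"]) ||
              min(x[lab == "pop1"]) > max(x[lab == "pop2"]))
})

test_that("F_ST closed-form limits and BN recovery", {
  # complete fixation
  d <- rbind(matrix(0L, 10, 50), matrix(2L, 10, 50))
  pops <- stats::setNames(rep(c("A", "B"), each = 10), paste0("i", 1:20))
  expect_equal(pairwise_fst(make_gmat(d, pops = pops), "A", "B"), 1)

  # duplicated population: estimator centers at/below zero
  set.seed(21)
  dd <- matrix(rbinom(10 * 500, 2, runif(500, 0.2, 0.8)), nrow = 10,
               byrow = FALSE)
  d2 <- rbind(dd, dd)
  th <- pairwise_fst(make_gmat(d2, pops = pops), "A", "B")
  expect_lte(th, 0)

  # Balding-Nichols F = 0.15 recovered within [0.12, 0.18]
  g <- simulate_structured_genotypes(
    structure_sim_config(n_pops = 2, n_per_pop = 50, n_snps = 5000,
                         F = c(0.15, 0.15), missing_rate = 0, seed = 3))
  th <- pairwise_fst(g, "pop1", "pop2")
  expect_gt(th, 0.12)
  expect_lt(th, 0.18)
})

test_that("pairwise_fst error paths", {
  d <- rbind(c(0, 0), c(0, 0), c(0, 0), c(0, 0))
  pops <- stats::setNames(rep(c("A", "B"), each = 2), paste0("i", 1:4))
  expect_error(pairwise_fst(make_gmat(d, pops = pops), "A", "B"),
               "no usable")
  expect_error(pairwise_fst(make_gmat(d[1:3, ], pops = pops[1:3]), "A", "B"),
               "2 individuals")
})

test_that("Ward tree places the divergent out-group at the last merge", {
  # five-breed pattern: one population far from all others
  pops <- c("AG", "JB", "BR", "HW", "YB")
  m <- matrix(0, 5, 5, dimnames = list(pops, pops))
  m["AG", c("JB", "BR", "HW", "YB")] <- c(0.167763, 0.166517, 0.23765,
                                          0.253095)
  m["JB", c("BR", "HW", "YB")] <- c(0.001246, 0.069886, 0.085332)
  m["BR", c("HW", "YB")] <- c(0.071132, 0.086578)
  m["HW", "YB"] <- 0.015445
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  tr <- fst_ward_tree(m)
  hc <- tr$hclust
  last <- hc$merge[nrow(hc$merge), ]
  ag <- which(hc$labels == "AG")
  expect_true(-ag %in% last)  # out-group joins as a singleton, last
  expect_match(tr$newick, "AG")
})

test_that("Ward tree tie-break, two-population and negative-distance cases", {
  pops <- c("b", "a", "c")
  m <- matrix(0.1, 3, 3, dimnames = list(pops, pops))
  diag(m) <- 0
  t1 <- fst_ward_tree(m)
  m2 <- m[c(2, 1, 3), c(2, 1, 3)]
  t2 <- fst_ward_tree(m2)
  expect_equal(t1$newick, t2$newick)  # label-sorted, input-order invariant

  m2p <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = list(c("x", "y"),
                                                      c("x", "y")))
  t2p <- fst_ward_tree(m2p)
  expect_equal(length(t2p$hclust$height), 1L)
  expect_equal(t2p$hclust$height, 0.3)

  mneg <- m
  mneg[1, 2] <- mneg[2, 1] <- -0.01
  expect_warning(fst_ward_tree(mneg), "floored")
})

test_that("fst_matrix is symmetric with zero diagonal", {
  g <- simulate_structured_genotypes(
    structure_sim_config(n_pops = 3, n_per_pop = 20, n_snps = 500,
                         F = c(0.2, 0.05, 0.05), missing_rate = 0, seed = 2))
  fm <- fst_matrix(g)
  expect_equal(unclass(fm), t(unclass(fm)))
  expect_equal(diag(unclass(fm)), rep(0, 3), ignore_attr = TRUE)
  # the high-drift population is the most divergent
  expect_gt(fm["pop1", "pop2"], fm["pop2", "pop3"])
})
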