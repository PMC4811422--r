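# EHHS decay, iES integration, Rsb standardization, prsb transform.

test_that("haplotype homozygosity matches direct pair counting", {
  expect_equal(haplotype_homozygosity(make_panel(c("00", "00", "00", "00")),
                                      c(1, 2)), 1)
  expect_equal(haplotype_homozygosity(make_panel(c("00", "01", "10", "11")),
                                      c(1, 2)), 0)
  # groups {2,1,1} over n = 4: 2 identical pairs of 12 ordered pairs
  expect_equal(haplotype_homozygosity(make_panel(c("00", "00", "11", "10")),
                                      c(1, 2)), 1 / 6)
})

test_that("haplotype homozygosity equals all-pairs oracle on random panels", {
  set.seed(31)
  for (rep in 1:25) {
    n <- 2 * sample(2:5, 1)
    m <- sample(3:8, 1)
    a <- matrix(rbinom(n * m, 1, 0.5), nrow = n)
    panel <- make_panel(apply(a, 1, paste, collapse = ""))
    span <- sort(sample.int(m, 2))
    expect_equal(haplotype_homozygosity(panel, span),
                 hh_oracle(a, span[1]:span[2]))
  }
})

test_that("EHHS profile matches the worked four-haplotype example", {
  panel <- make_panel(c("00", "00", "11", "10"))
  pr <- ehhs_profile(panel, focal = 1)
  # H(focal) = 1/3, H(span 1..2) = 1/6 -> EHHS at SNP2 = 0.5
  expect_equal(pr$ehhs, c(1, 0.5))
  expect_equal(pr$positions, c(1000, 2000))
  expect_true(pr$truncated_left)   # focal is the chromosome start
  expect_true(pr$truncated_right)  # 0.5 never fell below the cutoff
  expect_error(ehhs_profile(make_panel(c("00", "00")), 1), "monomorphic")
})

test_that("EHHS is 1 at the focal SNP, non-increasing, relabel-invariant", {
  set.seed(17)
  for (rep in 1:20) {
    n <- 12
    m <- 15
    a <- matrix(rbinom(n * m, 1, 0.5), nrow = n)
    a[, 8] <- rep(c(0L, 1L), each = n / 2)  # polymorphic focal
    panel <- make_panel(apply(a, 1, paste, collapse = ""))
    pr <- ehhs_profile(panel, 8, cutoff = 0)  # walk to both ends
    k <- which(pr$snp_index == 8)
    expect_equal(pr$ehhs[k], 1)
    expect_true(all(diff(pr$ehhs[k:length(pr$ehhs)]) <= 1e-12))
    expect_true(all(diff(rev(pr$ehhs[1:k])) <= 1e-12))
    # flipping 0<->1 at random SNPs changes nothing
    flip <- sample.int(m, 4)
    b <- a
    b[, flip] <- 1L - b[, flip]
    pr2 <- ehhs_profile(make_panel(apply(b, 1, paste, collapse = "")), 8,
                        cutoff = 0)
    expect_equal(pr2$ehhs, pr$ehhs)
  }
})

test_that("iES integrates trapezoids out to the cutoff crossing", {
  # hand-built profile: positions 0/1000/2000, EHHS 0.2/1/0.2
  prof <- structure(list(focal_index = 2L, snp_index = 1:3,
                         positions = c(0, 1000, 2000),
                         ehhs = c(0.2, 1, 0.2),
                         truncated_left = FALSE, truncated_right = FALSE),
                    class = "ehhs_profile")
  expect_equal(integrate_ies(prof, cutoff = 0.05,
                             discard_at_border = FALSE), 1200)

  # border-truncated profiles are discarded under the default
  prof$truncated_left <- TRUE
  expect_true(is.na(integrate_ies(prof, cutoff = 0.05)))
  expect_equal(integrate_ies(prof, cutoff = 0.05, discard_at_border = FALSE),
               1200)
})

test_that("single-SNP chromosome yields missing iES under border discard", {
  panel <- make_panel(c("0", "0", "1", "1"), pos = 500)
  expect_true(is.na(ies_track(panel)[1]))
})

test_that("all-EHHS-1 panel integrates to the covered chromosome span", {
  # two haplotype classes differing at every SNP: EHHS stays 1
  panel <- make_panel(c("00000", "00000", "11111", "11111"),
                      pos = c(0, 1000, 3000, 6000, 10000))
  ies <- ies_track(panel, discard_at_border = FALSE)
  expect_equal(ies[1], 10000)  # full span from SNP1
  expect_equal(ies[3], 10000)  # left 3000 + right 7000
})

test_that("iES is invariant to SNPs beyond the cutoff crossing", {
  # 10 haplotypes, focal at column 5 of 9; columns 4..2 (and 6..8)
  # progressively split every haplotype into singletons, so the walk
  # crosses the cutoff at columns 2 and 8 and never reads 1 or 9
  n <- 10
  cls <- rep(0:1, each = 5)       # focal alleles
  idx <- rep(0:4, 2)              # within-class id, 3 bits
  b1 <- idx %/% 4
  b2 <- (idx %/% 2) %% 2
  b3 <- idx %% 2
  a <- cbind(0L, b3, b2, b1, cls, b1, b2, b3, 0L)
  panel <- make_panel(apply(a, 1, paste, collapse = ""))
  pr <- ehhs_profile(panel, 5, cutoff = 0.05)
  expect_false(pr$truncated_left)
  expect_false(pr$truncated_right)
  expect_equal(range(pr$snp_index), c(2L, 8L))
  ies <- ies_track(panel)[5]
  expect_false(is.na(ies))
  # adding SNPs beyond the crossing (any alleles) changes nothing
  set.seed(13)
  ext <- cbind(rbinom(n, 1, 0.5), a, rbinom(n, 1, 0.5))
  panel2 <- make_panel(apply(ext, 1, paste, collapse = ""),
                       pos = c(500, seq_len(9) * 1000, 9500))
  expect_equal(ies_track(panel2)[6], ies)
})

test_that("identical panels give zero raw Rsb and prsb = log10(2)", {
  set.seed(23)
  a <- matrix(rbinom(20 * 40, 1, 0.5), nrow = 20)
  haps <- apply(a, 1, paste, collapse = "")
  p1 <- make_panel(haps)
  p2 <- make_panel(haps)
  res <- rsb_scan(p1, p2, discard_at_border = FALSE)
  ok <- !is.na(res$raw)
  expect_gte(sum(ok), 10)
  expect_equal(res$raw[ok], rep(0, sum(ok)))
  expect_equal(res$rsb_std[ok], rep(0, sum(ok)))
  expect_equal(res$prsb[ok], rep(log10(2), sum(ok)))
})

test_that("rsb_scan standardization is exact and guards its inputs", {
  sim <- simulate_sweep_haplotypes(small_sweep_cfg(seed = 61, s = 0))
  res <- rsb_scan(sim$panel_sel, sim$panel_ref)
  ok <- !is.na(res$rsb_std)
  expect_gte(sum(ok), 10)
  expect_equal(median(res$rsb_std[ok]), 0)
  expect_equal(sd(res$rsb_std[ok]), 1)
  expect_true(all(res$prsb[ok] >= 0))
  expect_true(all(res$ies_sel[ok] >= 0 & res$ies_ref[ok] >= 0))

  # mismatched maps refuse to scan
  p2 <- sim$panel_ref
  map2 <- p2$map
  map2$pos[1] <- map2$pos[1] + 1
  p2$map <- map2
  expect_error(rsb_scan(sim$panel_sel, p2), "identical SNP map")

  # too few scanned SNPs
  small <- make_panel(c("01", "10", "00", "11"))
  expect_error(rsb_scan(small, small), "fewer than 10")
})

test_that("prsb transform matches the normal upper tail", {
  expect_equal(prsb_transform(0), log10(2))
  expect_equal(prsb_transform(2.3263), 2, tolerance = 1e-3)
  expect_equal(prsb_transform(qnorm(0.99)), 2)
  expect_lt(prsb_transform(-8), 1e-14)
  # extreme scores stay finite and accurate through the log tail
  expect_equal(prsb_transform(6), -log10(pnorm(6, lower.tail = FALSE)))
})

test_that("peak rsb_std near the selected site rises with s", {
  # full-scale replicates; at desk scale 2Ns = 8 (s = 0.02) sits inside
  # drift noise, so the property is asserted as a positive trend plus a
  # clear strong-vs-neutral separation of the replicate means
  peak_near_site <- function(s, seeds) {
    vapply(seeds, function(sd_) {
      sim <- simulate_sweep_haplotypes(sweep_sim_config(s = s, seed = sd_))
      res <- rsb_scan(sim$panel_sel, sim$panel_ref)
      ok <- !is.na(res$rsb_std) &
        abs(res$pos - sim$truth$selected_pos) < 2.5e5
      if (!any(ok)) return(NA_real_)
      max(res$rsb_std[ok])
    }, numeric(1))
  }
  seeds <- 71:75
  s_lev <- c(0, 0.02, 0.05, 0.1)
  peaks <- lapply(s_lev, peak_near_site, seeds = seeds)
  means <- vapply(peaks, mean, numeric(1), na.rm = TRUE)
  expect_gt(cor(s_lev, means), 0)
  expect_gt(means[4], means[1])
})
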