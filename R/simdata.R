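## Synthetic-data generators with known truth.
##
## Two worlds: (1) structured diploid genotypes under the
## Balding-Nichols model, emulating a five-breed design with one
## distant out-group and two close pairs; (2) two-population phased
## haplotype panels from a forward Wright-Fisher simulation with a
## single recent hard sweep in population 1 only.
##
## The sweep simulator is deliberately desk-scale: N = 200 diploids on
## a 2 Mb chromosome with scaled-up mutation and recombination rates so
## that a sampled panel carries on the order of 2,000 segregating SNPs
## and neutral LD decays well inside the chromosome.  Rationale and what
## this does (and does not) emulate are discussed in the methods
## vignette.

#' Configuration for the structured-genotype generator
#'
#' Defaults emulate a five-population design: one distant out-group
#' (F = 0.2) plus two moderately (F = 0.08) and two closely related
#' (F = 0.015) populations.
#'
#' @param n_pops number of populations.
#' @param n_per_pop diploid individuals per population.
#' @param n_snps number of SNPs.
#' @param F per-population Balding-Nichols drift parameter, in (0, 1).
#' @param anc_range range of the uniform ancestral allele frequency.
#' @param missing_rate uniform genotype missingness rate.
#' @param seed RNG seed.
#' @return A `structure_sim_config` list.
#' @export
structure_sim_config <- function(n_pops = 5L, n_per_pop = 50L,
                                 n_snps = 5000L,
                                 F = c(0.2, 0.08, 0.08, 0.015, 0.015),
                                 anc_range = c(0.05, 0.95),
                                 missing_rate = 0.02, seed = 1L) {
  F <- rep_len(F, n_pops)
  stopifnot(n_pops >= 1, n_per_pop >= 1, n_snps >= 1,
            all(F > 0), all(F < 1),
            anc_range[1] > 0, anc_range[2] < 1,
            anc_range[1] <= anc_range[2],
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_pops = n_pops, n_per_pop = n_per_pop, n_snps = n_snps,
                 F = F, anc_range = anc_range,
                 missing_rate = missing_rate, seed = seed),
            class = "structure_sim_config")
}

#' Simulate structured diploid genotypes (Balding-Nichols)
#'
#' Ancestral frequency `p_j ~ U(anc_range)`; population-k frequency
#' `p_jk ~ Beta(p_j (1-F_k)/F_k, (1-p_j)(1-F_k)/F_k)` (so that
#' `Var(p_jk) = F_k p_j (1-p_j)`); genotypes `Binomial(2, p_jk)`;
#' missingness applied uniformly.  Bit-reproducible given the seed.
#'
#' @param cfg a [structure_sim_config()].
#' @return A [genotype_matrix()] with populations labelled
#'   `pop1..popK`; the ancestral frequencies are attached as attribute
#'   `"anc_freq"` and the per-population frequencies as `"pop_freq"`.
#' @export
simulate_structured_genotypes <- function(cfg = structure_sim_config()) {
  stopifnot(inherits(cfg, "structure_sim_config"))
  set.seed(cfg$seed)
  m <- cfg$n_snps
  p_anc <- stats::runif(m, cfg$anc_range[1], cfg$anc_range[2])
  n_tot <- cfg$n_pops * cfg$n_per_pop
  dosage <- matrix(NA_integer_, nrow = n_tot, ncol = m)
  pop_freq <- matrix(NA_real_, nrow = cfg$n_pops, ncol = m)
  for (k in seq_len(cfg$n_pops)) {
    Fk <- cfg$F[k]
    pk <- stats::rbeta(m, p_anc * (1 - Fk) / Fk,
                       (1 - p_anc) * (1 - Fk) / Fk)
    pop_freq[k, ] <- pk
    rows <- (k - 1L) * cfg$n_per_pop + seq_len(cfg$n_per_pop)
    dosage[rows, ] <- matrix(stats::rbinom(cfg$n_per_pop * m, 2L,
                                           rep(pk, each = cfg$n_per_pop)),
                             nrow = cfg$n_per_pop)
  }
  if (cfg$missing_rate > 0)
    dosage[stats::runif(length(dosage)) < cfg$missing_rate] <- NA_integer_
  map <- snp_map(chrom = rep("chr1", m),
                 pos = seq(1e4, by = 5e4, length.out = m),
                 snp_id = sprintf("snp%05d", seq_len(m)))
  pops <- rep(paste0("pop", seq_len(cfg$n_pops)), each = cfg$n_per_pop)
  ids <- paste0(pops, "_", rep(seq_len(cfg$n_per_pop), cfg$n_pops))
  g <- genotype_matrix(dosage, map, stats::setNames(pops, ids))
  attr(g, "anc_freq") <- p_anc
  attr(g, "pop_freq") <- pop_freq
  g
}

#' Configuration for the two-population sweep simulator
#'
#' Defaults are the desk-scale stated world used throughout the test
#' suite: 200 diploids, 2 Mb, scaled-up rates, an 8N-generation burn-in
#' and 60 post-split generations of genic selection (fitness 1, 1+s,
#' 1+2s) at a single young standing variant in population 1 only, so
#' that the sweep is near completion -- not long past -- when the
#' panels are sampled (the regime of a recent breeding program).
#'
#' @param N diploid population size per population.
#' @param chrom_len chromosome length in bp.
#' @param mu per-bp per-generation mutation rate.
#' @param rec per-bp per-generation recombination rate.
#' @param burnin_gens burn-in generations building standing variation.
#' @param split_gens generations after the population split.
#' @param s selection coefficient in population 1 (s >= 0; 0 = neutral).
#' @param sel_pos target bp position of the selected site (the nearest
#'   standing variant with frequency in `[1/2N, standing_freq_max]` is
#'   used).
#' @param standing_freq_min,standing_freq_max bounds on the selected
#'   variant's standing frequency at the split (defaults 0.02 and 0.1:
#'   a young rare variant, so carriers share a recent haplotype and the
#'   sweep is near completion, not long past, when panels are sampled).
#' @param n_sample sampled haplotypes per population (even, <= 2N).
#' @param max_retries re-draws of the post-split phase if the selected
#'   allele is lost.
#' @param seed RNG seed.
#' @return A `sweep_sim_config` list.
#' @export
sweep_sim_config <- function(N = 200L, chrom_len = 2e6, mu = 1.5e-7,
                             rec = 1e-7, burnin_gens = 8L * N,
                             split_gens = 60L, s = 0.1,
                             sel_pos = chrom_len / 2,
                             standing_freq_min = 0.02,
                             standing_freq_max = 0.1, n_sample = 120L,
                             max_retries = 20L, seed = 1L) {
  stopifnot(N >= 2, chrom_len > 0, mu > 0, rec >= 0, burnin_gens >= 1,
            split_gens >= 1, s >= 0, sel_pos >= 1, sel_pos <= chrom_len,
            standing_freq_min >= 0, standing_freq_max <= 1,
            standing_freq_min <= standing_freq_max,
            n_sample >= 4, n_sample %% 2 == 0, n_sample <= 2 * N)
  structure(list(N = as.integer(N), chrom_len = chrom_len, mu = mu,
                 rec = rec, burnin_gens = as.integer(burnin_gens),
                 split_gens = as.integer(split_gens), s = s,
                 sel_pos = sel_pos,
                 standing_freq_min = standing_freq_min,
                 standing_freq_max = standing_freq_max,
                 n_sample = as.integer(n_sample),
                 max_retries = as.integer(max_retries), seed = seed),
            class = "sweep_sim_config")
}

#' Simulate two-population phased haplotype panels with a known sweep
#'
#' Forward Wright-Fisher simulation: neutral burn-in builds standing
#' variation, the population splits into two copies, and population 1
#' then experiences genic selection at a single site while population 2
#' stays neutral.  Sampled haplotypes are returned phased on a shared
#' SNP map (sites segregating in the pooled sample), together with a
#' truth record.  Bit-reproducible given the seed.
#'
#' @param cfg a [sweep_sim_config()].
#' @return `list(panel_sel, panel_ref, truth)`, the two
#'   [haplotype_panel()]s (population 1 = selected) and a truth list
#'   with `selected_pos`, `selected_freq_split`, `selected_freq_pop1`,
#'   `selected_freq_pop2` (population frequencies), `s` and `retries`.
#' @export
simulate_sweep_haplotypes <- function(cfg = sweep_sim_config()) {
  stopifnot(inherits(cfg, "sweep_sim_config"))
  set.seed(cfg$seed)
  sim <- .wf_sim_cpp(cfg$N, cfg$chrom_len, cfg$mu, cfg$rec,
                     cfg$burnin_gens, cfg$split_gens, cfg$s, cfg$sel_pos,
                     cfg$standing_freq_min, cfg$standing_freq_max,
                     cfg$n_sample, cfg$max_retries, 5L)
  m <- length(sim$positions)
  if (m == 0L) stop("simulation produced no segregating sampled sites")
  map <- snp_map(chrom = rep("chr1", m), pos = sim$positions,
                 snp_id = sprintf("snp%06d", as.integer(sim$positions)))
  n_ind <- cfg$n_sample / 2L
  pop1 <- stats::setNames(rep("pop1", n_ind), paste0("p1_", seq_len(n_ind)))
  pop2 <- stats::setNames(rep("pop2", n_ind), paste0("p2_", seq_len(n_ind)))
  list(panel_sel = haplotype_panel(sim$hap1, map, pop1),
       panel_ref = haplotype_panel(sim$hap2, map, pop2),
       truth = list(selected_pos = sim$selected_pos,
                    selected_freq_split = sim$selected_freq_split,
                    selected_freq_pop1 = sim$selected_freq_pop1,
                    selected_freq_pop2 = sim$selected_freq_pop2,
                    s = cfg$s, retries = sim$retries))
}

#' Write a simulated sweep dataset to disk
#'
#' Phased VCF per population, a sample/population TSV, and the truth
#' record as JSON.
#'
#' @param sim output of [simulate_sweep_haplotypes()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sweep_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf_sel = file.path(dir, "panel_sel.vcf"),
             vcf_ref = file.path(dir, "panel_ref.vcf"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.json"))
  write_phased_vcf(sim$panel_sel, paths[["vcf_sel"]])
  write_phased_vcf(sim$panel_ref, paths[["vcf_ref"]])
  samples <- rbind(
    data.frame(sample = names(sim$panel_sel$sample_pop),
               population = unname(sim$panel_sel$sample_pop)),
    data.frame(sample = names(sim$panel_ref$sample_pop),
               population = unname(sim$panel_ref$sample_pop)))
  write.table(samples, paths[["samples"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
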