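test_that("configuration invariants are enforced", {
  expect_error(sim_config(drift_f = 0), "drift_f")
  expect_error(sim_config(drift_f = 1), "drift_f")
  expect_error(sim_config(n_founder_haplotypes = 1), "founder")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sweep_spec("pop1", 1, 100, 100), "end > start")
  expect_error(sweep_spec("pop1", 1, 100, 200, favored_fraction = 0.4),
               "favored_fraction")
  expect_error(sim_config(sweeps = list(sweep_spec("nope", 1, 1, 100))),
               "not in panel")
  expect_error(
    sim_config(chrom_length = 1e5, n_snps_per_chrom = 50,
               sweeps = list(sweep_spec("pop1", 1, 1, 2e5))),
    "past chromosome end")
})

test_that("identical config and seed give bit-identical panels", {
  cfg <- small_sweep_config(5)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$panel$dosage, b$panel$dosage)
  expect_identical(a$panel$markers, b$panel$markers)
  expect_identical(a$truth, b$truth)
})

test_that("positions are sorted, unique, within bounds; labels complete", {
  sim <- simulate_panel(small_sweep_config(3))
  mk <- sim$panel$markers
  expect_false(is.unsorted(mk$pos, strictly = TRUE))
  expect_true(all(mk$pos >= 1 & mk$pos <= 1e6))
  expect_true(all(table(sim$panel$samples$subpop) == 20))
})

test_that("no drift means no differentiation beyond sampling noise", {
  cfg <- sim_config(n_subpops = 2, samples_per_subpop = 40,
                    n_chromosomes = 1, chrom_length = 2e6,
                    n_snps_per_chrom = 3000, drift_f = 1e-4,
                    missing_rate = 0, seed = 9)
  sim <- simulate_panel(cfg)
  c1 <- genotype_counts(sim$panel, "pop1")
  c2 <- genotype_counts(sim$panel, "pop2")
  comp <- snp_fst_components(c1, c2)
  fst <- sum(comp$a[comp$informative]) / sum(comp$total[comp$informative])
  expect_lt(abs(fst), 0.005)
})

test_that("realized mean F_ST matches the Balding-Nichols expectation", {
  # Monte-Carlo over 5 seeds: 2 subpops, drift 0.05, 50 samples, 10k SNPs
  vals <- vapply(1:5, function(s) {
    cfg <- sim_config(n_subpops = 2, samples_per_subpop = 50,
                      n_chromosomes = 1, chrom_length = 5e6,
                      n_snps_per_chrom = 10000, drift_f = 0.05,
                      missing_rate = 0, seed = s)
    sim <- simulate_panel(cfg, keep_haplotypes = FALSE)
    c1 <- genotype_counts(sim$panel, "pop1")
    c2 <- genotype_counts(sim$panel, "pop2")
    comp <- snp_fst_components(c1, c2)
    sum(comp$a[comp$informative]) / sum(comp$total[comp$informative])
  }, 0)
  expect_lt(abs(mean(vals) - 0.05), 0.002)
})

test_that("mean differentiation is non-decreasing in drift_f", {
  mean_fst <- function(f) {
    mean(vapply(1:3, function(s) {
      cfg <- sim_config(n_subpops = 2, samples_per_subpop = 30,
                        n_chromosomes = 1, chrom_length = 2e6,
                        n_snps_per_chrom = 3000, drift_f = f,
                        missing_rate = 0, seed = s)
      sim <- simulate_panel(cfg, keep_haplotypes = FALSE)
      comp <- snp_fst_components(genotype_counts(sim$panel, "pop1"),
                                 genotype_counts(sim$panel, "pop2"))
      sum(comp$a[comp$informative]) / sum(comp$total[comp$informative])
    }, 0))
  }
  v <- c(mean_fst(0.01), mean_fst(0.05), mean_fst(0.15))
  expect_true(all(diff(v) > 0))
})

test_that("pooled frequency conserves the ancestral frequency", {
  cfg <- sim_config(n_subpops = 4, samples_per_subpop = 30,
                    n_chromosomes = 1, chrom_length = 2e6,
                    n_snps_per_chrom = 4000, drift_f = 0.05,
                    missing_rate = 0, seed = 13)
  sim <- simulate_panel(cfg)
  anc <- attr(sim$panel, "ancestral_freq")
  pooled <- panel_freq(sim$panel)
  expect_lt(abs(mean(pooled - anc)), 0.005)
  # per-SNP deviation bounded by drift + sampling variance
  expect_lt(mean((pooled - anc)^2), 2 * mean(anc * (1 - anc)) *
              (0.05 / 4 + 1 / (2 * 120)))
})

test_that("a sweep raises haplotype homozygosity in the target subpopulation", {
  sim <- simulate_panel(small_sweep_config(17))
  haps <- attr(sim$panel, "haplotypes")
  rows <- 1:40                       # pop1 haplotypes (2 per individual)
  p <- colMeans(haps[rows, , drop = FALSE])
  hom <- p^2 + (1 - p)^2             # per-SNP haplotype homozygosity
  inside <- sim$panel$markers$pos >= 4e5 & sim$panel$markers$pos <= 6e5
  expect_gt(mean(hom[inside]), mean(hom))
  # realized favored-founder frequency is high in the target subpop only
  tr <- sim$truth
  expect_gt(tr$core_allele_freq[tr$subpop == "pop1"], 0.85)
})

test_that("two-level hierarchy increases between-group differentiation", {
  base <- function(tree, seed) {
    cfg <- sim_config(n_subpops = 4, samples_per_subpop = 30,
                      n_chromosomes = 1, chrom_length = 2e6,
                      n_snps_per_chrom = 3000, drift_f = 0.05, tree = tree,
                      missing_rate = 0, seed = seed)
    sim <- simulate_panel(cfg, keep_haplotypes = FALSE)
    comp <- snp_fst_components(genotype_counts(sim$panel, "pop1"),
                               genotype_counts(sim$panel, "pop3"))
    sum(comp$a[comp$informative]) / sum(comp$total[comp$informative])
  }
  two_level <- list(c("pop1", "pop2"), c("pop3", "pop4"))
  v_flat <- mean(vapply(1:3, function(s) base(NULL, s), 0))
  v_tree <- mean(vapply(1:3, function(s) base(two_level, s), 0))
  expect_gt(v_tree, v_flat + 0.02)   # extra group-level drift branch
})

test_that("recovery metrics count overlaps with subpopulation matching", {
  truth <- data.frame(sweep = 1:2, target_subpop = c("a", "b"),
                      chrom = c(1L, 1L), start = c(100L, 5000L),
                      end = c(200L, 6000L), favored_fraction = 0.9,
                      subpop = c("a", "b"), core_allele_freq = 0.9)
  class(truth) <- c("sweep_truth", "data.frame")
  exact <- data.frame(chrom = 1L, start = c(100L, 5000L),
                      end = c(200L, 6000L), subpop = c("a", "b"))
  r <- evaluate_recovery(exact, truth)
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  r0 <- evaluate_recovery(exact[0, ], truth)
  expect_false(r0$precision_defined)
  expect_true(is.na(r0$precision))
  expect_equal(r0$recall, 0)
  half <- exact[1, ]
  expect_equal(evaluate_recovery(half, truth)$recall, 0.5)
  # wrong subpopulation: overlaps but does not recover
  wrong <- data.frame(chrom = 1L, start = 100L, end = 200L, subpop = "b")
  rw <- evaluate_recovery(wrong, truth)
  expect_equal(rw$recall, 0)
  expect_equal(rw$precision, 1)
})

test_that("truth export writes BED plus sidecar", {
  sim <- simulate_panel(small_sweep_config(2))
  paths <- write_truth(sim$truth, file.path(tempdir(), "truth"))
  bed <- read.table(paths["bed"], sep = "\t")
  expect_equal(nrow(bed), 1)
  expect_equal(bed$V2, 4e5 - 1)      # 0-based half-open start
  expect_equal(bed$V3, 6e5)
  tsv <- read.table(paths["tsv"], header = TRUE, sep = "\t")
  expect_true(all(c("target_subpop", "core_allele_freq") %in% names(tsv)))
})
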