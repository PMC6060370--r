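test_that("identical frequency profiles give no positive differentiation", {
  # 10 HWE individuals per pop at p = 0.5
  d <- c(rep(0L, 2), rep(1L, 5), rep(2L, 3))
  comp <- snp_fst_components(dosage_counts(d), dosage_counts(d))
  expect_true(comp$informative)
  expect_lte(comp$a / comp$total, 0)
  expect_equal(comp$a, wc_anova_oracle(d, d)[["a"]], tolerance = 1e-12)
})

test_that("fixed opposite alleles approach an F_ST of 1 at large n", {
  d1 <- rep(0L, 500); d2 <- rep(2L, 500)
  comp <- snp_fst_components(dosage_counts(d1), dosage_counts(d2))
  expect_gt(comp$a / comp$total, 0.995)
})

test_that("components match the independent ANOVA oracle on random SNPs", {
  set.seed(101)
  for (rep in 1:100) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    d1 <- sample(0:2, n1, replace = TRUE)
    d2 <- sample(0:2, n2, replace = TRUE)
    d1[runif(n1) < 0.1] <- NA; d2[runif(n2) < 0.1] <- NA
    comp <- snp_fst_components(dosage_counts(d1), dosage_counts(d2))
    if (!comp$informative) next
    orc <- wc_anova_oracle(d1, d2)
    expect_equal(comp$a, orc[["a"]], tolerance = 1e-12)
    expect_equal(comp$total, orc[["total"]], tolerance = 1e-12)
  }
})

test_that("monomorphic and empty-population SNPs are flagged uninformative", {
  mono <- snp_fst_components(c(10, 0, 0), c(8, 0, 0))
  expect_false(mono$informative)
  empty <- snp_fst_components(c(0, 0, 0), c(3, 4, 3))
  expect_false(empty$informative)
})

test_that("window grid follows the 1-based closed 10 kb convention", {
  w <- window_of(30595130)
  expect_equal(w$index, 3059)
  expect_equal(w$start, 30590001)
  expect_equal(w$end, 30600000)
  expect_equal(window_of(1)$index, 0)
  expect_equal(window_of(10000)$index, 0)
  expect_equal(window_of(10001)$index, 1)
})

test_that("window F_ST is the ratio of sums, not the mean of ratios", {
  set.seed(7)
  dos <- matrix(sample(0:2, 2 * 12 * 30, replace = TRUE), 30, 24)
  p <- tiny_panel(dos[, 1:2], rep(c("a", "b"), each = 15),
                  pos = c(1000L, 2000L))   # both SNPs in window 0
  fp <- window_fst(p)
  c_a <- genotype_counts(p, "a"); c_b <- genotype_counts(p, "b")
  comp <- snp_fst_components(c_a, c_b)
  direct <- sum(comp$a[comp$informative]) / sum(comp$total[comp$informative])
  expect_equal(unname(fp$fst[1, 1]), direct, tolerance = 1e-12)
  mean_of_ratios <- mean(comp$a / comp$total)
  expect_false(isTRUE(all.equal(direct, mean_of_ratios)))
})

test_that("windowed F_ST matches brute force on small random panels", {
  set.seed(33)
  for (rep in 1:10) {
    m <- sample(2:10, 1)
    dos <- matrix(sample(0:2, 3 * 8 * m, replace = TRUE), 24, m)
    dos[runif(length(dos)) < 0.05] <- NA
    p <- tiny_panel(dos, rep(c("a", "b", "c"), each = 8),
                    pos = sort(sample.int(9000, m)))  # one 10 kb window
    fp <- window_fst(p)
    for (k in seq_len(nrow(fp$pairs))) {
      orc <- oracle_window_fst(p, fp$pairs$i[k], fp$pairs$j[k])
      if (is.na(orc)) expect_true(is.na(fp$fst[1, k]))
      else expect_equal(unname(fp$fst[1, k]), orc, tolerance = 1e-12)
    }
  }
})

test_that("d_i equals hand-computed standardized z-score sums", {
  # 3 subpops, 4 windows with hand-set pair F_ST values
  fst <- cbind("A:B" = c(0.10, 0.20, 0.30, 0.40),
               "A:C" = c(0.05, 0.05, 0.05, 0.25),
               "B:C" = c(0.00, 0.10, 0.20, 0.10))
  panel <- structure(list(
    windows = data.frame(chrom = 1L, index = 0:3,
                         start = c(1L, 10001L, 20001L, 30001L),
                         end = c(10000L, 20000L, 30000L, 40000L)),
    fst = fst, n_snps = matrix(5L, 4, 3), window_size = 10000,
    pairs = data.frame(i = c("A", "A", "B"), j = c("B", "C", "C")),
    subpops = c("A", "B", "C")), class = "fst_panel")
  di <- compute_di(panel)
  z <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  expect_equal(unname(di$di[, "A"]), z(fst[, 1]) + z(fst[, 2]),
               tolerance = 1e-12)
  expect_equal(unname(di$di[, "B"]), z(fst[, 1]) + z(fst[, 3]),
               tolerance = 1e-12)
  expect_equal(unname(di$di[, "C"]), z(fst[, 2]) + z(fst[, 3]),
               tolerance = 1e-12)
  expect_equal(unname(colMeans(di$di)), rep(0, 3), tolerance = 1e-12)
})

test_that("constant pair F_ST gives d_i = 0 everywhere with a warning", {
  fst <- cbind("A:B" = rep(0.1, 4), "A:C" = c(0.0, 0.1, 0.2, 0.3),
               "B:C" = c(0.0, 0.1, 0.2, 0.3))
  panel <- structure(list(
    windows = data.frame(chrom = 1L, index = 0:3,
                         start = c(1L, 10001L, 20001L, 30001L),
                         end = c(10000L, 20000L, 30000L, 40000L)),
    fst = fst, n_snps = matrix(5L, 4, 3), window_size = 10000,
    pairs = data.frame(i = c("A", "A", "B"), j = c("B", "C", "C")),
    subpops = c("A", "B", "C")), class = "fst_panel")
  expect_warning(di <- compute_di(panel), "zero F_ST variance")
  # the A:B summand is 0, so d_A reduces to the A:C z-score alone
  z <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  expect_equal(unname(di$di[, "A"]), z(fst[, 2]), tolerance = 1e-12)
})

test_that("genome-wide mean d_i is exactly zero on simulated panels", {
  for (s in c(2, 8)) {
    cfg <- sim_config(n_subpops = 3, samples_per_subpop = 20,
                      n_chromosomes = 2, chrom_length = 1e6,
                      n_snps_per_chrom = 500, drift_f = 0.05,
                      n_founder_haplotypes = 10, seed = s)
    sim <- simulate_panel(cfg, keep_haplotypes = FALSE)
    di <- compute_di(window_fst(sim$panel))
    expect_lt(max(abs(colMeans(di$di))), 1e-10)
  }
})

test_that("the top-fraction count and tie-breaking follow the stated rules", {
  expect_equal(top_window_count(217806, 0.001), 218L)
  expect_equal(top_window_count(1000, 0.001), 1L)
  windows <- data.frame(chrom = rep(c(1L, 2L), each = 5), index = 0:9,
                        start = rep(c(1, 10001, 20001, 30001, 40001), 2),
                        end = rep(c(10000, 20000, 30000, 40000, 50000), 2))
  di <- structure(list(windows = windows,
                       di = matrix(1, 10, 2,
                                   dimnames = list(NULL, c("a", "b"))),
                       moments = NULL, n_snps = matrix(1L, 10, 3),
                       window_size = 10000), class = "di_scan")
  sig <- suppressWarnings(significant_windows(di, top_fraction = 0.3))
  # all d_i tied: the first 3 windows in (chrom, start) order are selected
  expect_equal(nrow(sig$a), 3)
  expect_equal(sig$a$chrom, rep(1L, 3))
  expect_equal(sig$a$start, c(1, 10001, 20001))
  expect_warning(significant_windows(di, 0.001), "1000")
})

test_that("label permutation destroys sweep detection (exchangeability null)", {
  # sweep spans ~5% of the windows, so chance overlap of the top 1% is rare
  hits <- function(permute, seeds) {
    vapply(seeds, function(s) {
      cfg <- sim_config(n_subpops = 2, samples_per_subpop = 20,
                        n_chromosomes = 1, chrom_length = 2e6,
                        n_snps_per_chrom = 800, drift_f = 0.05,
                        n_founder_haplotypes = 10, missing_rate = 0.01,
                        sweeps = list(sweep_spec("pop1", 1, 9e5, 1e6, 0.9)),
                        seed = s)
      sim <- simulate_panel(cfg, keep_haplotypes = FALSE)
      p <- sim$panel
      if (permute) {
        set.seed(s + 1000)
        p$samples$subpop <- sample(p$samples$subpop)
      }
      di <- compute_di(window_fst(p))
      sig <- suppressWarnings(significant_windows(di, 0.01))
      any(sig$pop1$chrom == 1 & sig$pop1$start <= 1e6 & sig$pop1$end >= 9e5)
    }, TRUE)
  }
  seeds <- 1:5
  observed <- sum(hits(FALSE, seeds))
  permuted <- sum(hits(TRUE, seeds))
  expect_equal(observed, 5L)        # real labels: sweep found every time
  expect_lte(permuted, 2L)          # permuted labels: chance-level overlap
})
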