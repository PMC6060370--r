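# shared fixtures and independent oracles

# tiny panel with explicit dosages
tiny_panel <- function(dosage, subpop, chrom = NULL, pos = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  genotype_panel(dosage,
                 data.frame(sample_id = paste0("s", seq_len(n)),
                            subpop = subpop, stringsAsFactors = FALSE),
                 data.frame(marker_id = paste0("m", seq_len(m)),
                            chrom = chrom, pos = pos,
                            stringsAsFactors = FALSE))
}

# Independent Weir-Cockerham oracle: three-level random-effects ANOVA on raw
# 0/1 allele indicators (individuals nested in populations), a different
# computational route than the closed-form components in the package.
wc_anova_oracle <- function(dos_i, dos_j) {
  expand <- function(d) {
    d <- d[!is.na(d)]
    list(a1 = as.numeric(d == 2), a2 = as.numeric(d >= 1))
  }
  pops <- list(expand(dos_i), expand(dos_j))
  ni <- vapply(pops, function(g) length(g$a1), 0)
  if (any(ni == 0)) return(c(a = NA_real_, total = NA_real_))
  r <- 2; S1 <- sum(ni)
  ybar_pop <- vapply(pops, function(g) mean(c(g$a1, g$a2)), 0)
  ybar <- sum(2 * ni * ybar_pop) / (2 * S1)
  SSP <- sum(2 * ni * (ybar_pop - ybar)^2)
  SSI <- 0; SSG <- 0
  for (g in pops) {
    yij <- (g$a1 + g$a2) / 2
    SSI <- SSI + sum(2 * (yij - mean(c(g$a1, g$a2)))^2)
    SSG <- SSG + sum((g$a1 - yij)^2 + (g$a2 - yij)^2)
  }
  MSP <- SSP / (r - 1); MSI <- SSI / (S1 - r); MSG <- SSG / S1
  nc <- (S1 - sum(ni^2) / S1) / (r - 1)
  a <- (MSP - MSI) / (2 * nc)
  s2I <- (MSI - MSG) / 2
  c(a = a, total = a + s2I + MSG)
}

dosage_counts <- function(d) {
  c(sum(d == 0, na.rm = TRUE), sum(d == 1, na.rm = TRUE),
    sum(d == 2, na.rm = TRUE))
}

# brute-force window F_ST on a panel: ratio of sums of oracle components
oracle_window_fst <- function(panel, pop_i, pop_j) {
  di <- panel$dosage[panel$samples$subpop == pop_i, , drop = FALSE]
  dj <- panel$dosage[panel$samples$subpop == pop_j, , drop = FALSE]
  num <- 0; den <- 0
  for (m in seq_len(ncol(di))) {
    comp <- wc_anova_oracle(di[, m], dj[, m])
    if (anyNA(comp)) next
    ni <- sum(!is.na(di[, m])); nj <- sum(!is.na(dj[, m]))
    pbar <- (sum(di[, m], na.rm = TRUE) + sum(dj[, m], na.rm = TRUE)) /
      (2 * (ni + nj))
    if (pbar <= 0 || pbar >= 1) next
    num <- num + comp["a"]; den <- den + comp["total"]
  }
  if (den == 0) return(NA_real_)
  unname(num / den)
}

# small simulated sweep/null configurations shared across files
small_sweep_config <- function(seed, with_sweep = TRUE) {
  sw <- if (with_sweep)
    list(sweep_spec("pop1", 1, 4e5, 6e5, favored_fraction = 0.9)) else list()
  sim_config(n_subpops = 2, samples_per_subpop = 20, n_chromosomes = 1,
             chrom_length = 1e6, n_snps_per_chrom = 250, drift_f = 0.05,
             n_founder_haplotypes = 8, missing_rate = 0.01, sweeps = sw,
             seed = seed)
}

# minimal hand-made cluster model (uniform posteriors etc.)
manual_cluster_model <- function(K, markers, n_samples, theta, alpha,
                                 rho = NULL) {
  M <- nrow(markers)
  if (is.null(rho)) { rho <- rep(0.05, M); rho[1] <- NA_real_ }
  structure(list(K = K, n_fits = 1,
                 fits = list(list(theta = theta, alpha = alpha, rho = rho,
                                  loglik = 0, trace = 0)),
                 markers = markers, n_samples = n_samples,
                 boundary = c(FALSE, markers$chrom[-1] != markers$chrom[-M])),
            class = "cluster_model")
}
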