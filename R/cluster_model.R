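# Haplotype-cluster hidden Markov model for unphased genotypes.
#
# Hidden state of a diploid individual at marker m is the (ordered) pair of
# haplotype clusters its two chromosomes copy from. Each cluster k has an
# allele frequency theta_k(m); a haplotype emits its allele Bernoulli(theta),
# so a genotype emits P(g | k1, k2) as the convolution of two Bernoullis.
# Between adjacent markers each haplotype chain independently "jumps" with
# probability rho(m), landing in cluster k with probability alpha_k(m); with
# probability 1 - rho(m) it stays. Chromosome boundaries force rho = 1
# (independent chains per chromosome). This is the fastPHASE-style LD model
# that hapFLK and local-haplotype-sharing scans are built on.
#
# The ordered-pair forward/backward pass is vectorized over individuals and
# uses the mixture structure of the transition kernel, so each marker update
# is a handful of N x K^2 matrix operations.

.theta_eps <- 1e-6

# emission probabilities for all ordered cluster pairs at one marker
.pair_emissions <- function(theta_m, i1, i2) {
  t1 <- theta_m[i1]; t2 <- theta_m[i2]
  list(e0 = (1 - t1) * (1 - t2),
       e1 = t1 * (1 - t2) + (1 - t1) * t2,
       e2 = t1 * t2)
}

# N x K^2 emission matrix for one marker (missing genotype -> 1)
.emission_matrix <- function(gm, em, K2) {
  n <- length(gm)
  E <- matrix(1, n, K2)
  for (g in 0:2) {
    idx <- which(!is.na(gm) & gm == g)
    if (length(idx))
      E[idx, ] <- matrix(em[[g + 1L]], length(idx), K2, byrow = TRUE)
  }
  E
}

# One forward/backward sweep. geno: N x M dosage matrix. boundary[m] TRUE
# forces a chain restart before marker m (rho treated as 1 there).
# Returns log-likelihood, optionally EM sufficient statistics and per-marker
# expected cluster-slot usage (N x K per marker, summed into group totals).
.fb_pass <- function(geno, boundary, theta, alpha, rho,
                     em_stats = FALSE, usage_groups = NULL) {
  N <- nrow(geno); M <- ncol(geno); K <- nrow(theta); K2 <- K * K
  i1 <- rep(seq_len(K), K)          # chain-1 cluster of each flattened pair
  i2 <- rep(seq_len(K), each = K)
  A1 <- matrix(0, K2, K); A1[cbind(seq_len(K2), i1)] <- 1
  A2 <- matrix(0, K2, K); A2[cbind(seq_len(K2), i2)] <- 1
  A12 <- A1 + A2

  emis <- vector("list", M)
  for (m in seq_len(M)) emis[[m]] <- .pair_emissions(theta[, m], i1, i2)

  fwd <- vector("list", M)
  ll <- 0
  for (m in seq_len(M)) {
    E <- .emission_matrix(geno[, m], emis[[m]], K2)
    if (m == 1L || boundary[m]) {
      a <- alpha[, m]
      Fm <- matrix(a[i1] * a[i2], N, K2, byrow = TRUE) * E
    } else {
      Fp <- fwd[[m - 1L]]
      r <- rho[m]
      a <- alpha[, m]
      r1 <- Fp %*% A1; r2 <- Fp %*% A2; S <- rowSums(Fp)
      av1 <- a[i1]; av2 <- a[i2]
      G <- (1 - r)^2 * Fp +
        (1 - r) * r * (r1[, i1, drop = FALSE] * rep(av2, each = N) +
                         rep(av1, each = N) * r2[, i2, drop = FALSE]) +
        r^2 * (S %o% (av1 * av2))
      Fm <- G * E
    }
    cs <- rowSums(Fm)
    if (any(cs <= 0)) stop("forward pass underflow at marker ", m)
    ll <- ll + sum(log(cs))
    fwd[[m]] <- Fm / cs
  }

  stats <- NULL
  usage <- NULL
  if (em_stats) {
    stats <- list(theta_num = matrix(0, K, M), theta_den = matrix(0, K, M),
                  jumps = numeric(M), alpha_dest = matrix(0, K, M),
                  init_usage = matrix(0, K, M))
  }
  if (!is.null(usage_groups)) {
    gids <- sort(unique(usage_groups))
    usage <- lapply(gids, function(g) matrix(0, K, M))
    names(usage) <- as.character(gids)
  }

  B <- matrix(1, N, K2)
  i1N <- i1; i2N <- i2
  for (m in rev(seq_len(M))) {
    gam <- fwd[[m]] * B
    gam <- gam / rowSums(gam)
    slot <- gam %*% A12                 # N x K expected slot usage (sums 2)
    if (!is.null(usage)) {
      for (g in names(usage)) {
        rows <- usage_groups == as.integer(g)
        usage[[g]][, m] <- usage[[g]][, m] + colSums(slot[rows, , drop = FALSE])
      }
    }
    if (em_stats) {
      gm <- geno[, m]
      called <- !is.na(gm)
      u_all <- colSums(gam[called, , drop = FALSE])
      stats$theta_den[, m] <- as.numeric(u_all %*% A12)
      u2 <- colSums(gam[called & gm == 2L, , drop = FALSE])
      num <- as.numeric(u2 %*% A12)
      u1 <- colSums(gam[called & gm == 1L, , drop = FALSE])
      if (any(u1 > 0)) {
        em <- emis[[m]]
        t1 <- theta[i1, m] * (1 - theta[i2, m])
        t2 <- theta[i2, m] * (1 - theta[i1, m])
        w <- ifelse(t1 + t2 > 0, t1 / (t1 + t2), 0.5)
        num <- num + as.numeric((u1 * w) %*% A1) +
          as.numeric((u1 * (1 - w)) %*% A2)
      }
      stats$theta_num[, m] <- num
      if (m == 1L || boundary[m]) {
        stats$init_usage[, m] <- as.numeric(colSums(slot) )
      }
    }
    # transition statistics between m-1 and m, and backward recursion
    if (m > 1L && !boundary[m]) {
      E <- .emission_matrix(geno[, m], emis[[m]], K2)
      V <- E * B
      r <- rho[m]; a <- alpha[, m]
      av1 <- a[i1N]; av2 <- a[i2N]
      if (em_stats) {
        Fp <- fwd[[m - 1L]]
        r1 <- Fp %*% A1; r2 <- Fp %*% A2; S <- rowSums(Fp)
        z0m <- (1 - r)^2 * (Fp * V)
        zbm <- (1 - r) * r * (r1[, i1N, drop = FALSE] * rep(av2, each = N)) * V
        zcm <- (1 - r) * r * (rep(av1, each = N) * r2[, i2N, drop = FALSE]) * V
        zdm <- r^2 * (S %o% (av1 * av2)) * V
        z0 <- rowSums(z0m); zb <- rowSums(zbm); zc <- rowSums(zcm)
        zd <- rowSums(zdm)
        Z <- z0 + zb + zc + zd
        stats$jumps[m] <- sum((zb + zc + 2 * zd) / Z)
        dest <- (colSums((zcm + zdm) / Z) %*% A1) +
          (colSums((zbm + zdm) / Z) %*% A2)
        stats$alpha_dest[, m] <- as.numeric(dest)
      }
      W1 <- (V * rep(av2, each = N)) %*% A1   # sum_k2 alpha(k2) V(j1,k2)
      W2 <- (V * rep(av1, each = N)) %*% A2
      s_all <- as.numeric(V %*% (av1 * av2))
      Bp <- (1 - r)^2 * V +
        (1 - r) * r * (W1[, i1N, drop = FALSE] + W2[, i2N, drop = FALSE]) +
        r^2 * matrix(s_all, N, K2)
      B <- Bp / rowSums(Bp)
    } else if (m > 1L) {
      B <- matrix(1, N, K2)               # chain restarts at boundary
    }
  }
  list(loglik = ll, stats = stats, usage = usage)
}

#' Fit a haplotype-cluster HMM to unphased genotypes
#'
#' Fits a fastPHASE-style model with `K` haplotype clusters to a diploid
#' panel by EM from `n_fits` random starts (seeds `seed + fit - 1`), keeping
#' every fit so downstream statistics can be averaged over fits. The hidden
#' state is the unordered pair of clusters the two haplotypes copy from;
#' genotype emissions come from per-cluster allele frequencies, transitions
#' from a per-marker jump probability with per-marker destination weights.
#' Multi-chromosome panels are handled by forcing a chain restart at each
#' chromosome boundary.
#'
#' @param g a QC'd [genotype_panel()].
#' @param K number of haplotype clusters (default 10).
#' @param n_fits number of EM restarts retained (default 5; 20 reproduces
#'   heavier published practice).
#' @param seed integer seed.
#' @param max_iter maximum EM iterations per fit (default 100).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param rho_init initial jump probability between adjacent markers.
#' @param verbose print per-fit convergence.
#' @return Object of class `cluster_model`: list with `K`, `n_fits`, `fits`
#'   (each with `theta` K x M, `alpha` K x M, `rho`, `loglik`, `trace`),
#'   `markers`, and the panel dimensions.
#' @export
fit_cluster_model <- function(g, K = 10, n_fits = 5, seed = 1L,
                              max_iter = 100, tol = 1e-6, rho_init = 0.05,
                              verbose = FALSE) {
  geno <- g$dosage
  N <- nrow(geno); M <- ncol(geno)
  if (M < 2) stop("need >= 2 markers")
  boundary <- c(FALSE, g$markers$chrom[-1] != g$markers$chrom[-M])
  pooled <- pmin(pmax(panel_freq(g), 0.05), 0.95)
  pooled[is.na(pooled)] <- 0.5

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  fits <- vector("list", n_fits)
  for (fit in seq_len(n_fits)) {
    set.seed(seed + fit - 1L)
    theta <- matrix(pmin(pmax(rep(pooled, each = K) +
                                stats::runif(K * M, -0.3, 0.3),
                              .theta_eps), 1 - .theta_eps), K, M)
    alpha <- matrix(1 / K, K, M)
    rho <- rep(rho_init, M); rho[1] <- NA_real_; rho[boundary] <- 1
    trace <- numeric(0)
    ll_prev <- -Inf
    for (it in seq_len(max_iter)) {
      res <- .fb_pass(geno, boundary, theta, alpha, rho, em_stats = TRUE)
      trace <- c(trace, res$loglik)
      st <- res$stats
      upd <- st$theta_den > 0
      theta[upd] <- st$theta_num[upd] / st$theta_den[upd]
      theta <- pmin(pmax(theta, .theta_eps), 1 - .theta_eps)
      free <- which(!boundary & seq_len(M) > 1L)
      rho[free] <- pmin(pmax(st$jumps[free] / (2 * N), 1e-6), 1 - 1e-6)
      # alpha: initial/boundary markers from initial-state usage; interior
      # markers from expected jump destinations, kept unchanged when the
      # expected jump mass is negligible (generalized EM step)
      for (m in c(1L, which(boundary))) {
        tot <- sum(st$init_usage[, m])
        if (tot > 0) alpha[, m] <- pmax(st$init_usage[, m] / tot, 1e-12)
      }
      for (m in free) {
        tot <- sum(st$alpha_dest[, m])
        if (tot > 1e-8) alpha[, m] <- pmax(st$alpha_dest[, m] / tot, 1e-12)
      }
      alpha <- sweep(alpha, 2, colSums(alpha), "/")
      if (is.finite(ll_prev) &&
          abs(res$loglik - ll_prev) < tol * abs(ll_prev)) break
      ll_prev <- res$loglik
    }
    final <- .fb_pass(geno, boundary, theta, alpha, rho)
    trace <- c(trace, final$loglik)
    if (verbose)
      message(sprintf("fit %d: loglik %.2f after %d EM iterations",
                      fit, final$loglik, length(trace) - 1L))
    fits[[fit]] <- list(theta = theta, alpha = alpha, rho = rho,
                        loglik = final$loglik, trace = trace)
  }
  structure(list(K = K, n_fits = n_fits, fits = fits,
                 markers = g$markers, n_samples = N, boundary = boundary),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  lls <- vapply(x$fits, `[[`, 0, "loglik")
  cat("cluster_model: K =", x$K, ",", x$n_fits, "EM fits over",
      nrow(x$markers), "markers,", x$n_samples, "samples\n")
  cat(sprintf("log-likelihood: best %.2f, worst %.2f\n", max(lls), min(lls)))
  invisible(x)
}

#' @export
logLik.cluster_model <- function(object, ...) {
  lls <- vapply(object$fits, `[[`, 0, "loglik")
  structure(max(lls), df = NA, class = "logLik")
}

#' Expected haplotype-cluster frequencies per subpopulation
#'
#' For each EM fit, runs a posterior pass and averages each individual's
#' expected cluster-slot usage (two slots per individual) within
#' subpopulations, giving the local cluster frequency `f_k(m)` of each
#' subpopulation at each marker -- the quantity hapFLK and the
#' local-haplotype-sharing score operate on.
#'
#' @param model a [fit_cluster_model()] result.
#' @param g the panel the model was fitted to.
#' @param pops subpopulation labels (default all).
#' @return List over fits; each element a 3-d array `K x M x n_pops`.
#' @export
expected_cluster_freqs <- function(model, g, pops = NULL) {
  if (is.null(pops)) pops <- subpops(g)
  grp <- match(g$samples$subpop, pops)
  keep <- !is.na(grp)
  geno <- g$dosage[keep, , drop = FALSE]
  grp <- grp[keep]
  counts <- table(factor(grp, levels = seq_along(pops)))
  out <- vector("list", model$n_fits)
  for (fit in seq_len(model$n_fits)) {
    fp <- model$fits[[fit]]
    res <- .fb_pass(geno, model$boundary, fp$theta, fp$alpha, fp$rho,
                    usage_groups = grp)
    arr <- array(0, c(model$K, nrow(model$markers), length(pops)),
                 dimnames = list(NULL, NULL, pops))
    for (i in seq_along(pops)) {
      u <- res$usage[[as.character(i)]]
      arr[, , i] <- u / (2 * as.integer(counts[i]))
    }
    out[[fit]] <- arr
  }
  out
}
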