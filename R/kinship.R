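#' Reynolds genetic distance between two populations
#'
#' Allele-frequency-based coancestry distance appropriate for short-term
#' drift: `theta = sum_l (p_i - p_j)^2 / sum_l (p_i + p_j - 2 p_i p_j)`,
#' aggregated as a ratio of sums over loci. 0 for identical frequency
#' vectors; 1 when the two populations are fixed for opposite alleles at
#' every locus.
#'
#' When haploid sample sizes `m_i`, `m_j` (numbers of called alleles) are
#' supplied, the numerator is bias-corrected by subtracting the sampling
#' variance of each sample frequency (`p(1-p)/(m-1)`), so the estimator
#' targets the pure drift signal; the corrections vanish at fixed loci, so
#' the fixed-opposite maximum of 1 is unaffected.
#'
#' @param freqs_i,freqs_j per-SNP alternate-allele frequencies.
#' @param m_i,m_j optional per-SNP haploid sample sizes for bias correction.
#' @return Scalar distance in `[0, 1]` (bias correction can push slightly
#'   below 0; clamped at 0).
#' @export
reynolds_distance <- function(freqs_i, freqs_j, m_i = NULL, m_j = NULL) {
  stopifnot(length(freqs_i) == length(freqs_j))
  ok <- !is.na(freqs_i) & !is.na(freqs_j)
  p <- freqs_i[ok]; q <- freqs_j[ok]
  den <- p + q - 2 * p * q
  num <- (p - q)^2
  if (!is.null(m_i) && !is.null(m_j)) {
    mi <- m_i[ok]; mj <- m_j[ok]
    num <- num - p * (1 - p) / pmax(mi - 1, 1) - q * (1 - q) / pmax(mj - 1, 1)
  }
  inf <- den > 0
  if (!any(inf)) stop("no SNP informative in both populations")
  max(sum(num[inf]) / sum(den[inf]), 0)
}

#' Pairwise Reynolds-based drift distance matrix for a panel
#'
#' With `additive = TRUE` (the default) entries are twice the Reynolds
#' coancestry, whose expectation under independent drift is `f_i + f_j` --
#' the additive path length a tree-fitting method needs so that branch
#' lengths estimate per-population drift. `additive = FALSE` returns the
#' classic Reynolds coancestry (expectation `(f_i + f_j) / 2`). Sampling
#' bias correction uses per-SNP called allele counts.
#'
#' @param g a [genotype_panel()].
#' @param additive return the additive drift scale (default TRUE).
#' @param bias_correct subtract finite-sample variance (default TRUE).
#' @return Symmetric distance matrix over subpopulations.
#' @export
reynolds_dist_matrix <- function(g, additive = TRUE, bias_correct = TRUE) {
  fr <- subpop_freqs(g)
  pops <- rownames(fr)
  m <- lapply(pops, function(p)
    2 * colSums(!is.na(g$dosage[g$samples$subpop == p, , drop = FALSE])))
  names(m) <- pops
  d <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_len(i - 1L)) {
    d[i, j] <- d[j, i] <- if (bias_correct)
      reynolds_distance(fr[i, ], fr[j, ], m[[i]], m[[j]])
    else reynolds_distance(fr[i, ], fr[j, ])
  }
  if (additive) 2 * d else d
}

#' Population kinship matrix from a neighbor-joining tree
#'
#' Builds a neighbor-joining tree from the distance matrix, roots it at the
#' midpoint (no outgroup), and derives the drift covariance matrix used by
#' the FLK/hapFLK tests: `F[i, j]` is the shared branch length from the root
#' to the most recent common ancestor of leaves `i` and `j`, and `F[i, i]`
#' the root-to-leaf path length. Negative NJ branch lengths are clipped to 0
#' with a warning. With exactly two populations the distance is split
#' equally between the two branches.
#'
#' @param d symmetric distance matrix with population names.
#' @return An object of class `kinship_matrix`: the matrix, with the rooted
#'   tree (an `ape::phylo`) as attribute `tree`.
#' @export
kinship_from_tree <- function(d) {
  d <- as.matrix(d)
  pops <- rownames(d)
  if (is.null(pops)) stop("distance matrix needs population names")
  if (nrow(d) < 2) stop("need >= 2 populations")
  if (nrow(d) == 2) {
    f <- diag(c(d[1, 2] / 2, d[1, 2] / 2))
    dimnames(f) <- list(pops, pops)
    tree <- ape::read.tree(
      text = sprintf("(%s:%f,%s:%f);", pops[1], d[1, 2] / 2,
                     pops[2], d[1, 2] / 2))
    return(structure(f, tree = tree, class = c("kinship_matrix", "matrix")))
  }
  tree <- ape::nj(stats::as.dist(d))
  if (any(tree$edge.length < 0)) {
    warning("negative NJ branch length(s) clipped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree <- phangorn::midpoint(tree)
  n <- length(tree$tip.label)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  dn <- ape::dist.nodes(tree)
  f <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  mrcas <- ape::mrca(tree)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    anc <- if (i == j) i else mrcas[i, j]
    f[i, j] <- dn[root, anc]
  }
  diag(f) <- dn[root, seq_len(n)]
  f <- f[pops, pops]
  structure(f, tree = tree, class = c("kinship_matrix", "matrix"))
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("kinship_matrix over", nrow(x), "populations:\n")
  print(round(unclass(x)[,], 5))
  invisible(x)
}

#' Write the kinship tree as Newick
#' @param f a `kinship_matrix`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_kinship_tree <- function(f, path) {
  ape::write.tree(attr(f, "tree"), file = path)
  invisible(path)
}

# inverse with pseudo-inverse fallback for singular covariance
solve_psd <- function(m) {
  out <- tryCatch(solve(m), error = function(e) NULL)
  if (is.null(out) || !all(is.finite(out))) {
    warning("singular covariance; using Moore-Penrose pseudo-inverse")
    out <- MASS::ginv(m)
  }
  out
}

#' FLK test of allele-frequency differentiation at one SNP
#'
#' Extension of the Lewontin-Krakauer test that models drift covariance
#' between populations through the kinship matrix `F`. The ancestral
#' frequency is estimated as `p0 = (1' F^-1 p) / (1' F^-1 1)` and the
#' statistic is the quadratic form
#' `T = (p - p0 1)' [p0 (1 - p0) F]^-1 (p - p0 1)`, compared to a chi-square
#' with `n_pops - 1` degrees of freedom.
#'
#' @param p per-population alternate-allele frequencies at one SNP.
#' @param f a `kinship_matrix` (or plain matrix) in the same population
#'   order.
#' @param f_inv optional precomputed inverse of `f`.
#' @return list with `T`, `p_value`, `neg_log10_p` and `p0`; `NULL` when the
#'   SNP is monomorphic across populations (skipped).
#' @export
flk_test <- function(p, f, f_inv = NULL) {
  npop <- length(p)
  stopifnot(nrow(f) == npop)
  if (is.null(f_inv)) f_inv <- solve_psd(unclass(f)[,])
  one <- rep(1, npop)
  p0 <- as.numeric(one %*% f_inv %*% p) / as.numeric(one %*% f_inv %*% one)
  if (p0 <= 0 || p0 >= 1 || all(p == p[1]) && (p[1] %in% c(0, 1)))
    return(NULL)
  res <- p - p0
  t_stat <- as.numeric(res %*% f_inv %*% res) / (p0 * (1 - p0))
  pv <- stats::pchisq(t_stat, df = npop - 1, lower.tail = FALSE)
  list(T = t_stat, p_value = pv, neg_log10_p = -log10(pv), p0 = p0)
}

#' Genome-wide FLK scan
#'
#' Applies [flk_test()] to every SNP of a panel. Monomorphic SNPs are
#' skipped. Significance is flagged at `-log10(p) > threshold`.
#'
#' Sample frequencies carry binomial noise on top of drift:
#' `Var(p_hat_i) = p0(1-p0) [f_i + (1-f_i)/m_i]` with `m_i` called alleles.
#' With `adjust_sampling = TRUE` (default) the kinship diagonal is augmented
#' by `(1 - f_i)/m_i` (per-population mean called alleles), which keeps the
#' chi-square null calibration at realistic sample sizes.
#'
#' @param g a QC'd [genotype_panel()].
#' @param f a `kinship_matrix` over the panel's subpopulations.
#' @param threshold `-log10(p)` significance threshold (default 4).
#' @param adjust_sampling add the finite-sample term to the diagonal.
#' @return data.frame of class `flk_scan`: `marker_id`, `chrom`, `pos`, `T`,
#'   `p_value`, `neg_log10_p`, `significant`.
#' @export
flk_scan <- function(g, f, threshold = 4, adjust_sampling = TRUE) {
  pops <- rownames(f)
  fr <- subpop_freqs(g)[pops, , drop = FALSE]
  fmat <- unclass(f)[,]
  if (adjust_sampling) {
    m <- vapply(pops, function(p)
      2 * mean(colSums(!is.na(g$dosage[g$samples$subpop == p, , drop = FALSE]))),
      0)
    diag(fmat) <- diag(fmat) + (1 - diag(fmat)) / m
  }
  f_inv <- solve_psd(fmat)
  m <- ncol(fr)
  t_stat <- p_val <- rep(NA_real_, m)
  for (i in seq_len(m)) {
    p <- fr[, i]
    if (anyNA(p)) next
    r <- flk_test(p, f, f_inv)
    if (is.null(r)) next
    t_stat[i] <- r$T; p_val[i] <- r$p_value
  }
  out <- data.frame(marker_id = g$markers$marker_id, chrom = g$markers$chrom,
                    pos = g$markers$pos, T = t_stat, p_value = p_val,
                    neg_log10_p = -log10(p_val),
                    significant = !is.na(p_val) & -log10(p_val) > threshold,
                    stringsAsFactors = FALSE)
  class(out) <- c("flk_scan", "data.frame")
  attr(out, "threshold") <- threshold
  out
}
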