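#' Weir-Cockerham two-population variance components for one SNP
#'
#' Computes the among-population component `a` and the total
#' `a + b + c` of the Weir-Cockerham (1984) F_ST estimator for two
#' populations from genotype counts, using observed heterozygosity.
#'
#' @param counts_i,counts_j numeric vectors `c(n0, n1, n2)` of called
#'   genotype counts (dosage classes) in each population, or 3 x M matrices
#'   for M SNPs at once.
#' @return list with numeric vectors `a`, `total` (= a + b + c) and logical
#'   `informative` (FALSE when either population has no called genotype or
#'   the SNP is monomorphic in both populations pooled).
#' @export
snp_fst_components <- function(counts_i, counts_j) {
  ci <- if (is.matrix(counts_i)) counts_i else matrix(counts_i, 3)
  cj <- if (is.matrix(counts_j)) counts_j else matrix(counts_j, 3)
  stopifnot(nrow(ci) == 3, nrow(cj) == 3, ncol(ci) == ncol(cj))
  ni <- colSums(ci); nj <- colSums(cj)
  ok <- ni > 0 & nj > 0
  pi_ <- (ci[2, ] + 2 * ci[3, ]) / (2 * ni)
  pj <- (cj[2, ] + 2 * cj[3, ]) / (2 * nj)
  hi <- ci[2, ] / ni
  hj <- cj[2, ] / nj

  r <- 2
  nbar <- (ni + nj) / r
  nc <- (r * nbar - (ni^2 + nj^2) / (r * nbar)) / (r - 1)
  pbar <- (ni * pi_ + nj * pj) / (r * nbar)
  s2 <- (ni * (pi_ - pbar)^2 + nj * (pj - pbar)^2) / ((r - 1) * nbar)
  hbar <- (ni * hi + nj * hj) / (r * nbar)

  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  informative <- ok & pbar > 0 & pbar < 1 & nbar > 1 & nc > 0
  a[!informative] <- NA_real_
  total <- a + b + cc
  list(a = unname(a), total = unname(total), informative = unname(informative))
}

#' Non-overlapping window grid index for marker positions
#'
#' Windows are 1-based closed intervals `[size*k + 1, size*(k + 1)]` anchored
#' at position 1 on every chromosome.
#'
#' @param pos 1-based positions.
#' @param size window size in bp (default 10 kb).
#' @return data.frame with `index` (0-based window index), `start`, `end`.
#' @export
window_of <- function(pos, size = 10000) {
  k <- floor((pos - 1) / size)
  data.frame(index = k, start = size * k + 1, end = size * (k + 1))
}

#' Windowed pairwise Weir-Cockerham F_ST
#'
#' For each subpopulation pair, per-SNP variance components are aggregated
#' within non-overlapping windows as a ratio of sums (sum of `a` over sum of
#' `a + b + c` across informative SNPs), which is more stable than averaging
#' per-SNP ratios for low-MAF SNPs. Negative window values are retained, not
#' clamped, so the downstream standardization stays unbiased. Windows without
#' an informative SNP for a pair get `NA` for that pair.
#'
#' @param g a QC'd [genotype_panel()].
#' @param pairs 2-column character matrix of subpopulation pairs (one row per
#'   pair), or `NULL` for all unordered pairs.
#' @param window_size window width in bp (default 10 kb).
#' @return An object of class `fst_panel`: list with `windows` (data.frame
#'   `chrom`, `index`, `start`, `end`), `fst` (windows x pairs matrix),
#'   `n_snps` (informative SNP counts) and `pairs` (data.frame `i`, `j`).
#' @export
window_fst <- function(g, pairs = NULL, window_size = 10000) {
  pops <- subpops(g)
  if (length(pops) < 2) stop("need >= 2 subpopulations")
  if (is.null(pairs)) {
    cmb <- utils::combn(pops, 2)
    pairs <- t(cmb)
  }
  pairs <- matrix(as.character(pairs), ncol = 2)
  counts <- lapply(pops, function(p) genotype_counts(g, p))
  names(counts) <- pops

  w <- window_of(g$markers$pos, window_size)
  wkey <- paste(g$markers$chrom, w$index)
  uw <- !duplicated(wkey)
  windows <- data.frame(chrom = g$markers$chrom[uw], index = w$index[uw],
                        start = w$start[uw], end = w$end[uw],
                        stringsAsFactors = FALSE)
  ord <- order(match(windows$chrom, unique(g$markers$chrom)), windows$start)
  windows <- windows[ord, , drop = FALSE]
  rownames(windows) <- NULL
  wid <- match(wkey, paste(windows$chrom, windows$index))

  npair <- nrow(pairs)
  fst <- matrix(NA_real_, nrow(windows), npair)
  nsnp <- matrix(0L, nrow(windows), npair)
  pair_names <- paste(pairs[, 1], pairs[, 2], sep = ":")
  colnames(fst) <- colnames(nsnp) <- pair_names
  for (k in seq_len(npair)) {
    comp <- snp_fst_components(counts[[pairs[k, 1]]], counts[[pairs[k, 2]]])
    inf <- comp$informative
    num <- rowsum(ifelse(inf, comp$a, 0), wid)
    den <- rowsum(ifelse(inf, comp$total, 0), wid)
    cnt <- rowsum(as.integer(inf), wid)
    idx <- as.integer(rownames(num))
    val <- ifelse(cnt > 0 & den != 0, num / den, NA_real_)
    fst[idx, k] <- val
    nsnp[idx, k] <- cnt
  }
  structure(list(windows = windows, fst = fst, n_snps = nsnp,
                 pairs = data.frame(i = pairs[, 1], j = pairs[, 2],
                                    stringsAsFactors = FALSE),
                 window_size = window_size, subpops = pops),
            class = "fst_panel")
}

#' @export
print.fst_panel <- function(x, ...) {
  cat("fst_panel:", nrow(x$windows), "windows x", nrow(x$pairs),
      "subpopulation pairs (window size", x$window_size, "bp)\n")
  cat("pairs:", paste(colnames(x$fst), collapse = ", "), "\n")
  invisible(x)
}

#' Number of windows in the top fraction of an empirical distribution
#'
#' @param n_windows number of analyzed windows.
#' @param top_fraction fraction retained (default 0.001, i.e. the top 0.1%).
#' @return `ceiling(top_fraction * n_windows)`.
#' @export
top_window_count <- function(n_windows, top_fraction = 0.001) {
  as.integer(ceiling(top_fraction * n_windows))
}

#' Locus-specific divergence statistic d_i per window and subpopulation
#'
#' For subpopulation `i` and window `w`,
#' `d_i(w) = sum_{j != i} (F_ST^{ij}(w) - E[F_ST^{ij}]) / sd[F_ST^{ij}]`:
#' the sum over all other subpopulations of the pairwise window F_ST
#' standardized by that pair's genome-wide mean and standard deviation. Large
#' values flag windows where `i` has diverged more than drift predicts.
#'
#' Moments (and d_i) are computed over the windows informative for every
#' pair, so the genome-wide mean of d_i is exactly 0 for every subpopulation.
#' The standard deviation uses the population formula (divisor N).
#'
#' @param panel an [window_fst()] result covering all pairs of the wanted
#'   subpopulations.
#' @param subpops subpopulation labels (default: all in the panel).
#' @return An object of class `di_scan`: list with `windows` (analyzed
#'   windows), `di` (windows x subpopulations matrix), `moments` (per-pair
#'   mean/sd) and `n_snps`.
#' @export
compute_di <- function(panel, subpops = NULL) {
  stopifnot(inherits(panel, "fst_panel"))
  if (is.null(subpops)) subpops <- panel$subpops
  if (length(subpops) < 2) stop("need >= 2 subpopulations")
  use_pair <- panel$pairs$i %in% subpops & panel$pairs$j %in% subpops
  if (sum(use_pair) != choose(length(subpops), 2))
    stop("fst_panel does not cover all pairs of the requested subpopulations")
  fst <- panel$fst[, use_pair, drop = FALSE]
  prs <- panel$pairs[use_pair, , drop = FALSE]
  common <- stats::complete.cases(fst)
  if (sum(common) < 2) stop("fewer than 2 windows analyzed for all pairs")
  fst <- fst[common, , drop = FALSE]
  windows <- panel$windows[common, , drop = FALSE]
  rownames(windows) <- NULL

  mu <- colMeans(fst)
  n <- nrow(fst)
  sdv <- sqrt(colMeans(fst^2) - mu^2)   # population formula, divisor N
  z <- fst
  for (k in seq_len(ncol(fst))) {
    if (sdv[k] == 0) {
      warning("pair ", colnames(fst)[k],
              " has zero F_ST variance; its summand is set to 0")
      z[, k] <- 0
    } else z[, k] <- (fst[, k] - mu[k]) / sdv[k]
  }
  di <- matrix(0, n, length(subpops), dimnames = list(NULL, subpops))
  for (s in subpops) {
    involve <- prs$i == s | prs$j == s
    di[, s] <- rowSums(z[, involve, drop = FALSE])
  }
  structure(list(windows = windows, di = di,
                 moments = data.frame(pair = colnames(fst), mean = mu,
                                      sd = sdv, row.names = NULL),
                 n_snps = panel$n_snps[common, use_pair, drop = FALSE],
                 window_size = panel$window_size),
            class = "di_scan")
}

#' @export
print.di_scan <- function(x, ...) {
  cat("di_scan:", nrow(x$windows), "windows x", ncol(x$di),
      "subpopulations\n")
  cat("per-subpopulation max d_i:\n")
  print(round(apply(x$di, 2, max), 3))
  invisible(x)
}

#' Significant d_i windows (top fraction of the empirical distribution)
#'
#' Selects, per subpopulation, the `ceiling(top_fraction * N)` windows with
#' the highest d_i. Ties at the cutoff value are broken by (chromosome,
#' start) ascending.
#'
#' @param scores a [compute_di()] result.
#' @param top_fraction retained fraction (default 0.001).
#' @return Named list (per subpopulation) of data.frames of significant
#'   windows (`chrom`, `start`, `end`, `di`), each sorted by genome order.
#' @export
significant_windows <- function(scores, top_fraction = 0.001) {
  stopifnot(inherits(scores, "di_scan"))
  n <- nrow(scores$windows)
  if (n < 1000)
    warning("only ", n, " analyzed windows; empirical top-fraction ",
            "thresholds are unstable below ~1000")
  k <- top_window_count(n, top_fraction)
  chrom_rank <- match(scores$windows$chrom, unique(scores$windows$chrom))
  out <- list()
  for (s in colnames(scores$di)) {
    o <- order(-scores$di[, s], chrom_rank, scores$windows$start)
    sel <- sort(o[seq_len(k)])
    out[[s]] <- data.frame(chrom = scores$windows$chrom[sel],
                           start = scores$windows$start[sel],
                           end = scores$windows$end[sel],
                           di = scores$di[sel, s],
                           stringsAsFactors = FALSE)
  }
  out
}

#' Export a d_i scan as a per-window TSV
#'
#' One row per (window, subpopulation) with the d_i value and significance
#' flag at the given top fraction.
#'
#' @param scores a [compute_di()] result.
#' @param path output TSV path.
#' @param top_fraction significance fraction (default 0.001).
#' @return Invisibly, the path.
#' @export
write_di_table <- function(scores, path, top_fraction = 0.001) {
  sig <- suppressWarnings(significant_windows(scores, top_fraction))
  rows <- list()
  for (s in colnames(scores$di)) {
    key <- paste(scores$windows$chrom, scores$windows$start)
    flag <- key %in% paste(sig[[s]]$chrom, sig[[s]]$start)
    rows[[s]] <- data.frame(chrom = scores$windows$chrom,
                            start = scores$windows$start,
                            end = scores$windows$end, subpop = s,
                            n_snps = apply(scores$n_snps, 1, max),
                            di = scores$di[, s], significant = flag,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
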