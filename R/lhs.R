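#' Local haplotype sharing score within one subpopulation
#'
#' The probability that two haplotypes drawn at random from the
#' subpopulation descend from the same ancestral haplotype (latent cluster)
#' at a marker: `s(m) = sum_k f_k(m)^2`, where `f_k(m)` is the
#' subpopulation's expected cluster frequency from the fitted HMM. `s`
#' ranges from `1/K` (uniform cluster usage) to 1 (all haplotypes in one
#' cluster); a selective sweep drives it up locally. Averaged over EM fits.
#'
#' This score is a cluster-homozygosity proxy for ancestral-haplotype
#' sharing: it preserves the downstream role of the Bayesian
#' local-haplotype-sharing machinery (confirming shared ancestral haplotypes
#' at candidate regions) without its Bayes-factor computation, and all
#' outputs label it as such.
#'
#' @param model a [fit_cluster_model()] result.
#' @param g the fitted panel.
#' @param subpop subpopulation label to score.
#' @return data.frame of class `lhs_track`: `marker_id`, `chrom`, `pos`,
#'   `sharing` (with the subpopulation as attribute `subpop`).
#' @export
lhs_score <- function(model, g, subpop) {
  if (!(subpop %in% subpops(g))) stop("unknown subpopulation: ", subpop)
  freqs <- expected_cluster_freqs(model, g, subpop)
  s <- rowMeans(vapply(freqs, function(arr) {
    fk <- matrix(arr[, , 1], nrow = dim(arr)[1])
    colSums(fk^2)
  }, numeric(nrow(model$markers))))
  out <- data.frame(marker_id = model$markers$marker_id,
                    chrom = model$markers$chrom, pos = model$markers$pos,
                    sharing = s, stringsAsFactors = FALSE)
  class(out) <- c("lhs_track", "data.frame")
  attr(out, "subpop") <- subpop
  out
}

#' Significant local-haplotype-sharing clusters with orphan removal
#'
#' Standardizes the sharing track genome-wide (median/MAD), flags markers
#' whose `-log10` normal upper-tail probability exceeds the threshold, and
#' keeps only runs of at least `min_run` contiguous flagged markers --
#' isolated ("orphan") signals are removed because a single SNP does not
#' constitute a shared haplotype.
#'
#' @param track an [lhs_score()] result.
#' @param threshold `-log10` tail-probability threshold (default 5, the
#'   empirical-tail analog of a log10 Bayes-factor cutoff).
#' @param min_run minimum run length kept (default 2).
#' @return list with `flags` (per-marker data.frame adding `z`,
#'   `neg_log10_tail`, `significant`, `in_cluster`) and `clusters`
#'   (data.frame of significant runs: `chrom`, `start`, `end`, `n_snps`,
#'   `peak`).
#' @export
lhs_significant <- function(track, threshold = 5, min_run = 2) {
  s <- track$sharing
  madv <- stats::mad(s)
  if (madv == 0) stop("constant sharing track (MAD = 0); cannot flag")
  z <- (s - stats::median(s)) / madv
  nlt <- -stats::pnorm(z, lower.tail = FALSE, log.p = TRUE) / log(10)
  flag <- nlt > threshold
  runs <- rle(paste(track$chrom, flag))
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  keep <- flag[idx_start] & runs$lengths >= min_run
  in_cluster <- logical(length(s))
  rows <- list()
  for (r in which(keep)) {
    i <- idx_start[r]:idx_end[r]
    in_cluster[i] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = track$chrom[i[1]], start = min(track$pos[i]),
      end = max(track$pos[i]), n_snps = length(i), peak = max(nlt[i]),
      stringsAsFactors = FALSE)
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_snps = integer(), peak = numeric(), stringsAsFactors = FALSE)
  flags <- cbind(as.data.frame(track),
                 z = z, neg_log10_tail = nlt, significant = flag,
                 in_cluster = in_cluster)
  list(flags = flags, clusters = clusters)
}
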