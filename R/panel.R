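#' Genotype panel container
#'
#' Bundles a samples x markers diploid dosage matrix (values 0, 1, 2 or `NA`
#' for missing) with per-sample subpopulation labels and a marker map.
#' This is the substrate of every scan in the package.
#'
#' @param dosage integer/numeric matrix, samples in rows, markers in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param samples data.frame with columns `sample_id` and `subpop`.
#' @param markers data.frame with columns `marker_id`, `chrom`, `pos`
#'   (1-based). Positions must be strictly increasing within a chromosome.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosage, samples, markers) {
  dosage <- as.matrix(dosage)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "subpop") %in% names(samples)),
            all(c("marker_id", "chrom", "pos") %in% names(markers)))
  if (nrow(dosage) != nrow(samples))
    stop("dosage has ", nrow(dosage), " rows but samples has ",
         nrow(samples), " entries")
  if (ncol(dosage) != nrow(markers))
    stop("dosage has ", ncol(dosage), " columns but markers has ",
         nrow(markers), " entries")
  if (anyDuplicated(markers$marker_id))
    stop("duplicated marker_id in marker map")
  bad <- dosage[!is.na(dosage) & !(dosage %in% 0:2)]
  if (length(bad))
    stop("dosage values outside {0,1,2,NA}: ", paste(unique(bad), collapse = ", "))
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("marker positions not strictly increasing on chromosome ", ch)
  }
  rownames(dosage) <- samples$sample_id
  colnames(dosage) <- markers$marker_id
  structure(list(dosage = dosage, samples = samples, markers = markers),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$dosage), "samples x", ncol(x$dosage), "markers\n")
  tab <- table(x$samples$subpop)
  cat("subpopulations:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "), "\n")
  cat("chromosomes:", paste(unique(x$markers$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
summary.genotype_panel <- function(object, ...) {
  maf <- panel_maf(object)
  out <- list(
    n_samples = nrow(object$dosage),
    n_markers = ncol(object$dosage),
    subpops = table(object$samples$subpop),
    missing_rate = mean(is.na(object$dosage)),
    maf_quartiles = stats::quantile(maf, c(0, .25, .5, .75, 1), na.rm = TRUE))
  class(out) <- "summary.genotype_panel"
  out
}

#' @export
print.summary.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", x$n_samples, "samples x", x$n_markers, "markers\n")
  print(x$subpops)
  cat(sprintf("missing rate: %.4f\n", x$missing_rate))
  cat("pooled MAF quartiles:\n")
  print(round(x$maf_quartiles, 4))
  invisible(x)
}

#' Subpopulation labels of a panel
#' @param g a `genotype_panel`.
#' @return Character vector of unique subpopulation labels, in order of first
#'   appearance.
#' @export
subpops <- function(g) unique(g$samples$subpop)

#' Restrict a panel to a set of samples and/or markers
#'
#' @param g a `genotype_panel`.
#' @param samples logical/integer/character index into samples, or a
#'   subpopulation label vector via `subpop=`.
#' @param markers logical/integer/character index into markers.
#' @param subpop keep only samples whose label is in this set.
#' @return A `genotype_panel`.
#' @export
subset_panel <- function(g, samples = NULL, markers = NULL, subpop = NULL) {
  si <- seq_len(nrow(g$dosage))
  if (!is.null(subpop)) si <- si[g$samples$subpop %in% subpop]
  if (!is.null(samples)) si <- intersect(si, seq_len(nrow(g$dosage))[samples])
  mi <- if (is.null(markers)) seq_len(ncol(g$dosage)) else seq_len(ncol(g$dosage))[markers]
  genotype_panel(g$dosage[si, mi, drop = FALSE],
                 g$samples[si, , drop = FALSE],
                 g$markers[mi, , drop = FALSE])
}

#' Pooled alternate-allele frequency per marker
#' @param g a `genotype_panel`.
#' @return Numeric vector, `NA` where no genotype is called.
#' @export
panel_freq <- function(g) {
  colMeans(g$dosage, na.rm = TRUE) / 2
}

#' Pooled minor allele frequency per marker
#' @param g a `genotype_panel`.
#' @return Numeric vector in `[0, 0.5]`.
#' @export
panel_maf <- function(g) {
  p <- panel_freq(g)
  pmin(p, 1 - p)
}

#' Per-subpopulation allele frequencies
#'
#' @param g a `genotype_panel`.
#' @return Matrix, subpopulations in rows, markers in columns; alternate-allele
#'   frequency among called genotypes.
#' @export
subpop_freqs <- function(g) {
  pops <- subpops(g)
  out <- matrix(NA_real_, length(pops), ncol(g$dosage),
                dimnames = list(pops, colnames(g$dosage)))
  for (p in pops) {
    rows <- g$samples$subpop == p
    out[p, ] <- colMeans(g$dosage[rows, , drop = FALSE], na.rm = TRUE) / 2
  }
  out
}

#' Per-marker genotype counts for one subpopulation
#'
#' Tallies called genotypes by dosage class.
#'
#' @param g a `genotype_panel`.
#' @param pop subpopulation label.
#' @return Matrix with rows `n0`, `n1`, `n2` (counts of dosage 0/1/2) and one
#'   column per marker.
#' @export
genotype_counts <- function(g, pop) {
  d <- g$dosage[g$samples$subpop == pop, , drop = FALSE]
  rbind(n0 = colSums(d == 0, na.rm = TRUE),
        n1 = colSums(d == 1, na.rm = TRUE),
        n2 = colSums(d == 2, na.rm = TRUE))
}
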