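# Worked-example tables from a high-density selection scan of six American
# Quarter Horse performance subpopulations (cutting, halter, racing,
# reining, western pleasure, working cow). They exercise the ROI/consensus
# bookkeeping on real published-scale numbers without requiring the
# underlying genotypes.

qh_file <- function(name) {
  system.file("extdata", name, package = "sweepscan", mustWork = TRUE)
}

#' Per-subpopulation d_i ROI and gene counts (Quarter Horse example)
#'
#' Summary of a windowed d_i genome scan over six Quarter Horse performance
#' subpopulations: number of merged regions of interest and number of
#' annotated genes within them, per subpopulation.
#'
#' @return data.frame with `subpop`, `n_roi`, `n_genes`.
#' @export
qh_roi_summary <- function() {
  utils::read.table(qh_file("qh_roi_summary.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Significant d_i windows shared between subpopulations (Quarter Horse example)
#'
#' Window-by-subpopulation membership matrix of 10 kb d_i windows that were
#' significant in two or more of the six Quarter Horse performance
#' subpopulations. `pos` is the window's reported position (bp) on the
#' autosome.
#'
#' @return data.frame with `chrom`, `pos` and one 0/1 column per
#'   subpopulation.
#' @export
qh_shared_windows <- function() {
  utils::read.table(qh_file("qh_shared_windows.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
}

#' hapFLK regions of interest (Quarter Horse example)
#'
#' The regions flagged by a hapFLK scan over all six subpopulations
#' combined: interval, lowest p-value, gene symbols within the region
#' (`"-"` when none annotated), and the per-subpopulation method(s) that
#' independently flagged the region (`d_i`, `hapQTL`, `Both`, or `-`).
#'
#' @return data.frame with `chrom`, `start`, `end`, `lowest_p`, `genes` and
#'   one column per subpopulation.
#' @export
qh_hapflk_regions <- function() {
  utils::read.table(qh_file("qh_hapflk_regions.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
}

#' Distinct gene symbols in an annotated ROI table
#'
#' @param regions data.frame with a `genes` column of comma-separated gene
#'   symbols (`"-"` or `""` meaning none).
#' @return Character vector of distinct gene symbols.
#' @export
roi_gene_symbols <- function(regions) {
  g <- unlist(strsplit(regions$genes, ","))
  unique(g[!(g %in% c("-", "")) & !is.na(g)])
}
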