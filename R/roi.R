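#' Merge significant windows into regions of interest
#'
#' Single-linkage merge: consecutive windows on the same chromosome whose
#' edge-to-edge gap (start of the next minus end of the previous) is at most
#' `max_gap` join one region of interest (ROI). Singleton windows remain
#' single-window ROI. Idempotent and order-invariant (input is sorted
#' internally).
#'
#' @param windows data.frame with `chrom`, `start`, `end` (1-based closed)
#'   and optionally a statistic column named by `stat_col`.
#' @param max_gap maximum merge gap in bp (default 500 kb), inclusive.
#' @param method,subpop provenance labels stored on each ROI.
#' @param stat_col name of the statistic column used for `peak_stat`.
#' @return data.frame of class `roi`: `chrom`, `start`, `end`, `n_windows`,
#'   `peak_stat`, `method`, `subpop`.
#' @export
merge_windows <- function(windows, max_gap = 500000, method = NA_character_,
                          subpop = NA_character_, stat_col = NULL) {
  if (is.null(windows) || nrow(windows) == 0) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      peak_stat = numeric(), method = character(),
                      subpop = character(), stringsAsFactors = FALSE)
    class(out) <- c("roi", "data.frame")
    return(out)
  }
  stat <- if (!is.null(stat_col) && stat_col %in% names(windows))
    windows[[stat_col]] else rep(NA_real_, nrow(windows))
  o <- order(match(windows$chrom, unique(windows$chrom)), windows$start)
  w <- windows[o, , drop = FALSE]; stat <- stat[o]
  n <- nrow(w)
  new_grp <- c(TRUE, w$chrom[-1] != w$chrom[-n] |
                 w$start[-1] - w$end[-n] > max_gap)
  grp <- cumsum(new_grp)
  out <- data.frame(
    chrom = tapply(w$chrom, grp, `[`, 1),
    start = as.integer(tapply(w$start, grp, min)),
    end = as.integer(tapply(w$end, grp, max)),
    n_windows = as.integer(tapply(w$start, grp, length)),
    peak_stat = as.numeric(tapply(stat, grp, function(x)
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))),
    method = method, subpop = subpop,
    stringsAsFactors = FALSE, row.names = NULL)
  num <- suppressWarnings(as.numeric(as.character(out$chrom)))
  out <- out[order(is.na(num), num, as.character(out$chrom), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("roi", "data.frame")
  out
}

#' @export
print.roi <- function(x, ...) {
  cat("roi:", nrow(x), "regions\n")
  print(as.data.frame(x))
  invisible(x)
}

#' Window-by-subpopulation sharing matrix
#'
#' Given per-subpopulation significant window sets on a common grid, builds
#' the boolean membership matrix over the union of windows, the per-window
#' multiplicity (number of subpopulations sharing it), a multiplicity
#' histogram, and all pairwise intersection counts.
#'
#' @param sig_sets named list of data.frames (`chrom`, `start`, `end`), one
#'   per subpopulation, as from [significant_windows()].
#' @return list with `membership` (data.frame: window coordinates, one
#'   logical column per subpopulation, `multiplicity`), `shared` (rows with
#'   multiplicity >= 2), `histogram` (table of multiplicities among shared
#'   windows), `pairwise` (symmetric count matrix).
#' @export
sharing_matrix <- function(sig_sets) {
  pops <- names(sig_sets)
  stopifnot(!is.null(pops), all(nzchar(pops)))
  keys <- lapply(sig_sets, function(d) paste(d$chrom, d$start))
  all_w <- unique(do.call(rbind, lapply(sig_sets, function(d)
    d[, c("chrom", "start", "end")])))
  o <- order(match(all_w$chrom, unique(all_w$chrom)), all_w$start)
  all_w <- all_w[o, , drop = FALSE]
  rownames(all_w) <- NULL
  akey <- paste(all_w$chrom, all_w$start)
  mem <- sapply(pops, function(p) akey %in% keys[[p]])
  if (is.null(dim(mem))) mem <- matrix(mem, nrow = 1, dimnames = list(NULL, pops))
  mult <- rowSums(mem)
  membership <- cbind(all_w, as.data.frame(mem), multiplicity = mult)
  pairwise <- crossprod(mem)
  hist <- table(mult[mult >= 2])
  list(membership = membership,
       shared = membership[mult >= 2, , drop = FALSE],
       histogram = hist, pairwise = pairwise)
}

#' Overlap of one ROI list with another
#'
#' Interval intersection (>= 1 bp, same coordinate convention); reports how
#' many and what fraction of `a`'s regions are overlapped by at least one
#' region of `b`.
#'
#' @param a,b data.frames with `chrom`, `start`, `end` (1-based closed).
#' @return list with `overlapped` (logical per row of `a`), `count`,
#'   `fraction`.
#' @export
method_overlap <- function(a, b) {
  n <- nrow(a)
  if (n == 0) return(list(overlapped = logical(0), count = 0L,
                          fraction = NA_real_))
  hit <- logical(n)
  if (nrow(b) > 0) {
    ga <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start, a$end))
    gb <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start, b$end))
    # disjoint chromosome sets legitimately yield no overlap
    hit <- suppressWarnings(GenomicRanges::countOverlaps(ga, gb) > 0)
  }
  list(overlapped = hit, count = sum(hit), fraction = mean(hit))
}

#' Read gene annotation from BED or GFF3
#'
#' BED input (0-based half-open) is validated line by line (field count and
#' numeric coordinates, reporting the offending line number) and converted
#' to 1-based closed coordinates; GFF3 is read with rtracklayer and
#' restricted to `gene` features when present. Gene names come from the BED
#' name column or the GFF3 `Name`/`ID`/`gene_id` attribute.
#'
#' @param path annotation file path (`.bed`, `.gff`, `.gff3`).
#' @return data.frame with `chrom`, `start`, `end` (1-based closed), `gene`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    body <- which(!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines)))
    for (i in body) {
      f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      if (length(f) < 3)
        stop("malformed BED line ", i, ": fewer than 3 fields")
      if (is.na(suppressWarnings(as.numeric(f[2]))) ||
          is.na(suppressWarnings(as.numeric(f[3]))))
        stop("malformed BED line ", i, ": non-numeric coordinates")
    }
    gr <- rtracklayer::import(path, format = "BED")
    nm <- if (!is.null(gr$name)) gr$name else paste0("feature", seq_along(gr))
  } else if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- tryCatch(rtracklayer::import(path, format = "GFF3"),
                   error = function(e) stop("malformed GFF3 (", path, "): ",
                                            conditionMessage(e)))
    if ("type" %in% names(S4Vectors::mcols(gr)) && any(gr$type == "gene"))
      gr <- gr[gr$type == "gene"]
    nm <- gr$Name
    if (is.null(nm)) nm <- gr$ID
    if (is.null(nm)) nm <- gr$gene_id
    if (is.null(nm)) nm <- paste0("feature", seq_along(gr))
    nm[is.na(nm)] <- paste0("feature", which(is.na(nm)))
  } else stop("unrecognized annotation format (want .bed or .gff3): ", path)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             gene = as.character(nm), stringsAsFactors = FALSE)
}

#' Annotate regions of interest with genes
#'
#' Assigns a gene to an ROI when their intervals overlap by at least 1 bp
#' (both in 1-based closed convention; BED input is normalized on read).
#' Reports per-subpopulation distinct-gene counts: a gene hit by two ROI of
#' one subpopulation counts once for that subpopulation.
#'
#' @param rois an `roi` data.frame (or any with `chrom`, `start`, `end`,
#'   optionally `subpop`).
#' @param annotation path to a BED/GFF3 file, or a data.frame as returned by
#'   [read_gene_annotation()].
#' @return list with `rois` (input plus `genes` comma-separated string and
#'   `n_genes`), `genes_per_subpop` (named integer vector of distinct gene
#'   counts), `n_genes_total` (distinct genes over all ROI).
#' @export
annotate_genes <- function(rois, annotation) {
  genes <- if (is.character(annotation)) read_gene_annotation(annotation)
  else as.data.frame(annotation)
  stopifnot(all(c("chrom", "start", "end", "gene") %in% names(genes)))
  n <- nrow(rois)
  glist <- vector("list", n)
  if (n > 0 && nrow(genes) > 0) {
    gr_r <- GenomicRanges::GRanges(rois$chrom,
                                   IRanges::IRanges(rois$start, rois$end))
    gr_g <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$start, genes$end))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_r, gr_g))
    for (i in seq_len(n)) {
      g <- genes$gene[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]]
      glist[[i]] <- unique(g)
    }
  }
  out <- as.data.frame(rois)
  out$genes <- vapply(glist, paste, "", collapse = ",")
  out$n_genes <- vapply(glist, length, 0L)
  subp <- if ("subpop" %in% names(out)) out$subpop else rep("all", n)
  per_pop <- vapply(split(glist, subp),
                    function(l) length(unique(unlist(l))), 0L)
  list(rois = out, genes_per_subpop = per_pop,
       n_genes_total = length(unique(unlist(glist))))
}

#' Write regions as BED (0-based half-open)
#' @param x data.frame with `chrom`, `start`, `end` (1-based closed).
#' @param path output path.
#' @param names optional feature names.
#' @return Invisibly, the path.
#' @export
write_bed <- function(x, path, names = NULL) {
  if (is.null(names))
    names <- paste0(x$chrom, ":", x$start, "-", x$end)
  bed <- data.frame(x$chrom, x$start - 1L, x$end, names)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# coordinates: BED 0-based half-open", con)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
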