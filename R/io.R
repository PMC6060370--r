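#' Read a PLINK PED/MAP pair into a genotype panel
#'
#' The PED family id column is taken as the subpopulation label. Allele pairs
#' `"0 0"` are missing. Alleles are recoded to dosages with the first-seen
#' allele at each marker as the reference; dosage counts the other
#' (alternate) allele. The writer ([write_plink()]) emits heterozygotes
#' reference-allele first, so a write/read round trip preserves dosages at
#' every marker whose first called genotype carries the reference allele;
#' a marker whose first called genotype is homozygous-alternate reads back
#' with flipped orientation (`2 - dosage`), because PED carries no REF/ALT
#' declaration. The genotype configuration (including missingness) is
#' always preserved; use VCF for orientation-exact round trips.
#'
#' @param ped_path,map_path file paths.
#' @return A [genotype_panel()].
#' @export
read_plink <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE,
                           col.names = c("chrom", "marker_id", "cm", "pos"),
                           stringsAsFactors = FALSE)
  n_mark <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * n_mark
  for (i in seq_along(toks)) {
    if (length(toks[[i]]) != want)
      stop("PED parse error at line ", i, ": expected ", want,
           " fields (6 + 2 alleles x ", n_mark, " markers), found ",
           length(toks[[i]]))
  }
  n_samp <- length(toks)
  samples <- data.frame(
    sample_id = vapply(toks, `[`, "", 2L),
    subpop = vapply(toks, `[`, "", 1L), stringsAsFactors = FALSE)
  a1 <- matrix("", n_samp, n_mark); a2 <- matrix("", n_samp, n_mark)
  for (i in seq_len(n_samp)) {
    gt <- toks[[i]][-(1:6)]
    a1[i, ] <- gt[seq(1, 2 * n_mark, 2)]
    a2[i, ] <- gt[seq(2, 2 * n_mark, 2)]
  }
  dos <- matrix(NA_integer_, n_samp, n_mark)
  for (m in seq_len(n_mark)) {
    x1 <- a1[, m]; x2 <- a2[, m]
    miss <- x1 == "0" | x2 == "0"
    seen <- c(rbind(x1, x2))            # sample-major order
    seen <- seen[seen != "0"]
    if (!length(seen)) next             # all missing
    ref <- seen[1]
    alleles <- unique(seen)
    if (length(alleles) > 2)
      stop("marker ", map$marker_id[m], " has >2 alleles: ",
           paste(alleles, collapse = "/"))
    dos[, m] <- (x1 != ref) + (x2 != ref)
    dos[miss, m] <- NA_integer_
  }
  genotype_panel(dos, samples,
                 data.frame(marker_id = map$marker_id, chrom = map$chrom,
                            pos = map$pos, stringsAsFactors = FALSE))
}

#' Write a genotype panel as PLINK PED/MAP
#'
#' Dosage 0/1/2 is encoded with alleles `A` (reference) and `B` (alternate);
#' missing genotypes as `"0 0"`. Heterozygotes are written `A B` so the
#' first-seen-allele recoding of [read_plink()] restores the orientation.
#' The family id column carries the subpopulation label.
#'
#' @param g a [genotype_panel()].
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return Invisibly, the two paths.
#' @export
write_plink <- function(g, prefix) {
  if (ncol(g$dosage) == 0 || nrow(g$dosage) == 0) stop("empty panel")
  map <- data.frame(g$markers$chrom, g$markers$marker_id, 0,
                    g$markers$pos)
  map_path <- paste0(prefix, ".map"); ped_path <- paste0(prefix, ".ped")
  utils::write.table(map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  code <- c(`0` = "A A", `1` = "A B", `2` = "B B")
  con <- file(ped_path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(g$dosage))) {
    d <- g$dosage[i, ]
    gt <- ifelse(is.na(d), "0 0", code[as.character(d)])
    writeLines(paste(c(g$samples$subpop[i], g$samples$sample_id[i],
                       "0", "0", "0", "-9", gt), collapse = " "), con)
  }
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a VCF into a genotype panel
#'
#' Requires a GT field; biallelic sites only (multiallelic records are
#' rejected). Phased and unphased genotypes are both accepted; phase is
#' discarded. `./.` is missing. Subpopulation labels are taken from a
#' `<path>.pops.tsv` sidecar (columns `sample_id`, `subpop`) when present,
#' from `subpop_map` when given, else all samples are labelled `"all"`.
#'
#' @param path VCF path.
#' @param subpop_map optional named character vector `sample_id -> subpop`.
#' @return A [genotype_panel()].
#' @export
read_vcf <- function(path, subpop_map = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (any(grepl(",", fix[, "ALT"])))
    stop("multiallelic site(s) found; this scan is biallelic-only")
  fmt <- v@gt[, 1]
  if (!all(vapply(strsplit(fmt, ":"), function(x) "GT" %in% x, TRUE)))
    stop("VCF records without a GT field")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("\\|", "/", gt)
  dos <- matrix(NA_integer_, ncol(gt), nrow(gt))
  parse1 <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  vals <- parse1[gt]
  bad <- !is.na(gt) & gt != "./." & is.na(vals)
  if (any(bad)) stop("unparseable GT value(s): ",
                     paste(unique(gt[bad]), collapse = ", "))
  dos[] <- t(matrix(vals, nrow(gt), ncol(gt)))
  ids <- colnames(gt)
  sidecar <- paste0(path, ".pops.tsv")
  if (is.null(subpop_map) && file.exists(sidecar)) {
    sc <- utils::read.table(sidecar, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    subpop_map <- stats::setNames(sc$subpop, sc$sample_id)
  }
  subs <- if (is.null(subpop_map)) rep("all", length(ids)) else
    unname(subpop_map[ids])
  if (anyNA(subs)) stop("subpop_map missing labels for some samples")
  genotype_panel(dos,
                 data.frame(sample_id = ids, subpop = subs,
                            stringsAsFactors = FALSE),
                 data.frame(marker_id = ifelse(fix[, "ID"] == "." | is.na(fix[, "ID"]),
                                               paste0(fix[, "CHROM"], ":", fix[, "POS"]),
                                               fix[, "ID"]),
                            chrom = fix[, "CHROM"],
                            pos = as.integer(fix[, "POS"]),
                            stringsAsFactors = FALSE))
}

#' Write a genotype panel as VCF v4.2 (plus subpopulation sidecar)
#'
#' Genotypes are emitted unphased (`0/0`, `0/1`, `1/1`, `./.`) with
#' placeholder REF/ALT alleles `A`/`B`. Subpopulation labels go to a
#' `<path>.pops.tsv` sidecar that [read_vcf()] picks up automatically.
#'
#' @param g a [genotype_panel()].
#' @param path output VCF path.
#' @return Invisibly, the VCF path.
#' @export
write_vcf <- function(g, path) {
  if (ncol(g$dosage) == 0 || nrow(g$dosage) == 0) stop("empty panel")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=sweepscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$samples$sample_id), collapse = "\t")),
             con)
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (m in seq_len(ncol(g$dosage))) {
    d <- g$dosage[, m]
    gt <- ifelse(is.na(d), "./.", code[as.character(d)])
    writeLines(paste(c(g$markers$chrom[m], g$markers$pos[m],
                       g$markers$marker_id[m], "A", "B", ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  utils::write.table(g$samples, paste0(path, ".pops.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype panel in PED/MAP or VCF form
#'
#' @param g a [genotype_panel()].
#' @param prefix output prefix (PED/MAP) or path (VCF; `.vcf` appended if
#'   absent).
#' @param format `"ped_map"` or `"vcf"`.
#' @return Invisibly, the written path(s).
#' @export
write_panel <- function(g, prefix, format = c("ped_map", "vcf")) {
  format <- match.arg(format)
  if (format == "ped_map") write_plink(g, prefix)
  else write_vcf(g, if (grepl("\\.vcf$", prefix)) prefix else paste0(prefix, ".vcf"))
}

is_autosome <- function(chrom) {
  suppressWarnings(!is.na(as.numeric(as.character(chrom))))
}

#' Marker quality control
#'
#' Removes, in this fixed order of attribution: non-autosomal markers, then
#' markers with genotyping call rate below `min_call_rate`, then markers with
#' pooled minor allele frequency (across all individuals) below `min_maf`.
#' Removal is strict `<`, so markers exactly at a threshold are retained.
#'
#' @param g a [genotype_panel()].
#' @param min_call_rate minimum call rate (default 0.95).
#' @param min_maf minimum pooled MAF (default 0.05).
#' @param autosomes_only drop markers whose chromosome is not numeric.
#' @return list with `panel` (filtered [genotype_panel()]) and `report`
#'   (class `qc_report`).
#' @export
apply_qc <- function(g, min_call_rate = 0.95, min_maf = 0.05,
                     autosomes_only = TRUE) {
  n_input <- ncol(g$dosage)
  if (n_input == 0) stop("empty panel")
  keep <- rep(TRUE, n_input)
  fail_auto <- if (autosomes_only) !is_autosome(g$markers$chrom) else
    rep(FALSE, n_input)
  call_rate <- colMeans(!is.na(g$dosage))
  fail_cr <- call_rate < min_call_rate & !fail_auto
  maf <- panel_maf(g)
  fail_maf <- (is.na(maf) | maf < min_maf) & !fail_auto & !fail_cr
  keep <- !(fail_auto | fail_cr | fail_maf)
  if (!any(keep)) stop("QC removed every marker; empty panel")
  report <- structure(list(n_input = n_input,
                           n_removed_nonautosomal = sum(fail_auto),
                           n_removed_call_rate = sum(fail_cr),
                           n_removed_maf = sum(fail_maf),
                           n_retained = sum(keep),
                           min_call_rate = min_call_rate,
                           min_maf = min_maf),
                      class = "qc_report")
  list(panel = subset_panel(g, markers = keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Marker QC (call rate >=", x$min_call_rate, ", pooled MAF >=",
      x$min_maf, "):\n")
  cat("  input markers:      ", x$n_input, "\n")
  cat("  removed non-autosomal:", x$n_removed_nonautosomal, "\n")
  cat("  removed call rate:  ", x$n_removed_call_rate, "\n")
  cat("  removed MAF:        ", x$n_removed_maf, "\n")
  cat("  retained:           ", x$n_retained, "\n")
  invisible(x)
}

#' Write a QC report as TSV
#' @param report a `qc_report`.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(field = c("n_input", "n_removed_nonautosomal",
                             "n_removed_call_rate", "n_removed_maf",
                             "n_retained"),
                   value = c(report$n_input, report$n_removed_nonautosomal,
                             report$n_removed_call_rate, report$n_removed_maf,
                             report$n_retained))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
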