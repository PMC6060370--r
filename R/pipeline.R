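#' Configuration for an end-to-end selection-signature run
#'
#' Exactly one of `sim` (a [sim_config()]) or input paths (`ped`/`map` or
#' `vcf`) must be supplied.
#'
#' @param sim a [sim_config()] for a simulated run.
#' @param ped,map PLINK input paths.
#' @param vcf VCF input path.
#' @param annotation optional BED/GFF3 gene annotation path.
#' @param min_call_rate,min_maf marker QC thresholds.
#' @param window_size d_i window size in bp.
#' @param top_fraction d_i empirical significance fraction.
#' @param merge_gap ROI merge gap in bp.
#' @param K haplotype clusters for the LD model.
#' @param n_fits EM restarts averaged by hapFLK/LHS.
#' @param em_max_iter maximum EM iterations per fit.
#' @param flk_threshold `-log10(p)` threshold for FLK/hapFLK.
#' @param lhs_threshold `-log10` tail threshold for the sharing scan.
#' @param seed integer seed for the stochastic stages.
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(sim = NULL, ped = NULL, map = NULL, vcf = NULL,
                        annotation = NULL, min_call_rate = 0.95,
                        min_maf = 0.05, window_size = 10000,
                        top_fraction = 0.001, merge_gap = 500000,
                        K = 10, n_fits = 5, em_max_iter = 100,
                        flk_threshold = 4, lhs_threshold = 5, seed = 1L,
                        out_dir = NULL) {
  has_sim <- !is.null(sim)
  has_files <- !is.null(vcf) || (!is.null(ped) && !is.null(map))
  if (has_sim == has_files)
    stop("supply exactly one input: a sim_config, or ped+map / vcf paths")
  if (has_sim && !inherits(sim, "sim_config")) stop("sim must be a sim_config")
  for (p in c(ped, map, vcf, annotation)) {
    if (!is.null(p) && !file.exists(p)) stop("input path not found: ", p)
  }
  for (v in c(min_call_rate, min_maf, top_fraction, merge_gap, K, n_fits,
              flk_threshold, lhs_threshold, window_size)) {
    if (!is.numeric(v) || v <= 0) stop("all thresholds must be positive")
  }
  structure(list(sim = sim, ped = ped, map = map, vcf = vcf,
                 annotation = annotation, min_call_rate = min_call_rate,
                 min_maf = min_maf, window_size = window_size,
                 top_fraction = top_fraction, merge_gap = merge_gap,
                 K = K, n_fits = n_fits, em_max_iter = em_max_iter,
                 flk_threshold = flk_threshold,
                 lhs_threshold = lhs_threshold, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "scan_config")
}

stage_msg <- function(verbose, ...) if (verbose) message("[sweepscan] ", ...)

#' Run the full selection-signature pipeline
#'
#' Stages, in order: simulate or load genotypes; marker QC; windowed F_ST
#' and d_i with empirical thresholding; Reynolds-distance kinship and the
#' FLK scan; haplotype-cluster model fit; hapFLK scan; per-subpopulation
#' local-haplotype-sharing scan with orphan removal; merging of significant
#' windows/runs into ROI; cross-method overlap and subpopulation sharing;
#' optional gene annotation; recovery metrics against simulation truth.
#' Each stage's outputs are written to `out_dir` (when set) together with
#' the configuration and seed.
#'
#' @param config a [scan_config()].
#' @param verbose print stage progress (default TRUE).
#' @return An object of class `scan_report`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "scan_config"))
  t0 <- Sys.time()
  truth <- NULL
  if (!is.null(config$sim)) {
    stage_msg(verbose, "simulate: ", config$sim$n_subpops, " subpops x ",
              config$sim$samples_per_subpop, " samples, ",
              config$sim$n_chromosomes * config$sim$n_snps_per_chrom, " SNPs")
    simres <- simulate_panel(config$sim)
    panel <- simres$panel; truth <- simres$truth
  } else if (!is.null(config$vcf)) {
    stage_msg(verbose, "load VCF: ", config$vcf)
    panel <- read_vcf(config$vcf)
  } else {
    stage_msg(verbose, "load PED/MAP: ", config$ped)
    panel <- read_plink(config$ped, config$map)
  }

  qc <- apply_qc(panel, config$min_call_rate, config$min_maf)
  stage_msg(verbose, "QC: ", qc$report$n_retained, "/", qc$report$n_input,
            " markers retained")
  g <- qc$panel
  pops <- subpops(g)

  fst <- window_fst(g, window_size = config$window_size)
  di <- compute_di(fst)
  sig <- suppressWarnings(significant_windows(di, config$top_fraction))
  stage_msg(verbose, "d_i: ", nrow(di$windows), " analyzed windows, top ",
            nrow(sig[[1]]), " per subpopulation")
  di_roi <- do.call(rbind, lapply(pops, function(p)
    merge_windows(sig[[p]], config$merge_gap, method = "di", subpop = p,
                  stat_col = "di")))

  kin <- kinship_from_tree(reynolds_dist_matrix(g))
  flk <- flk_scan(g, kin, config$flk_threshold)
  stage_msg(verbose, "FLK: ", sum(flk$significant, na.rm = TRUE),
            " significant SNPs")

  stage_msg(verbose, "cluster model: K = ", config$K, ", ", config$n_fits,
            " EM fits")
  model <- fit_cluster_model(g, K = config$K, n_fits = config$n_fits,
                             seed = config$seed,
                             max_iter = config$em_max_iter)
  hfl <- hapflk_scan(model, g, kin, config$flk_threshold)
  hfl_sig <- hfl[hfl$significant, c("chrom", "pos"), drop = FALSE]
  hapflk_roi <- merge_windows(
    data.frame(chrom = hfl_sig$chrom, start = hfl_sig$pos,
               end = hfl_sig$pos, stringsAsFactors = FALSE),
    config$merge_gap, method = "hapflk", subpop = "all")
  stage_msg(verbose, "hapFLK: ", nrow(hapflk_roi), " ROI")

  lhs <- list(); lhs_roi_list <- list()
  for (p in pops) {
    track <- lhs_score(model, g, p)
    sigl <- lhs_significant(track, config$lhs_threshold)
    lhs[[p]] <- sigl
    if (nrow(sigl$clusters)) {
      lhs_roi_list[[p]] <- merge_windows(sigl$clusters, config$merge_gap,
                                         method = "lhs", subpop = p,
                                         stat_col = "peak")
    }
  }
  lhs_roi <- if (length(lhs_roi_list)) do.call(rbind, lhs_roi_list) else
    merge_windows(NULL)
  stage_msg(verbose, "LHS: ", nrow(lhs_roi), " ROI across subpopulations")

  share <- sharing_matrix(sig)
  overlap_di_lhs <- lapply(pops, function(p) {
    a <- di_roi[di_roi$subpop == p, , drop = FALSE]
    b <- lhs_roi[lhs_roi$subpop == p, , drop = FALSE]
    method_overlap(a, b)
  })
  names(overlap_di_lhs) <- pops
  overlap_hapflk_di <- method_overlap(hapflk_roi, di_roi)

  annotated <- NULL
  if (!is.null(config$annotation)) {
    all_roi <- rbind(di_roi, hapflk_roi, lhs_roi)
    annotated <- annotate_genes(all_roi, config$annotation)
    stage_msg(verbose, "annotation: ", annotated$n_genes_total,
              " distinct genes in ROI")
  }

  recovery <- NULL
  if (!is.null(truth) && nrow(truth) > 0) {
    recovery <- evaluate_recovery(di_roi, truth)
    stage_msg(verbose, sprintf("recovery (d_i): recall %.2f, precision %s",
                               recovery$recall,
                               format(recovery$precision, digits = 2)))
  }

  report <- structure(list(
    config = config, qc = qc$report, n_windows = nrow(di$windows),
    di = di, significant = sig, di_roi = di_roi,
    kinship = kin, flk = flk, model = model, hapflk = hfl,
    hapflk_roi = hapflk_roi, lhs = lhs, lhs_roi = lhs_roi,
    sharing = share, overlap_di_lhs = overlap_di_lhs,
    overlap_hapflk_di = overlap_hapflk_di, annotated = annotated,
    truth = truth, recovery = recovery,
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    version = as.character(utils::packageVersion("sweepscan"))),
    class = "scan_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.scan_report <- function(x, ...) {
  cat("sweepscan report (package", x$version, ")\n")
  cat("seed:", x$config$seed, "| elapsed:", round(x$elapsed, 1), "s\n")
  print(x$qc)
  cat("analyzed windows:", x$n_windows, "\n")
  cat("d_i ROI per subpopulation:\n")
  print(table(x$di_roi$subpop))
  cat("hapFLK ROI:", nrow(x$hapflk_roi), "\n")
  cat("LHS ROI:", nrow(x$lhs_roi), "\n")
  cat("windows shared by >= 2 subpopulations:", nrow(x$sharing$shared), "\n")
  if (!is.null(x$recovery))
    cat(sprintf("sweep recovery: recall %.2f, precision %s of %d truth interval(s)\n",
                x$recovery$recall, format(x$recovery$precision, digits = 2),
                x$recovery$n_truth))
  invisible(x)
}

#' Write a scan report bundle to a directory
#'
#' Emits per-stage TSV/BED files, the kinship tree as Newick, a plain-text
#' summary and a configuration dump (parameters and seed, reproducing the
#' run verbatim).
#'
#' @param report a `scan_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(name) file.path(dir, name)
  write_qc_report(report$qc, fp("qc_report.tsv"))
  write_di_table(report$di, fp("di_windows.tsv"),
                 report$config$top_fraction)
  for (p in names(report$significant))
    write_bed(report$significant[[p]], fp(paste0("di_significant_", p, ".bed")))
  utils::write.table(as.data.frame(report$di_roi), fp("di_roi.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(round(unclass(report$kinship)[,], 6),
                     fp("kinship_matrix.tsv"), sep = "\t", quote = FALSE)
  write_kinship_tree(report$kinship, fp("kinship_tree.nwk"))
  write_scan_table(report$flk, fp("flk_snps.tsv"))
  write_scan_table(report$hapflk, fp("hapflk_snps.tsv"))
  utils::write.table(as.data.frame(report$hapflk_roi), fp("hapflk_roi.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (p in names(report$lhs))
    utils::write.table(report$lhs[[p]]$flags, fp(paste0("lhs_", p, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(report$lhs_roi), fp("lhs_roi.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$sharing$membership, fp("sharing_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- report$config
  cfg_lines <- c(
    paste0("sweepscan version: ", report$version),
    paste0("seed: ", cfg$seed),
    paste0("window_size: ", cfg$window_size),
    paste0("top_fraction: ", cfg$top_fraction),
    paste0("merge_gap: ", cfg$merge_gap),
    paste0("K: ", cfg$K), paste0("n_fits: ", cfg$n_fits),
    paste0("flk_threshold: ", cfg$flk_threshold),
    paste0("lhs_threshold: ", cfg$lhs_threshold),
    paste0("min_call_rate: ", cfg$min_call_rate),
    paste0("min_maf: ", cfg$min_maf))
  writeLines(cfg_lines, fp("config.txt"))
  summary_path <- fp("summary.txt")
  con <- file(summary_path, "w")
  sink(con); print(report); sink()
  close(con)
  invisible(dir)
}
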