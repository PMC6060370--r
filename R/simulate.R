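#' Simulation configuration for structured populations with sweeps
#'
#' Describes a hierarchically structured set of subpopulations under the
#' Balding-Nichols drift model, with linkage disequilibrium generated by
#' founder-haplotype mosaics and optional localized selective sweeps.
#'
#' Drift: each branch of a two-level hierarchy (ancestral population ->
#' groups -> subpopulations) draws allele frequencies from the
#' Balding-Nichols beta distribution with parameters `p(1-F)/F` and
#' `(1-p)(1-F)/F`, where `p` is the parent frequency and `F = drift_f`.
#' With a single group the group level is skipped, so each subpopulation sits
#' at drift `F` from the common ancestor and the expected pairwise
#' Weir-Cockerham F_ST between subpopulations is approximately `drift_f`.
#'
#' @param n_subpops number of subpopulations.
#' @param samples_per_subpop diploid individuals per subpopulation.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_snps_per_chrom SNPs per chromosome (positions drawn uniformly
#'   without replacement, then sorted; 1-based).
#' @param drift_f per-branch drift parameter, strictly inside (0, 1).
#' @param tree two-level hierarchy: list of character vectors partitioning the
#'   subpopulation labels into groups, or `NULL` for a single group (star).
#' @param n_founder_haplotypes founder haplotypes per subpopulation (>= 2).
#' @param copying_switch_rate per-bp probability intensity of switching
#'   founder templates between adjacent SNPs (mosaic LD scale).
#' @param missing_rate fraction of genotypes set missing, in `[0, 1)`.
#' @param sweeps list of [sweep_spec()] objects.
#' @param subpop_labels labels; default `pop1..popN`.
#' @param seed integer seed; the simulation is fully reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subpops = 6, samples_per_subpop = 24,
                       n_chromosomes = 3, chrom_length = 2.5e6,
                       n_snps_per_chrom = 2000, drift_f = 0.05,
                       tree = NULL, n_founder_haplotypes = 100,
                       copying_switch_rate = 2e-5, missing_rate = 0.01,
                       sweeps = list(),
                       subpop_labels = paste0("pop", seq_len(n_subpops)),
                       seed = 1L) {
  if (!(drift_f > 0 && drift_f < 1))
    stop("drift_f must lie strictly inside (0, 1)")
  if (n_founder_haplotypes < 2) stop("n_founder_haplotypes must be >= 2")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (n_snps_per_chrom > chrom_length)
    stop("more SNPs than base pairs on a chromosome")
  if (length(subpop_labels) != n_subpops || anyDuplicated(subpop_labels))
    stop("subpop_labels must be ", n_subpops, " unique labels")
  if (is.null(tree)) tree <- list(subpop_labels)
  if (!setequal(unlist(tree), subpop_labels) ||
      length(unlist(tree)) != n_subpops)
    stop("tree must partition the subpopulation labels")
  for (s in sweeps) {
    if (!inherits(s, "sweep_spec")) stop("sweeps must be sweep_spec objects")
    if (!(s$target_subpop %in% subpop_labels))
      stop("sweep target subpopulation '", s$target_subpop, "' not in panel")
    if (!(s$chrom %in% seq_len(n_chromosomes)))
      stop("sweep chromosome ", s$chrom, " outside panel")
    if (s$end > chrom_length)
      stop("sweep interval extends past chromosome end")
  }
  structure(list(n_subpops = n_subpops,
                 samples_per_subpop = samples_per_subpop,
                 n_chromosomes = n_chromosomes, chrom_length = chrom_length,
                 n_snps_per_chrom = n_snps_per_chrom, drift_f = drift_f,
                 tree = tree, n_founder_haplotypes = n_founder_haplotypes,
                 copying_switch_rate = copying_switch_rate,
                 missing_rate = missing_rate, sweeps = sweeps,
                 subpop_labels = subpop_labels, seed = as.integer(seed)),
            class = "sim_config")
}

#' Specification of one injected selective sweep
#'
#' Inside the interval, `favored_fraction` of the target subpopulation's
#' haplotypes are forced to copy a single favored founder haplotype, which
#' raises local haplotype homozygosity and shifts local allele frequencies --
#' the two signals (frequency-based and haplotype-based) the scans target.
#'
#' @param target_subpop subpopulation label under selection.
#' @param chrom chromosome id (integer).
#' @param start,end sweep interval in bp, 1-based closed, `end > start`.
#' @param favored_fraction fraction in (0.5, 1] of haplotypes forced onto the
#'   favored founder.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(target_subpop, chrom, start, end,
                       favored_fraction = 0.9) {
  if (end <= start) stop("sweep interval must have end > start")
  if (start < 1) stop("sweep start must be >= 1")
  if (!(favored_fraction > 0.5 && favored_fraction <= 1))
    stop("favored_fraction must lie in (0.5, 1]")
  structure(list(target_subpop = target_subpop, chrom = as.integer(chrom),
                 start = as.integer(start), end = as.integer(end),
                 favored_fraction = favored_fraction),
            class = "sweep_spec")
}

# Balding-Nichols draw: beta around parent frequency p with drift F
rbn <- function(p, f) {
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate a structured genotype panel with known sweeps
#'
#' Ancestral allele frequencies are uniform on `[0.05, 0.95]`; group and
#' subpopulation frequencies follow Balding-Nichols drift down the two-level
#' hierarchy of the configuration. Each subpopulation receives a pool of
#' founder haplotypes whose allele counts match the subpopulation frequency
#' (stochastic rounding), and each sampled haplotype is a mosaic of founders
#' with per-bp switch intensity `copying_switch_rate`. Within each sweep
#' interval, the specified fraction of the target subpopulation's haplotypes
#' copy the favored founder. Genotypes are haplotype sums with uniform random
#' missingness.
#'
#' @param config a [sim_config()].
#' @param keep_haplotypes store the underlying haplotype matrix as attribute
#'   `haplotypes` (2 rows per individual) for validation work.
#' @return A list with components `panel` (a [genotype_panel()], carrying the
#'   per-SNP ancestral frequencies as attribute `ancestral_freq`) and `truth`
#'   (class `sweep_truth`: data.frame of injected sweeps with realized
#'   favored-founder allele frequencies per subpopulation).
#' @export
simulate_panel <- function(config, keep_haplotypes = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  labs <- config$subpop_labels
  npop <- config$n_subpops
  nind <- config$samples_per_subpop
  K <- config$n_founder_haplotypes
  M <- config$n_snps_per_chrom
  f <- config$drift_f

  chrom_ids <- integer(0); positions <- integer(0)
  hap_list <- vector("list", config$n_chromosomes)
  anc_list <- vector("list", config$n_chromosomes)
  truth_rows <- list()

  # per-subpop haplotypes: 2*nind rows each, stacked in label order
  for (ch in seq_len(config$n_chromosomes)) {
    pos <- sort(sample.int(config$chrom_length, M))
    chrom_ids <- c(chrom_ids, rep.int(ch, M))
    positions <- c(positions, pos)

    p_anc <- stats::runif(M, 0.05, 0.95)
    anc_list[[ch]] <- p_anc
    haps <- matrix(0L, 2L * nind * npop, M)
    founder_pools <- vector("list", npop)
    paths <- vector("list", npop)

    two_level <- length(config$tree) > 1
    p_group <- lapply(config$tree, function(g) if (two_level) rbn(p_anc, f) else p_anc)
    names(p_group) <- vapply(config$tree, function(g) paste(g, collapse = "+"), "")

    for (ip in seq_len(npop)) {
      grp <- which(vapply(config$tree, function(g) labs[ip] %in% g, TRUE))
      p_sub <- rbn(p_group[[grp]], f)
      # founder pool with allele counts stochastically rounded to K*p_sub,
      # so the pool mean is unbiased for p_sub and adds no extra drift
      cnt <- floor(K * p_sub) + stats::rbinom(M, 1L, K * p_sub - floor(K * p_sub))
      u <- matrix(stats::runif(K * M), K, M)
      rk <- apply(u, 2, rank, ties.method = "first")
      H <- matrix(as.integer(rk <= rep(cnt, each = K)), K, M)
      founder_pools[[ip]] <- H

      nh <- 2L * nind
      # mosaic founder paths
      d <- diff(pos)
      psw <- 1 - exp(-config$copying_switch_rate * d)
      path <- matrix(0L, nh, M)
      path[, 1] <- sample.int(K, nh, replace = TRUE)
      prop <- matrix(sample.int(K, nh * (M - 1), replace = TRUE), nh, M - 1)
      sw <- matrix(stats::rbinom(nh * (M - 1), 1L, rep(psw, each = nh)) == 1L,
                   nh, M - 1)
      for (m in 2:M) {
        path[, m] <- ifelse(sw[, m - 1], prop[, m - 1], path[, m - 1])
      }
      paths[[ip]] <- path
    }

    # sweeps: force favored fraction of target haplotypes onto founder 1
    for (si in seq_along(config$sweeps)) {
      s <- config$sweeps[[si]]
      if (s$chrom != ch) next
      ip <- match(s$target_subpop, labs)
      in_iv <- which(pos >= s$start & pos <= s$end)
      if (!length(in_iv)) next
      nh <- 2L * nind
      n_fav <- round(s$favored_fraction * nh)
      fav <- sample.int(nh, n_fav)
      paths[[ip]][fav, in_iv] <- 1L
    }

    for (ip in seq_len(npop)) {
      nh <- 2L * nind
      rows <- (ip - 1L) * nh + seq_len(nh)
      H <- founder_pools[[ip]]
      idx <- cbind(as.vector(paths[[ip]]), rep(seq_len(M), each = nh))
      haps[rows, ] <- matrix(H[idx], nh, M)
    }
    hap_list[[ch]] <- haps

    # realized favored-founder allele frequency inside each sweep, per subpop
    for (si in seq_along(config$sweeps)) {
      s <- config$sweeps[[si]]
      if (s$chrom != ch) next
      in_iv <- which(pos >= s$start & pos <= s$end)
      ip_t <- match(s$target_subpop, labs)
      fav_alleles <- founder_pools[[ip_t]][1L, in_iv]
      freqs <- vapply(seq_len(npop), function(ip) {
        nh <- 2L * nind
        rows <- (ip - 1L) * nh + seq_len(nh)
        if (!length(in_iv)) return(NA_real_)
        hh <- haps[rows, in_iv, drop = FALSE]
        mean(t(hh) == fav_alleles)
      }, 0)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        sweep = si, target_subpop = s$target_subpop, chrom = s$chrom,
        start = s$start, end = s$end, favored_fraction = s$favored_fraction,
        subpop = labs, core_allele_freq = freqs, stringsAsFactors = FALSE)
    }
  }

  haps_all <- do.call(cbind, hap_list)
  n_total <- nind * npop
  geno <- haps_all[seq(1, 2 * n_total, by = 2), , drop = FALSE] +
    haps_all[seq(2, 2 * n_total, by = 2), , drop = FALSE]
  storage.mode(geno) <- "integer"
  if (config$missing_rate > 0) {
    nmiss <- stats::rbinom(1, length(geno), config$missing_rate)
    geno[sample.int(length(geno), nmiss)] <- NA_integer_
  }

  samples <- data.frame(
    sample_id = paste0(rep(labs, each = nind), "_", rep(seq_len(nind), npop)),
    subpop = rep(labs, each = nind), stringsAsFactors = FALSE)
  markers <- data.frame(
    marker_id = paste0("snp", seq_along(positions)),
    chrom = chrom_ids, pos = positions, stringsAsFactors = FALSE)
  panel <- genotype_panel(geno, samples, markers)
  attr(panel, "ancestral_freq") <- unlist(anc_list)
  if (keep_haplotypes) attr(panel, "haplotypes") <- haps_all

  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(sweep = integer(), target_subpop = character(),
               chrom = integer(), start = integer(), end = integer(),
               favored_fraction = numeric(), subpop = character(),
               core_allele_freq = numeric(), stringsAsFactors = FALSE)
  class(truth) <- c("sweep_truth", "data.frame")
  list(panel = panel, truth = truth)
}

#' Unique truth intervals of a sweep_truth table
#' @param truth a `sweep_truth` as returned by [simulate_panel()].
#' @return data.frame with one row per injected sweep (`target_subpop`,
#'   `chrom`, `start`, `end`).
#' @export
truth_intervals <- function(truth) {
  unique(truth[, c("sweep", "target_subpop", "chrom", "start", "end")])
}

#' Precision and recall of detected regions against sweep truth
#'
#' A truth sweep counts as recovered when at least one detected region of the
#' matching subpopulation overlaps it by >= 1 bp. A detected region counts as
#' true when it overlaps any truth interval by >= 1 bp (any subpopulation).
#'
#' @param detected data.frame of regions with columns `chrom`, `start`, `end`
#'   and optionally `subpop` (required for recall matching; regions labelled
#'   `"all"` match every subpopulation).
#' @param truth a `sweep_truth`.
#' @return list with `precision` (NA with `precision_defined = FALSE` when no
#'   regions were detected), `recall`, `n_detected`, `n_truth`.
#' @export
evaluate_recovery <- function(detected, truth) {
  tr <- truth_intervals(truth)
  n_truth <- nrow(tr)
  n_det <- if (is.null(detected)) 0L else nrow(detected)
  ov <- function(a1, a2, b1, b2) a1 <= b2 & b1 <= a2
  hit_truth <- logical(n_truth)
  hit_det <- logical(n_det)
  if (n_det > 0 && n_truth > 0) {
    det_sub <- if ("subpop" %in% names(detected)) detected$subpop else
      rep("all", n_det)
    for (i in seq_len(n_truth)) {
      m <- detected$chrom == tr$chrom[i] &
        ov(detected$start, detected$end, tr$start[i], tr$end[i])
      hit_det <- hit_det | m
      hit_truth[i] <- any(m & (det_sub == tr$target_subpop[i] | det_sub == "all"))
    }
  }
  precision_defined <- n_det > 0
  list(precision = if (precision_defined) mean(hit_det) else NA_real_,
       precision_defined = precision_defined,
       recall = if (n_truth > 0) mean(hit_truth) else NA_real_,
       n_detected = n_det, n_truth = n_truth)
}

#' Export sweep truth as BED (0-based half-open) plus a TSV sidecar
#'
#' @param truth a `sweep_truth`.
#' @param prefix file path prefix; writes `<prefix>.bed` and `<prefix>.tsv`.
#' @return Invisibly, the two file paths.
#' @export
write_truth <- function(truth, prefix) {
  tr <- truth_intervals(truth)
  bed <- data.frame(chrom = tr$chrom, start = tr$start - 1L, end = tr$end,
                    name = if (nrow(tr)) paste0("sweep", tr$sweep)
                    else character(0))
  bed_path <- paste0(prefix, ".bed")
  tsv_path <- paste0(prefix, ".tsv")
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(truth, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(bed = bed_path, tsv = tsv_path))
}
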