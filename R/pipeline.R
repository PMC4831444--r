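#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. Exactly one input source
#' must be active: either a synthetic-generator configuration or a VCF +
#' metadata path pair. Validation problems are reported as a single
#' aggregated error.
#'
#' @param generator a [generator_config()], or `NULL`.
#' @param vcf,metadata input file paths (VCF and sample-metadata TSV), or
#'   `NULL`.
#' @param out_dir output directory for the report bundle.
#' @param min_depth,min_inds,min_groups coverage-filter thresholds.
#' @param q_threshold,q_strict primary and stringent FDR thresholds for the
#'   outlier scans (the study's sensitivity axis: 0.2 vs 0.05).
#' @param scan_B null-ensemble size per calibration.
#' @param percentile_breaks F_st percentile breaks for stratification.
#' @param phi,e_min LD-network outlier parameters.
#' @param ld_max_loci cap on loci entering the LD matrix (quadratic cost).
#' @param bootstrap NJ bootstrap replicates.
#' @param plots emit PNG figures alongside the TSV data.
#' @param seed integer master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = NULL, vcf = NULL, metadata = NULL,
                            out_dir = tempfile("radscan_run_"),
                            min_depth = 10, min_inds = 15, min_groups = 2,
                            q_threshold = 0.2, q_strict = 0.05,
                            scan_B = 20000L,
                            percentile_breaks = c(60, 70, 80, 90),
                            phi = 4, e_min = 16L, ld_max_loci = 2000L,
                            bootstrap = 50L, plots = FALSE, seed = 1L) {
  problems <- character(0)
  has_gen <- !is.null(generator)
  has_vcf <- !is.null(vcf)
  if (has_gen == has_vcf) {
    problems <- c(problems, "exactly one of `generator` or `vcf` must be given")
  }
  if (has_gen && !inherits(generator, "generator_config")) {
    problems <- c(problems, "`generator` must be a generator_config")
  }
  if (has_vcf && is.null(metadata)) {
    problems <- c(problems, "`metadata` TSV is required with `vcf` input")
  }
  if (!(q_threshold > 0 && q_threshold < 1)) {
    problems <- c(problems, "`q_threshold` must lie in (0, 1)")
  }
  if (!(q_strict > 0 && q_strict < 1)) {
    problems <- c(problems, "`q_strict` must lie in (0, 1)")
  }
  if (any(diff(percentile_breaks) <= 0) ||
      any(percentile_breaks <= 0 | percentile_breaks >= 100)) {
    problems <- c(problems, "`percentile_breaks` must be increasing within (0, 100)")
  }
  if (phi <= 0) problems <- c(problems, "`phi` must be positive")
  if (e_min < 1) problems <- c(problems, "`e_min` must be >= 1")
  if (length(problems) > 0L) {
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  structure(list(generator = generator, vcf = vcf, metadata = metadata,
                 out_dir = out_dir, min_depth = min_depth,
                 min_inds = min_inds, min_groups = min_groups,
                 q_threshold = q_threshold, q_strict = q_strict,
                 scan_B = as.integer(scan_B),
                 percentile_breaks = percentile_breaks,
                 phi = phi, e_min = as.integer(e_min),
                 ld_max_loci = as.integer(ld_max_loci),
                 bootstrap = as.integer(bootstrap),
                 plots = plots, seed = as.integer(seed)),
            class = "pipeline_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full adaptation-vs-speciation analysis
#'
#' Orchestrates the study's analysis arc on one dataset: SNP filtering;
#' pairwise multilocus F_st tables along both the location ("adaptation") and
#' species ("speciation") axes; per-locus F_st histograms; percentile
#' stratification with a PCA/k-means clustering summary per bin; outlier
#' scans per species (location axis) and per location (species axis) at both
#' FDR thresholds, with repeated-outlier reports; the cross-axis sharing
#' statistic (fraction of top-percentile SNPs, and of outliers, shared
#' between the two axes); and a randomized-grouping null. All tables are
#' written as TSV under `cfg$out_dir`, with a JSON manifest recording seeds
#' and thresholds so every report row traces back to its configuration.
#' Re-running with the same configuration reproduces the bundle bit for bit.
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly) list with the in-memory results: `data`, `fst_tables`,
#'   `bins`, `cluster_by_bin`, `scans`, `reports`, `sharing`,
#'   `randomized`, `files`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(x, name) {
    p <- file.path(cfg$out_dir, name)
    write_tsv(x, p)
    files[[length(files) + 1L]] <<- p
    p
  }

  # -- input ----------------------------------------------------------------
  if (!is.null(cfg$generator)) {
    ds <- generate_dataset(cfg$generator)
    g <- ds$genotypes; cov <- ds$coverage; groups <- ds$groups
    truth <- ds$truth
  } else {
    inp <- read_vcf(cfg$vcf)
    g <- inp$genotypes; cov <- inp$coverage
    groups <- read_metadata_tsv(cfg$metadata)
    truth <- NULL
  }

  # -- filtering ------------------------------------------------------------
  g_f <- filter_loci_by_coverage(g, cov, groups, min_depth = cfg$min_depth,
                                 min_inds = cfg$min_inds,
                                 min_groups = cfg$min_groups,
                                 group_by = "location")
  g_f <- filter_rare_alleles(g_f, groups)

  # -- F_st tables, both axes ----------------------------------------------
  tab_loc <- pairwise_fst_table(g_f, groups, axis = "location")
  tab_sp <- pairwise_fst_table(g_f, groups, axis = "species")
  emit(tab_loc, "fst_pairwise_locations.tsv")
  emit(tab_sp, "fst_pairwise_species.tsv")

  f_loc <- wc_fst(g_f, group_labels(g_f, groups, "location"))
  f_sp <- wc_fst(g_f, group_labels(g_f, groups, "species"))
  emit(fst_histogram(f_loc), "fst_hist_locations.tsv")
  emit(fst_histogram(f_sp), "fst_hist_species.tsv")
  if (cfg$plots) {
    for (nm in c("locations", "species")) {
      f <- if (nm == "locations") f_loc else f_sp
      grDevices::png(file.path(cfg$out_dir, paste0("fst_hist_", nm, ".png")),
                     width = 720, height = 480)
      graphics::hist(f$loci$fst[f$loci$defined], breaks = 60,
                     main = paste("Per-locus F_st among", nm),
                     xlab = "F_st")
      grDevices::dev.off()
    }
  }

  # -- percentile stratification + clustering per bin -----------------------
  bins <- percentile_stratify(f_loc, cfg$percentile_breaks)
  bin_tab <- data.frame(bin = names(bins$bins), n_loci = as.integer(bins$counts))
  emit(bin_tab, "percentile_bins.tsv")
  g_one <- select_first_snp_per_stack(g_f)
  cluster_by_bin <- list()
  for (nm in rev(names(bins$bins))) {
    ids <- intersect(bins$bins[[nm]], locus_ids(g_one))
    if (length(ids) < 10L) next
    cl <- pca_cluster(subset_loci(g_one, ids), seed = cfg$seed)
    cluster_by_bin[[nm]] <- cl
  }
  cl_tab <- data.frame(
    bin = names(cluster_by_bin),
    k = vapply(cluster_by_bin, `[[`, integer(1L), "k"),
    best_silhouette = vapply(cluster_by_bin, function(cl) {
      s <- cl$scores[-1L]
      if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE)
    }, numeric(1L)))
  emit(cl_tab, "percentile_bin_clustering.tsv")

  # -- outlier scans on both axes ------------------------------------------
  null_cache <- new.env(parent = emptyenv())
  scans_loc <- scan_comparisons(g_f, groups, mode = "per_pair",
                                q_threshold = cfg$q_threshold, B = cfg$scan_B,
                                null_cache = null_cache, seed = cfg$seed)
  # species axis: swap the factors so "species" is contrasted within location
  groups_sw <- sample_groups(groups$sample, species = groups$location,
                             location = groups$species)
  scans_sp <- scan_comparisons(g_f, groups_sw, mode = "per_pair",
                               q_threshold = cfg$q_threshold, B = cfg$scan_B,
                               null_cache = null_cache, seed = cfg$seed)
  rep_loc <- repeated_outliers(scans_loc)
  rep_sp <- repeated_outliers(scans_sp)
  scan_tab <- function(scans, axis) {
    do.call(rbind, lapply(scans, function(s) {
      strict <- sum(s$loci$q < cfg$q_strict)
      data.frame(axis = axis, comparison = s$comparison,
                 n_loci = s$n_considered, n_outliers = s$n_outliers,
                 pct_outliers = 100 * s$n_outliers / max(1L, s$n_considered),
                 n_outliers_strict = strict,
                 stringsAsFactors = FALSE)
    }))
  }
  emit(rbind(scan_tab(scans_loc, "location"), scan_tab(scans_sp, "species")),
       "outlier_scans.tsv")
  rep_tab <- function(rep, axis) {
    data.frame(axis = axis,
               n_flagged = length(rep$repeat_count),
               n_repeated = length(rep$repeated),
               n_triple = length(rep$triple),
               shared_consideration = rep$shared_consideration_ratio)
  }
  emit(rbind(rep_tab(rep_loc, "location"), rep_tab(rep_sp, "species")),
       "repeated_outliers.tsv")

  # -- cross-axis sharing ---------------------------------------------------
  top_share <- function(fa, fb, q = 0.9) {
    ta <- fa$loci$locus_id[fa$loci$defined &
      fa$loci$fst >= stats::quantile(fa$loci$fst[fa$loci$defined], q, type = 1)]
    tb <- fb$loci$locus_id[fb$loci$defined &
      fb$loci$fst >= stats::quantile(fb$loci$fst[fb$loci$defined], q, type = 1)]
    if (length(ta) == 0L) return(NA_real_)
    length(intersect(ta, tb)) / length(ta)
  }
  out_loc <- unique(unlist(rep_loc$per_species))
  out_sp <- unique(unlist(rep_sp$per_species))
  sharing <- data.frame(
    statistic = c("top_decile_snps", "outliers"),
    shared_fraction = c(
      top_share(f_loc, f_sp),
      if (length(out_loc) == 0L) NA_real_ else
        length(intersect(out_loc, out_sp)) / length(out_loc)))
  emit(sharing, "cross_axis_sharing.tsv")

  # -- randomized-grouping null --------------------------------------------
  rnd <- randomized_grouping_scan(g_f, seed = cfg$seed,
                                  q_threshold = cfg$q_threshold,
                                  B = cfg$scan_B, null_cache = null_cache)
  emit(data.frame(randomized_global_fst = rnd$fst$fst,
                  n_flagged = length(rnd$report$repeat_count),
                  n_repeated = length(rnd$report$repeated)),
       "randomized_null.tsv")

  manifest <- list(package = "radscan",
                   version = as.character(utils::packageVersion("radscan")),
                   seed = cfg$seed,
                   thresholds = list(min_depth = cfg$min_depth,
                                     min_inds = cfg$min_inds,
                                     min_groups = cfg$min_groups,
                                     q_threshold = cfg$q_threshold,
                                     q_strict = cfg$q_strict,
                                     scan_B = cfg$scan_B,
                                     percentile_breaks = cfg$percentile_breaks,
                                     phi = cfg$phi, e_min = cfg$e_min),
                   generator_seed = if (!is.null(cfg$generator)) cfg$generator$seed else NULL,
                   input = if (is.null(cfg$vcf)) "generator" else cfg$vcf,
                   n_loci_input = n_loci(g), n_loci_filtered = n_loci(g_f),
                   files = basename(unlist(files)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(data = list(genotypes = g_f, groups = groups, truth = truth),
                 fst_tables = list(location = tab_loc, species = tab_sp),
                 fst = list(location = f_loc, species = f_sp),
                 bins = bins, cluster_by_bin = cluster_by_bin,
                 scans = list(location = scans_loc, species = scans_sp),
                 reports = list(location = rep_loc, species = rep_sp),
                 sharing = sharing, randomized = rnd,
                 files = unlist(files)))
}
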