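#' Calibrate a neutral F_st null ensemble by island-model simulation
#'
#' Builds the null distribution for the empirical-p outlier test: an
#' island-model run with as many demes as the scan has groups and the scan's
#' per-group sample size, with the migration rate solved numerically so the
#' null's stationary multilocus F_st matches the observed one. The stationary
#' island-model relation `F_st ~ 1 / (1 + 4*N*m*(d/(d-1))^2)` provides the
#' starting value; a reduced probe run then refines `m` once if the realized
#' F_st misses the target by more than 10%. At least `B` per-locus null draws
#' (F_st plus pooled expected heterozygosity) are retained and binned into
#' `n_bins` equal-count heterozygosity classes, so that locus-specific
#' p-values condition on heterozygosity, as simulation-based outlier tests do.
#'
#' @param target_fst observed multilocus F_st to match; values below `1e-6`
#'   are clamped to that floor (near-panmictic null).
#' @param n_groups number of groups in the scan design (demes in the null).
#' @param sample_size diploids sampled per group.
#' @param B minimum number of retained null locus draws.
#' @param n_bins number of heterozygosity classes (each holds ~`B/n_bins`
#'   draws).
#' @param deme_size null deme size (diploids).
#' @param init_freq optional pool of ancestral allele frequencies for the
#'   null loci, drawn from with replacement. Default `NULL` uses
#'   Uniform(0.05, 0.95).
#' @param missing_rate per-genotype missing-call rate applied to the null
#'   samples. Matching the scanned data's missingness is essential: missing
#'   calls vary the per-locus usable sample size, which widens the tails of
#'   the per-locus F_st sampling distribution, and a complete-data null is
#'   anti-conservative against RAD data with typical missingness.
#' @param seed integer seed.
#' @return An object of class `fst_null`: list with `breaks` (heterozygosity
#'   bin edges), `bins` (list of sorted null F_st vectors), `B`, `m`,
#'   `target_fst`, `realized_fst`.
#' @export
calibrate_null <- function(target_fst, n_groups, sample_size, B = 200000L,
                           n_bins = 20L, deme_size = 1000L, init_freq = NULL,
                           missing_rate = 0, seed = 1L) {
  if (!is.null(init_freq)) {
    init_freq <- init_freq[is.finite(init_freq)]
    init_freq <- pmin(pmax(init_freq, 0.01), 0.99)
    if (length(init_freq) == 0L) init_freq <- NULL
  }
  if (is.na(target_fst)) stop("target F_st is NA")
  if (target_fst >= 0.9) {
    stop("target F_st ", target_fst, " outside the feasible range [0, 0.9)")
  }
  target <- max(target_fst, 1e-6)
  d <- as.integer(n_groups)
  stopifnot(d >= 2L, sample_size >= 2L)
  # post-migration-census stationary relation: F = lambda^2 / (2N (1 - lambda^2))
  # with lambda = 1 - m d/(d-1); full mixing (lambda = 0) reaches F = 0
  solve_m <- function(f) {
    lam <- sqrt(2 * deme_size * f / (1 + 2 * deme_size * f))
    min((1 - lam) * (d - 1) / d, (d - 1) / d)
  }
  m <- solve_m(target)
  set.seed(seed)

  run_null <- function(m, L) {
    cfg <- sim_config(m = m, n_demes = d, deme_size = deme_size, n_loci = L,
                      mu = 0, sample_size = sample_size, n_sample_times = 1L,
                      replicates = 1L, seed = sample.int(.Machine$integer.max, 1L))
    gens <- quasi_stationarity_gens(cfg)
    state <- init_island_state(cfg)
    if (!is.null(init_freq)) {
      p0 <- sample(init_freq, L, replace = TRUE)
      state$p <- matrix(rep(p0, each = d), nrow = d)
    }
    for (i in seq_len(gens)) state <- step_generation(state, cfg)
    ds <- sample_dataset(state, cfg, design = NULL, rep_i = 1L)
    dos <- ds$genotypes$dosages
    if (missing_rate > 0) {
      dos[stats::runif(length(dos)) < missing_rate] <- NA_integer_
      ds$genotypes$dosages <- dos
    }
    f <- wc_fst(ds$genotypes, ds$groups$location)
    n <- rowSums(!is.na(dos))
    p <- rowSums(dos, na.rm = TRUE) / (2 * pmax(n, 1L))
    list(fst = f$loci$fst, he = ifelse(n > 0, 2 * p * (1 - p), NA_real_),
         multi = f$fst)
  }

  # probe refinement: one multiplicative correction through the m(F) relation,
  # applied only for gross misses (the closed form is within a few percent at
  # stationarity, while the probe estimate itself carries sampling noise)
  probe <- run_null(m, max(20000L, min(50000L, B %/% 2L)))
  if (is.finite(probe$multi) && probe$multi > 0 &&
      abs(probe$multi - target) > 0.15 * target) {
    m <- min(m * solve_m(target) / solve_m(probe$multi), (d - 1) / d)
  }

  draws_fst <- numeric(0); draws_he <- numeric(0); realized <- numeric(0)
  while (length(draws_fst) < B) {
    need <- B - length(draws_fst)
    res <- run_null(m, ceiling(need * 1.1) + 1000L)
    keep <- !is.na(res$fst)
    draws_fst <- c(draws_fst, res$fst[keep])
    draws_he <- c(draws_he, res$he[keep])
    realized <- c(realized, res$multi)
  }
  qs <- stats::quantile(draws_he, probs = seq(0, 1, length.out = n_bins + 1L),
                        names = FALSE)
  breaks <- unique(qs)
  bin <- findInterval(draws_he, breaks, all.inside = TRUE)
  bins <- lapply(split(draws_fst, factor(bin, levels = seq_len(length(breaks) - 1L))),
                 sort)
  structure(list(breaks = breaks, bins = bins, B = length(draws_fst),
                 m = m, target_fst = target,
                 realized_fst = mean(realized)),
            class = "fst_null")
}

#' @export
print.fst_null <- function(x, ...) {
  cat(sprintf("fst_null: B = %d draws in %d He classes; target F_st = %.4g, realized = %.4g (m = %.4g)\n",
              x$B, length(x$bins), x$target_fst, x$realized_fst, x$m))
  invisible(x)
}

#' Empirical p- and q-values against a calibrated null
#'
#' For every scanned locus, the empirical p-value is
#' `(1 + #null draws in the locus's heterozygosity class with F_st >= observed)
#' / (B_class + 1)`; q-values are Benjamini-Hochberg, and a locus is flagged
#' as an outlier iff `q < q_threshold` (the study's rule, an expected false
#' discovery rate of `q_threshold`).
#'
#' @param fst numeric vector of per-locus F_st values (NA = undefined,
#'   excluded).
#' @param he pooled expected heterozygosity per locus, aligned with `fst`.
#' @param null an [calibrate_null()] ensemble.
#' @param locus_id optional locus identifiers.
#' @param q_threshold FDR threshold (default 0.2).
#' @param comparison free-form label describing the scanned contrast.
#' @return An object of class `outlier_scan`: list with `loci` (data.frame:
#'   `locus_id`, `fst`, `he`, `p`, `q`, `outlier`), `comparison`,
#'   `q_threshold`, `n_considered`, `n_outliers`, `null_B`,
#'   `null_target_fst`.
#' @export
empirical_pq <- function(fst, he, null, locus_id = NULL, q_threshold = 0.2,
                         comparison = "scan") {
  stopifnot(inherits(null, "fst_null"), length(fst) == length(he))
  if (is.null(locus_id)) locus_id <- as.character(seq_along(fst))
  keep <- !is.na(fst) & !is.na(he)
  x <- fst[keep]
  bin <- findInterval(he[keep], null$breaks, all.inside = TRUE)
  p <- rep(NA_real_, length(x))
  for (b in unique(bin)) {
    v <- null$bins[[b]]
    sel <- bin == b
    n_ge <- length(v) - findInterval(x[sel], v, left.open = TRUE)
    p[sel] <- (1 + n_ge) / (length(v) + 1)
  }
  q <- stats::p.adjust(p, method = "BH")
  loci <- data.frame(locus_id = locus_id[keep], fst = x, he = he[keep],
                     p = p, q = q, outlier = q < q_threshold,
                     stringsAsFactors = FALSE)
  structure(list(loci = loci, comparison = comparison,
                 q_threshold = q_threshold,
                 n_considered = nrow(loci),
                 n_outliers = sum(loci$outlier),
                 null_B = null$B, null_target_fst = null$target_fst),
            class = "outlier_scan")
}

#' @export
print.outlier_scan <- function(x, ...) {
  cat(sprintf("outlier_scan [%s]: %d / %d loci flagged at q < %.2g\n",
              x$comparison, x$n_outliers, x$n_considered, x$q_threshold))
  invisible(x)
}

# pooled expected heterozygosity per locus for a dosage matrix
pooled_he <- function(dos) {
  n <- rowSums(!is.na(dos))
  p <- rowSums(dos, na.rm = TRUE) / (2 * pmax(n, 1L))
  ifelse(n > 0, 2 * p * (1 - p), NA_real_)
}

#' Run the study's battery of outlier scans
#'
#' `per_pair` mode emits one scan per (species, location pair) — the nine-row
#' design of the study's outlier table; `global_per_species` mode emits one
#' scan per species across all its locations. Each scan computes per-locus
#' Weir-Cockerham F_st among locations on the species' individuals, calibrates
#' (or reuses) a simulation null matching the comparison's multilocus F_st,
#' sample sizes and group count, and applies [empirical_pq()].
#'
#' Null ensembles are cached in `null_cache` keyed by (group count, sample
#' size, target F_st rounded to 2 significant digits): comparisons of the same
#' design and background differentiation share a null.
#'
#' @param g a [genotype_matrix()].
#' @param groups a [sample_groups()].
#' @param mode `"per_pair"` or `"global_per_species"`.
#' @param q_threshold FDR threshold.
#' @param B null-ensemble size passed to [calibrate_null()].
#' @param null_cache environment used to memoize null ensembles across calls;
#'   supply your own to share nulls between datasets.
#' @param seed integer seed for null calibration.
#' @return list of [empirical_pq()] results (class `outlier_scan_list`), each
#'   carrying `species` and `pair` fields.
#' @export
scan_comparisons <- function(g, groups,
                             mode = c("per_pair", "global_per_species"),
                             q_threshold = 0.2, B = 200000L,
                             null_cache = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(null_cache)) null_cache <- new.env(parent = emptyenv())
  sp_lab <- group_labels(g, groups, "species")
  loc_lab <- group_labels(g, groups, "location")
  miss_rate <- mean(is.na(g$dosages))
  scans <- list()
  for (sp in sort(unique(sp_lab))) {
    locs <- sort(unique(loc_lab[sp_lab == sp]))
    contrasts <- if (mode == "per_pair") {
      if (length(locs) < 2L) {
        warning("species ", sp, " has fewer than 2 locations; skipped")
        list()
      } else utils::combn(locs, 2L, simplify = FALSE)
    } else {
      if (length(locs) < 2L) {
        warning("species ", sp, " has fewer than 2 locations; skipped")
        list()
      } else list(locs)
    }
    for (ctr in contrasts) {
      sel <- which(sp_lab == sp & loc_lab %in% ctr)
      sub <- subset_samples(g, sel)
      f <- wc_fst(sub, loc_lab[sel])
      n_grp <- length(ctr)
      n_per <- round(length(sel) / n_grp)
      # calibration targets snap to a 25%-step multiplicative grid (within the
      # calibration's own 10% tolerance) so comparisons with near-identical
      # background F_st share one cached null ensemble
      target <- exp(log(1.25) * round(log(max(f$fst, 1e-6)) / log(1.25)))
      key <- paste(n_grp, n_per, signif(target, 3), signif(miss_rate, 1),
                   sep = "|")
      if (!exists(key, envir = null_cache, inherits = FALSE)) {
        assign(key,
               calibrate_null(target, n_groups = n_grp, sample_size = n_per,
                              B = B, missing_rate = miss_rate,
                              seed = seed + length(ls(null_cache))),
               envir = null_cache)
      }
      null <- get(key, envir = null_cache)
      scan <- empirical_pq(f$loci$fst, pooled_he(sub$dosages), null,
                           locus_id = f$loci$locus_id,
                           q_threshold = q_threshold,
                           comparison = paste0(sp, ": ", paste(ctr, collapse = " vs ")))
      scan$species <- sp
      scan$pair <- paste(ctr, collapse = "|")
      scans[[length(scans) + 1L]] <- scan
    }
  }
  structure(scans, class = "outlier_scan_list")
}

#' Repeated outliers across species
#'
#' A locus is a *repeated* outlier when flagged in at least two species
#' (matching by locus identity across any location pair), and
#' *triple-repeated* when flagged in all species scanned. The
#' shared-consideration ratio — the fraction of flagged loci that were also
#' considered (tested, flagged or not) in at least one other species — is the
#' study's control for coverage-driven non-repeatability. A stricter same-pair
#' matching variant (flagged for the same location pair in several species) is
#' reported alongside.
#'
#' @param scans an `outlier_scan_list` from [scan_comparisons()].
#' @return An object of class `repeated_outlier_report`: list with
#'   `per_species` (named list of flagged locus-id vectors), `repeat_count`
#'   (per flagged locus, species count), `repeated` / `triple` locus-id
#'   vectors, `repeated_same_pair`, `shared_consideration_ratio`,
#'   `n_species`.
#' @export
repeated_outliers <- function(scans) {
  sp_levels <- sort(unique(vapply(scans, `[[`, "", "species")))
  flagged_by_sp <- lapply(sp_levels, function(sp) {
    ids <- unlist(lapply(scans[vapply(scans, `[[`, "", "species") == sp],
                         function(s) s$loci$locus_id[s$loci$outlier]))
    unique(ids)
  })
  names(flagged_by_sp) <- sp_levels
  considered_by_sp <- lapply(sp_levels, function(sp) {
    unique(unlist(lapply(scans[vapply(scans, `[[`, "", "species") == sp],
                         function(s) s$loci$locus_id)))
  })
  names(considered_by_sp) <- sp_levels
  all_flagged <- unique(unlist(flagged_by_sp))
  cnt <- vapply(all_flagged, function(id) {
    sum(vapply(flagged_by_sp, function(v) id %in% v, logical(1L)))
  }, integer(1L))
  repeated <- all_flagged[cnt >= 2L]
  triple <- all_flagged[cnt >= length(sp_levels) & length(sp_levels) >= 3L]
  # same-pair variant: flagged for the same location pair in >= 2 species
  pair_sp <- list()
  for (s in scans) {
    for (id in s$loci$locus_id[s$loci$outlier]) {
      k <- paste(id, s$pair, sep = "@")
      pair_sp[[k]] <- union(pair_sp[[k]], s$species)
    }
  }
  same_pair <- unique(sub("@.*$", "", names(pair_sp)[lengths(pair_sp) >= 2L]))
  shared <- if (length(all_flagged) == 0L) NA_real_ else {
    mean(vapply(all_flagged, function(id) {
      owners <- sp_levels[vapply(flagged_by_sp, function(v) id %in% v, logical(1L))]
      if (length(owners) >= 2L) return(TRUE)   # flagged elsewhere => considered there
      others <- setdiff(sp_levels, owners)
      any(vapply(considered_by_sp[others], function(v) id %in% v, logical(1L)))
    }, logical(1L)))
  }
  structure(list(per_species = flagged_by_sp,
                 repeat_count = stats::setNames(cnt, all_flagged),
                 repeated = repeated, triple = triple,
                 repeated_same_pair = same_pair,
                 shared_consideration_ratio = shared,
                 n_species = length(sp_levels)),
            class = "repeated_outlier_report")
}

#' @export
print.repeated_outlier_report <- function(x, ...) {
  cat(sprintf("repeated_outlier_report: %d flagged loci, %d repeated, %d triple (shared-consideration %.0f%%)\n",
              length(x$repeat_count), length(x$repeated), length(x$triple),
              100 * x$shared_consideration_ratio))
  invisible(x)
}

#' Randomized-grouping null scan
#'
#' Permutes individuals uniformly into an `n_species` x `n_locations` design
#' of equal cell sizes (the study's "three random species from three random
#' locations") and reruns the F_st + outlier-scan + repeated-outlier pipeline
#' on the shuffled labels. On structured data of the study's magnitude this
#' destroys the signal: the global F_st is ~0 and no repeated outliers are
#' expected.
#'
#' @param g a [genotype_matrix()].
#' @param n_species,n_locations randomized design dimensions; `n_samples(g)`
#'   must be divisible by their product.
#' @param seed integer seed (recorded in the result).
#' @param q_threshold,B,null_cache passed to [scan_comparisons()].
#' @param scan set `FALSE` to skip the (expensive) outlier scans and report
#'   only the randomized F_st.
#' @return list with `fst` ([wc_fst()] by randomized location), `scans`,
#'   `report` ([repeated_outliers()]), `groups`, `seed`.
#' @export
randomized_grouping_scan <- function(g, n_species = 3L, n_locations = 3L,
                                     seed = 1L, q_threshold = 0.2,
                                     B = 200000L, null_cache = NULL,
                                     scan = TRUE) {
  n <- n_samples(g)
  cells <- n_species * n_locations
  if (n %% cells != 0L) {
    stop("sample count ", n, " is not divisible into ", cells, " equal cells")
  }
  set.seed(seed)
  perm <- sample.int(n)
  cell_idx <- rep(seq_len(cells), each = n %/% cells)
  species <- paste0("rsp", ((cell_idx - 1L) %% n_species) + 1L)
  location <- paste0("rloc", ((cell_idx - 1L) %/% n_species) + 1L)
  groups <- sample_groups(g$samples[perm], species, location)
  groups <- groups[match(g$samples, groups$sample), ]
  class(groups) <- c("sample_groups", "data.frame")
  f <- wc_fst(g, groups$location)
  scans <- NULL; report <- NULL
  if (scan) {
    scans <- scan_comparisons(g, groups, mode = "per_pair",
                              q_threshold = q_threshold, B = B,
                              null_cache = null_cache, seed = seed)
    report <- repeated_outliers(scans)
  }
  list(fst = f, scans = scans, report = report, groups = groups, seed = seed)
}
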