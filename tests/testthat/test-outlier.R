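test_that("null calibration hits its target F_st and respects the binning contract", {
  null <- calibrate_null(0.004, n_groups = 3L, sample_size = 14L, B = 100000L,
                         seed = 3L)
  expect_lt(abs(null$realized_fst - 0.004), 0.1 * 0.004 + 2e-4)
  expect_gte(null$B, 100000L)
  expect_gte(length(null$bins), 19L)
  expect_true(all(lengths(null$bins) >= null$B / 40))

  # target 0 is clamped to a near-panmictic null instead of failing
  null0 <- calibrate_null(0, n_groups = 2L, sample_size = 10L, B = 5000L,
                          seed = 4L)
  expect_lt(null0$realized_fst, 0.005)
  expect_error(calibrate_null(0.95, 2L, 10L), "feasible")
})

test_that("empirical p-values follow the rank formula and drive BH flags", {
  null <- structure(list(breaks = c(0, 0.25, 0.5),
                         bins = list(sort(runif(999, -0.01, 0.2)),
                                     sort(runif(999, -0.01, 0.2))),
                         B = 1998L, m = 0.01, target_fst = 0.004,
                         realized_fst = 0.004),
                    class = "fst_null")
  # a locus exceeding all 999 draws in its class gets p = 1/1000
  s <- empirical_pq(c(0.9, 0.15), c(0.1, 0.4), null, c("hi", "mid"))
  expect_equal(s$loci$p[s$loci$locus_id == "hi"], 1 / 1000)
  # all-tied-at-top p values -> q = p; the extreme locus is flagged
  expect_true(s$loci$outlier[s$loci$locus_id == "hi"])

  # observations below every null draw give p = 1 and no flags
  s2 <- empirical_pq(rep(-0.5, 5L), rep(0.3, 5L), null)
  expect_true(all(s2$loci$p == 1))
  expect_equal(s2$n_outliers, 0L)
})

test_that("scan battery emits one scan per species-pair and honours the design", {
  ds <- generate_dataset(generator_config(n_stacks = 150, seed = 21))
  cache <- new.env(parent = emptyenv())
  scans <- scan_comparisons(ds$genotypes, ds$groups, mode = "per_pair",
                            B = 3000L, null_cache = cache, seed = 2L)
  expect_length(scans, 9L)
  sp <- vapply(scans, `[[`, "", "species")
  expect_equal(unname(table(sp)), rep(3L, 3L), ignore_attr = TRUE)
  # global mode: one scan per species
  gl <- scan_comparisons(ds$genotypes, ds$groups, mode = "global_per_species",
                         B = 3000L, null_cache = cache, seed = 2L)
  expect_length(gl, 3L)

  # a species missing one location is skipped with a warning
  keep <- !(ds$groups$species == "spA" & ds$groups$location == "L3")
  g2 <- subset_samples(ds$genotypes, which(keep))
  s2 <- scan_comparisons(g2, ds$groups[keep, ], mode = "per_pair",
                         B = 3000L, null_cache = cache, seed = 2L)
  expect_length(s2, 7L)   # spA contributes its single remaining pair
})

test_that("repeated-outlier bookkeeping matches set semantics", {
  mk <- function(species, pair, ids, considered) {
    loci <- data.frame(locus_id = considered,
                       fst = 0.1, he = 0.3, p = 0.5, q = 0.5,
                       outlier = considered %in% ids)
    structure(list(loci = loci, species = species, pair = pair,
                   comparison = paste(species, pair)),
              class = "outlier_scan")
  }
  scans <- structure(list(
    mk("sp1", "A|B", "L1", c("L1", "L2", "L3")),
    mk("sp2", "A|B", "L1", c("L1", "L2")),
    mk("sp3", "A|C", c("L1", "L4"), c("L1", "L4"))),
    class = "outlier_scan_list")
  rep <- repeated_outliers(scans)
  expect_equal(rep$repeated, "L1")
  expect_equal(rep$triple, "L1")
  # L1 flagged in all, considered everywhere; L4 flagged in sp3 only and not
  # considered by any other species -> ratio 1/2
  expect_equal(rep$shared_consideration_ratio, 0.5)
  expect_equal(rep$repeated_same_pair, "L1")   # same pair in sp1 and sp2

  disjoint <- structure(list(
    mk("sp1", "A|B", "L1", c("L1", "L9")),
    mk("sp2", "A|B", "L2", c("L2", "L9")),
    mk("sp3", "A|B", "L3", c("L3", "L9"))),
    class = "outlier_scan_list")
  rep0 <- repeated_outliers(disjoint)
  expect_length(rep0$repeated, 0L)
  expect_length(rep0$triple, 0L)
})

test_that("randomized regrouping destroys structure and repeats", {
  ds <- generate_dataset(generator_config(n_stacks = 400, seed = 25,
                                          f_loc = 0.004, f_sp = 0.004))
  r1 <- randomized_grouping_scan(ds$genotypes, seed = 5L, scan = FALSE)
  expect_lt(abs(r1$fst$fst), 0.002)
  r2 <- randomized_grouping_scan(ds$genotypes, seed = 5L, scan = FALSE)
  expect_identical(r1$groups, r2$groups)       # same seed, same grouping
  r3 <- randomized_grouping_scan(ds$genotypes, seed = 6L, scan = FALSE)
  expect_false(identical(r1$groups$cell, r3$groups$cell))
  # sample counts must divide into the requested cells
  odd <- subset_samples(ds$genotypes, 1:125)
  expect_error(randomized_grouping_scan(odd, seed = 1L), "divisible")
})

test_that("p-values are super-uniform under a matched null", {
  # island-model data scanned against an island-model-calibrated null
  cfg <- sim_config(m = 0.02, n_demes = 2L, n_loci = 4000L,
                    generations = 250L, n_sample_times = 1L,
                    replicates = 1L, seed = 31L)
  ds <- run_scenario(cfg)[[1L]]
  f <- wc_fst(ds$genotypes, ds$groups$location)
  null <- calibrate_null(max(f$fst, 1e-6), 2L, 14L, B = 30000L, seed = 6L)
  he <- radscan:::pooled_he(ds$genotypes$dosages)
  s <- empirical_pq(f$loci$fst, he, null, f$loci$locus_id)
  for (x in c(0.01, 0.05, 0.1, 0.25)) {
    # empirical CDF at x must not exceed x by more than binomial noise
    expect_lte(mean(s$loci$p <= x),
               x + 3 * sqrt(x * (1 - x) / nrow(s$loci)) + 0.01)
  }
  expect_equal(s$n_outliers, 0L)
})
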