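test_that("initial state starts all demes identical and is seed-reproducible", {
  cfg <- sim_config(m = 0.1, n_demes = 5L, n_loci = 500L, seed = 3L)
  set.seed(cfg$seed)
  s1 <- init_island_state(cfg)
  set.seed(cfg$seed)
  s2 <- init_island_state(cfg)
  expect_identical(s1$p, s2$p)
  expect_true(all(s1$p >= 0.05 & s1$p <= 0.95))
  expect_equal(max(apply(s1$p, 2L, function(x) diff(range(x)))), 0)
  # F_st on a sampled dataset from the identical-deme state is ~0
  ds <- radscan:::sample_dataset(s1, cfg, design = NULL, rep_i = 1L)
  f <- wc_fst(ds$genotypes, ds$groups$location)
  expect_lt(abs(f$fst), 0.02)
})

test_that("one generation of drift has binomial variance", {
  cfg <- sim_config(m = 0, n_demes = 2L, deme_size = 1000L, n_loci = 20000L,
                    mu = 0, seed = 5L)
  cfg$n_demes <- 1L   # single-deme drift check; config floor bypassed on purpose
  state <- structure(list(p = matrix(0.5, 1L, cfg$n_loci), gen = 0L),
                     class = "sim_state")
  set.seed(5)
  nxt <- step_generation(state, cfg)
  v <- var(as.vector(nxt$p))
  expect_equal(v, 0.5 * 0.5 / 2000, tolerance = 0.05)
})

test_that("full mixing equalizes post-migration frequencies; no migration fixes loci", {
  p <- matrix(c(0.2, 0.8), 2L, 5L)
  # with 2 demes, full mixing happens at m = (d-1)/d = 0.5 (m = 1 swaps demes)
  mixed <- radscan:::migrate_freq(p, 0.5)
  expect_equal(mixed[1L, ], mixed[2L, ])
  expect_equal(mixed[1L, ], rep(0.5, 5L))
  expect_equal(radscan:::migrate_freq(p, 1), p[2:1, ])

  cfg <- sim_config(m = 0, n_demes = 2L, deme_size = 30L, n_loci = 200L,
                    mu = 0, seed = 11L)
  set.seed(cfg$seed)
  state <- init_island_state(cfg)
  for (i in 1:2000) state <- step_generation(state, cfg)
  expect_true(all(state$p %in% c(0, 1)))   # pure drift absorbs
})

test_that("isolated demes fixed for different alleles reach per-locus F_st 1", {
  cfg <- sim_config(m = 0, n_demes = 2L, deme_size = 50L, n_loci = 100L,
                    mu = 0, sample_size = 10L, seed = 2L)
  state <- structure(list(p = rbind(rep(0, 100L), rep(1, 100L)), gen = 0L),
                     class = "sim_state")
  set.seed(2)
  ds <- radscan:::sample_dataset(state, cfg, design = NULL, rep_i = 1L)
  f <- wc_fst(ds$genotypes, ds$groups$location)
  expect_true(all(f$loci$fst == 1))
  # a deme at frequency 0 yields all-zero dosages
  expect_true(all(ds$genotypes$dosages[, 1:10] == 0L))
})

test_that("sampled heterozygosity tracks 2p(1-p) per deme (HWE realization)", {
  cfg <- sim_config(m = 0.1, n_demes = 3L, n_loci = 3000L, generations = 20L,
                    sample_size = 30L, n_sample_times = 1L, replicates = 1L,
                    seed = 17L)
  ds <- run_scenario(cfg)[[1L]]
  dos <- ds$genotypes$dosages[, 1:30]          # first deme's sample
  p_hat <- rowMeans(dos) / 2
  ho <- rowMeans(dos == 1L)
  keep <- p_hat > 0.2 & p_hat < 0.8
  expect_equal(mean(ho[keep]), mean(2 * p_hat[keep] * (1 - p_hat[keep])),
               tolerance = 0.02)
})

test_that("quasi-stationarity detection is fast for strong migration and capped without it", {
  cfg <- sim_config(m = 0.5, n_loci = 1000L, seed = 7L)
  set.seed(7)
  gens <- quasi_stationarity_gens(cfg, probe_loci = 1000L)
  expect_lte(gens, 100L)
  set.seed(7)
  gens2 <- quasi_stationarity_gens(cfg, probe_loci = 1000L)
  expect_identical(gens, gens2)                # deterministic under seed

  cfg0 <- sim_config(m = 0, n_loci = 500L, deme_size = 5000L, seed = 7L)
  set.seed(7)
  expect_warning(g0 <- quasi_stationarity_gens(cfg0, probe_loci = 300L,
                                               cap = 200L),
                 "cap")
  expect_equal(g0, 200L)
})

test_that("run_scenario yields replicates x sample times datasets with the pseudo-design", {
  cfg <- sim_config(m = 0.5, n_loci = 400L, generations = 20L,
                    n_sample_times = 2L, sample_interval = 5L,
                    replicates = 2L, sample_size = 4L, seed = 19L)
  ds <- run_scenario(cfg, design = c(3L, 3L))
  expect_length(ds, 4L)
  g1 <- ds[[1L]]
  expect_equal(n_samples(g1$genotypes), 36L)
  expect_setequal(unique(g1$groups$species), paste0("sp", 1:3))
  expect_setequal(unique(g1$groups$location), paste0("loc", 1:3))
  expect_true(all(table(g1$groups$cell) == 4L))
})

test_that("structured migration yields more differentiation than panmictic", {
  fs <- function(m, burn) {
    cfg <- sim_config(m = m, n_loci = 2000L, generations = burn,
                      n_sample_times = 10L, sample_interval = 10L,
                      replicates = 3L, seed = 23L)
    vapply(run_scenario(cfg),
           function(d) wc_fst(d$genotypes, d$groups$location)$fst,
           numeric(1L))
  }
  f_pan <- fs(0.5, 60L)
  f_str <- fs(0.02, 250L)
  expect_length(f_pan, 30L)
  expect_gt(mean(f_str), mean(f_pan))
  expect_gt(min(f_str), max(f_pan))   # distributions do not even overlap
  # panmictic per-locus histogram is tight around 0, far from 1
  cfg <- sim_config(m = 0.5, n_loci = 2000L, generations = 60L,
                    n_sample_times = 1L, replicates = 1L, seed = 29L)
  d <- run_scenario(cfg)[[1L]]
  f <- wc_fst(d$genotypes, d$groups$location)
  expect_lt(max(f$loci$fst, na.rm = TRUE), 0.5)
  expect_lt(abs(median(f$loci$fst, na.rm = TRUE)), 0.02)
})
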