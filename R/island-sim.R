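#' Island-model simulation configuration
#'
#' Parameters of the forward Wright-Fisher island model used as the neutral
#' null: `n_demes` equal-size demes of `deme_size` diploids exchange migrants
#' symmetrically; `m` is the total per-individual emigration probability per
#' generation, split equally among the other `n_demes - 1` demes; mutation is
#' symmetric at rate `mu` per allele copy per generation. The study's two
#' scenarios are `m = 0.5` ("panmictic") and `m = 0.02` ("structure"),
#' 9 demes of 1000 diploids, 80,000 unlinked diallelic loci, `mu = 1e-9`,
#' 14 individuals sampled per deme, 3 replicate runs sampled 10 times each
#' (30 datasets per scenario).
#'
#' @param m migration rate in `[0, 1]`.
#' @param n_demes,deme_size,n_loci,mu,sample_size,n_sample_times,sample_interval,replicates
#'   see description; defaults match the study's scenarios.
#' @param generations burn-in generations before the first sample; `NULL`
#'   (default) means determine it with [quasi_stationarity_gens()].
#' @param seed integer RNG seed for the whole run.
#' @return An object of class `sim_config` (validated list).
#' @export
sim_config <- function(m, n_demes = 9L, deme_size = 1000L, n_loci = 80000L,
                       mu = 1e-9, generations = NULL, sample_size = 14L,
                       n_sample_times = 10L, sample_interval = 10L,
                       replicates = 3L, seed = 1L) {
  stopifnot(m >= 0, m <= 1, mu >= 0, n_demes >= 2, deme_size >= 1,
            n_loci >= 1, sample_size >= 1, n_sample_times >= 1,
            replicates >= 1)
  structure(list(m = m, n_demes = as.integer(n_demes),
                 deme_size = as.integer(deme_size),
                 n_loci = as.integer(n_loci), mu = mu,
                 generations = generations,
                 sample_size = as.integer(sample_size),
                 n_sample_times = as.integer(n_sample_times),
                 sample_interval = as.integer(sample_interval),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Initialize the allele-frequency state
#'
#' Every locus receives one ancestral frequency drawn Uniform(0.05, 0.95),
#' identical across demes, so among-deme F_st starts at exactly zero.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `sim_state`: list with `p` (demes x loci
#'   frequency matrix) and `gen` (generation counter).
#' @export
init_island_state <- function(cfg) {
  p0 <- stats::runif(cfg$n_loci, 0.05, 0.95)
  structure(list(p = matrix(rep(p0, each = cfg$n_demes),
                            nrow = cfg$n_demes),
                 gen = 0L),
            class = "sim_state")
}

#' Advance the island model by one generation
#'
#' Per locus and deme: (1) migration — the post-migration frequency is
#' `(1 - m) * own + m * mean(others)`; (2) drift — the next generation's
#' allele count is binomial with `2N` trials at the post-migration frequency;
#' (3) mutation — allele copies flip symmetrically at rate `mu` (binomial on
#' each allele class). Deme sizes are constant.
#'
#' @param state a `sim_state`.
#' @param cfg the matching [sim_config()].
#' @return the updated `sim_state`.
#' @export
step_generation <- function(state, cfg) {
  p <- migrate_freq(state$p, cfg$m)
  d <- cfg$n_demes
  two_n <- 2L * cfg$deme_size
  counts <- matrix(stats::rbinom(length(p), two_n, p), nrow = d)
  if (cfg$mu > 0) {
    gain <- stats::rbinom(length(counts), two_n - counts, cfg$mu)
    loss <- stats::rbinom(length(counts), counts, cfg$mu)
    counts <- counts + gain - loss
  }
  state$p <- counts / two_n
  state$gen <- state$gen + 1L
  state
}

# ratio-of-sums F_st monitor straight from deme frequencies (no sampling):
# sum over loci of among-deme variance / sum of pbar*(1-pbar)
freq_fst <- function(p) {
  pbar <- colMeans(p)
  v <- colMeans(sweep(p, 2L, pbar)^2)
  denom <- sum(pbar * (1 - pbar))
  if (denom == 0) return(0)
  sum(v) / denom
}

#' Generations to quasi-stationarity of the F_st trajectory
#'
#' Runs a reduced probe simulation (default 2,000 loci) with the same deme
#' structure, monitoring the frequency-level multilocus F_st every
#' `check_every` generations, and returns the first generation at which the
#' trajectory changes by less than `tol` (relative) over a `window`-generation
#' look-back. Capped at `cap` generations with a warning (a pure-drift model
#' with `m = 0` never stabilizes on this timescale).
#'
#' @param cfg a [sim_config()].
#' @param probe_loci loci used by the probe run.
#' @param check_every,window,tol,cap monitor settings.
#' @return integer generation count.
#' @export
quasi_stationarity_gens <- function(cfg, probe_loci = 2000L, check_every = 10L,
                                    window = 50L, tol = 0.05, cap = 500L) {
  probe <- cfg
  probe$n_loci <- as.integer(probe_loci)
  state <- init_island_state(probe)
  traj <- numeric(0)
  gens <- seq(check_every, cap, by = check_every)
  lag <- window %/% check_every
  for (t in gens) {
    for (i in seq_len(check_every)) state <- step_generation(state, probe)
    traj <- c(traj, freq_fst(state$p))
    k <- length(traj)
    if (k > lag) {
      now <- traj[k]; then <- traj[k - lag]
      if (abs(now - then) < tol * max(now, 1e-8)) return(t)
    }
  }
  warning("quasi-stationarity not reached within ", cap, " generations; using the cap")
  cap
}

#' Run an island-model scenario and sample genotype datasets
#'
#' Burns each replicate in to `cfg$generations` (or the quasi-stationarity
#' point when `NULL`), then draws `n_sample_times` datasets spaced
#' `sample_interval` generations apart. Each dataset samples `sample_size`
#' diploids per deme as Hardy-Weinberg genotype pairs from the deme's allele
#' frequency at the post-migration census point: individuals are observed
#' after the generation's migrants have joined their deme, as an
#' individual-based simulator censuses them, and before reproduction
#' regenerates drift deviations. Loci monomorphic in a sample are retained
#' (they are flagged undefined downstream by the F_st machinery).
#'
#' @param cfg a [sim_config()].
#' @param design optional `c(n_species, n_locations)` mapping the demes onto a
#'   crossed pseudo-design (requires `n_demes == n_species * n_locations`);
#'   deme `k` becomes species `((k-1) %% n_species) + 1` at location
#'   `((k-1) %/% n_species) + 1`. Default `NULL` labels every deme as its own
#'   location within a single "species".
#' @return list of datasets; each is a list with `genotypes`
#'   ([genotype_matrix()]), `groups` ([sample_groups()]), `replicate`,
#'   `generation`.
#' @export
run_scenario <- function(cfg, design = NULL) {
  set.seed(cfg$seed)
  gens <- cfg$generations
  if (is.null(gens)) gens <- quasi_stationarity_gens(cfg)
  if (!is.null(design)) {
    stopifnot(length(design) == 2L, prod(design) == cfg$n_demes)
  }
  datasets <- list()
  for (rep_i in seq_len(cfg$replicates)) {
    state <- init_island_state(cfg)
    for (i in seq_len(gens)) state <- step_generation(state, cfg)
    for (s in seq_len(cfg$n_sample_times)) {
      if (s > 1L) for (i in seq_len(cfg$sample_interval)) {
        state <- step_generation(state, cfg)
      }
      datasets[[length(datasets) + 1L]] <-
        sample_dataset(state, cfg, design, rep_i)
    }
  }
  datasets
}

migrate_freq <- function(p, m) {
  d <- nrow(p)
  if (m <= 0 || d < 2L) return(p)
  tot <- colSums(p)
  (1 - m) * p + m * (matrix(tot, nrow = d, ncol = ncol(p), byrow = TRUE) - p) / (d - 1L)
}

sample_dataset <- function(state, cfg, design, rep_i) {
  d <- cfg$n_demes; L <- cfg$n_loci; k <- cfg$sample_size
  p_census <- migrate_freq(state$p, cfg$m)   # post-migration census point
  dos <- matrix(0L, nrow = L, ncol = d * k)
  for (dm in seq_len(d)) {
    cols <- ((dm - 1L) * k + 1L):(dm * k)
    dos[, cols] <- matrix(stats::rbinom(L * k, 2L, rep(p_census[dm, ], k)),
                          nrow = L)
  }
  samples <- paste0("d", rep(seq_len(d), each = k), "_i", rep(seq_len(k), d),
                    "_r", rep_i, "g", state$gen)
  if (is.null(design)) {
    species <- rep("sim", d * k)
    location <- paste0("deme", rep(seq_len(d), each = k))
  } else {
    sp_of_deme <- ((seq_len(d) - 1L) %% design[1L]) + 1L
    loc_of_deme <- ((seq_len(d) - 1L) %/% design[1L]) + 1L
    species <- paste0("sp", rep(sp_of_deme, each = k))
    location <- paste0("loc", rep(loc_of_deme, each = k))
  }
  g <- genotype_matrix(dos,
                       data.frame(stack_id = seq_len(L), snp_offset = 0L,
                                  ref = "A", alt = "C"),
                       samples)
  list(genotypes = g,
       groups = sample_groups(samples, species, location),
       replicate = rep_i, generation = state$gen)
}
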