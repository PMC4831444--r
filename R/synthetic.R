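#' Configuration for the synthetic RAD-genotype generator
#'
#' Emulates the study's SNP genotype calls: a crossed species x location
#' design (default 3 x 3 cells of 14 diploids, 126 individuals), ~30,000
#' stacks carrying 1-3 SNPs each (mean 1.8), hierarchical Balding-Nichols
#' divergence with independent knobs for the location axis (`f_loc`) and the
#' species-within-location axis (`f_sp`, both defaulting to the study's
#' background of 0.004), negative-binomial per-stack read depth around a mean
#' of 31x, depth-driven plus MCAR missingness, and optional planted divergent
#' loci and linked blocks with recorded ground truth.
#'
#' @param species,locations label vectors of the design.
#' @param n_per_cell diploid individuals per species x location cell.
#' @param n_stacks number of RAD stacks.
#' @param snp_count_probs probabilities of a stack carrying 1, 2 or 3 SNPs
#'   (defaults give a mean of 1.8 SNPs per stack).
#' @param f_loc,f_sp target divergence in `[0, 1)` along the location axis
#'   (realized multilocus F_st among locations, species pooled) and the
#'   species-within-location axis. Internally the location-level
#'   Balding-Nichols parameter is `f_loc - f_sp/n_species`, because the
#'   species-step deviations average into the pooled location frequencies and
#'   would otherwise inflate the among-location divergence beyond its target.
#' @param ancestral_shape Beta shape parameters of the ancestral-frequency
#'   law; `ancestral_bounds` truncates it (keeps loci polymorphic and the
#'   expected-heterozygosity spread realistic).
#' @param snp_jitter_sd within-stack SNP frequency jitter (SNPs of one stack
#'   share their stack's genealogy up to this perturbation).
#' @param depth_mean,depth_size negative-binomial depth law per stack and
#'   individual.
#' @param min_call_depth genotypes with stack depth below this are dropped to
#'   missing (their depth is zeroed).
#' @param mcar_rate additional missing-completely-at-random genotype rate.
#' @param planted data.frame of planted divergent loci, one row per locus,
#'   with columns `type` (`"location_divergent"`, `"species_divergent"` or
#'   `"fixed_difference"`), `level` (the focal label), `p_focal`, `p_other`
#'   (allele frequencies in the focal and remaining groups;
#'   ignored for `fixed_difference`, which is frequency 0 in the focal
#'   location and 1 elsewhere, in all species).
#' @param linked_blocks list of linked-block requests added by
#'   [plant_linked_block()].
#' @param seed integer seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(species = c("spA", "spB", "spC"),
                             locations = c("L1", "L2", "L3"),
                             n_per_cell = 14L, n_stacks = 30000L,
                             snp_count_probs = c(0.45, 0.30, 0.25),
                             f_loc = 0.004, f_sp = 0.004,
                             ancestral_shape = c(0.8, 0.8),
                             ancestral_bounds = c(0.02, 0.98),
                             snp_jitter_sd = 0.03,
                             depth_mean = 31, depth_size = 4,
                             min_call_depth = 10L, mcar_rate = 0.02,
                             planted = NULL, linked_blocks = list(),
                             seed = 1L) {
  stopifnot(n_per_cell >= 2L, n_stacks >= 1L,
            f_loc >= 0, f_loc < 1, f_sp >= 0, f_sp < 1,
            abs(sum(snp_count_probs) - 1) < 1e-8,
            mcar_rate >= 0, mcar_rate < 1)
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("type", "level") %in% names(planted)),
              all(planted$type %in% c("location_divergent", "species_divergent",
                                      "fixed_difference")))
  }
  structure(list(species = species, locations = locations,
                 n_per_cell = as.integer(n_per_cell),
                 n_stacks = as.integer(n_stacks),
                 snp_count_probs = snp_count_probs,
                 f_loc = f_loc, f_sp = f_sp,
                 ancestral_shape = ancestral_shape,
                 ancestral_bounds = ancestral_bounds,
                 snp_jitter_sd = snp_jitter_sd,
                 depth_mean = depth_mean, depth_size = depth_size,
                 min_call_depth = as.integer(min_call_depth),
                 mcar_rate = mcar_rate,
                 planted = planted, linked_blocks = linked_blocks,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Request a planted linked block
#'
#' Adds a block of loci sharing a latent haplotype indicator, so that their
#' realized median pairwise r-squared approaches `r2`. Allele copies follow
#' the latent haplotype with a per-copy flip probability
#' `e = (1 - r2^(1/4)) / 2` (dosage correlation between two such loci is
#' approximately `(1 - 2e)^4`). A block of size 1 is a no-op (with warning).
#'
#' @param cfg a [generator_config()].
#' @param size number of loci in the block.
#' @param r2 target median pairwise r-squared.
#' @return the updated `generator_config`.
#' @export
plant_linked_block <- function(cfg, size, r2 = 0.6) {
  stopifnot(inherits(cfg, "generator_config"), r2 > 0, r2 <= 1)
  if (size < 2L) {
    warning("linked block of size ", size, " is a no-op")
    return(cfg)
  }
  cfg$linked_blocks <- c(cfg$linked_blocks,
                         list(list(size = as.integer(size), r2 = r2)))
  cfg
}

# Balding-Nichols draw: frequencies around p with divergence parameter F
bn_draw <- function(p, f) {
  if (f <= 0) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Generate a synthetic RAD genotype dataset
#'
#' See [generator_config()] for the model. Per stack, an ancestral frequency
#' is drawn from the truncated-Beta law; each location receives a
#' Balding-Nichols draw around it with parameter `f_loc`, and each species
#' within each location a further draw with parameter `f_sp`. SNPs within a
#' stack share these stack-level frequencies up to a small jitter. Genotypes
#' are Hardy-Weinberg draws from the cell frequencies; depth is
#' negative-binomial per stack and individual (shared by the stack's SNPs);
#' genotypes are dropped to missing where depth is below `min_call_depth`
#' (their depth zeroed) plus an MCAR component. Planted loci (appended as
#' dedicated single-SNP stacks) overwrite cell frequencies per the truth
#' table; a planted fixed difference is frequency 0 in the focal location and
#' 1 elsewhere, in all species.
#'
#' @param cfg a [generator_config()].
#' @return list (class `synthetic_dataset`) with `genotypes`
#'   ([genotype_matrix()]), `coverage` ([coverage_matrix()]), `groups`
#'   ([sample_groups()]), `truth` (data.frame: `locus_id`, `type`, `level`,
#'   `block`), `seed`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n_sp <- length(cfg$species); n_loc <- length(cfg$locations)
  cells <- expand.grid(species = cfg$species, location = cfg$locations,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_cells <- nrow(cells)
  k <- cfg$n_per_cell
  n_ind <- n_cells * k
  samples <- paste0(rep(cells$species, each = k), "_",
                    rep(cells$location, each = k), "_",
                    rep(seq_len(k), n_cells))
  groups <- sample_groups(samples,
                          rep(cells$species, each = k),
                          rep(cells$location, each = k))

  # --- background stacks ---------------------------------------------------
  n_snps_per_stack <- sample.int(length(cfg$snp_count_probs), cfg$n_stacks,
                                 replace = TRUE, prob = cfg$snp_count_probs)
  stack_of_snp <- rep.int(seq_len(cfg$n_stacks), n_snps_per_stack)
  offset_of_snp <- sequence(n_snps_per_stack) * 7L  # arbitrary in-stack spacing
  S <- length(stack_of_snp)
  lo <- cfg$ancestral_bounds[1L]; hi <- cfg$ancestral_bounds[2L]
  p0_stack <- pmin(pmax(stats::rbeta(cfg$n_stacks, cfg$ancestral_shape[1L],
                                     cfg$ancestral_shape[2L]), lo), hi)
  # stack-level cell frequencies: BN location step then BN species step.
  # The species-step deviations, averaged over the n_sp species pooled within
  # a location, inflate the realized among-location variance by f_sp/n_sp;
  # the location step is compensated so f_loc remains the *realized* pooled
  # among-location divergence.
  f_loc_eff <- max(0, cfg$f_loc - cfg$f_sp / n_sp)
  loc_p <- vapply(seq_len(n_loc), function(l) bn_draw(p0_stack, f_loc_eff),
                  numeric(cfg$n_stacks))                  # stacks x locations
  cell_p_stack <- matrix(0, cfg$n_stacks, n_cells)
  for (ci in seq_len(n_cells)) {
    l <- match(cells$location[ci], cfg$locations)
    cell_p_stack[, ci] <- bn_draw(loc_p[, l], cfg$f_sp)
  }
  jitter <- stats::rnorm(S, 0, cfg$snp_jitter_sd)
  cell_p <- cell_p_stack[stack_of_snp, , drop = FALSE] + jitter
  cell_p <- pmin(pmax(cell_p, 0), 1)                       # SNPs x cells

  dos <- matrix(0L, nrow = S, ncol = n_ind)
  for (ci in seq_len(n_cells)) {
    cols <- ((ci - 1L) * k + 1L):(ci * k)
    dos[, cols] <- matrix(stats::rbinom(S * k, 2L, rep(cell_p[, ci], k)),
                          nrow = S)
  }
  loci <- data.frame(stack_id = stack_of_snp, snp_offset = offset_of_snp,
                     ref = "A", alt = "C", stringsAsFactors = FALSE)
  truth <- data.frame(locus_id = character(0), type = character(0),
                      level = character(0), block = integer(0),
                      stringsAsFactors = FALSE)

  next_stack <- cfg$n_stacks
  # --- planted divergent loci ---------------------------------------------
  if (!is.null(cfg$planted) && nrow(cfg$planted) > 0L) {
    for (i in seq_len(nrow(cfg$planted))) {
      pl <- cfg$planted[i, ]
      next_stack <- next_stack + 1L
      if (pl$type == "fixed_difference") {
        freq <- ifelse(cells$location == pl$level, 0, 1)
      } else if (pl$type == "location_divergent") {
        freq <- ifelse(cells$location == pl$level, pl$p_focal, pl$p_other)
      } else {
        freq <- ifelse(cells$species == pl$level, pl$p_focal, pl$p_other)
      }
      row <- integer(n_ind)
      for (ci in seq_len(n_cells)) {
        cols <- ((ci - 1L) * k + 1L):(ci * k)
        row[cols] <- stats::rbinom(k, 2L, freq[ci])
      }
      dos <- rbind(dos, row)
      loci <- rbind(loci, data.frame(stack_id = next_stack, snp_offset = 7L,
                                     ref = "A", alt = "C"))
      truth <- rbind(truth, data.frame(
        locus_id = paste(next_stack, 7L, sep = "_"),
        type = pl$type, level = pl$level, block = NA_integer_))
    }
  }
  # --- planted linked blocks ----------------------------------------------
  if (length(cfg$linked_blocks) > 0L) {
    for (b in seq_along(cfg$linked_blocks)) {
      blk <- cfg$linked_blocks[[b]]
      e <- (1 - blk$r2^(1 / 4)) / 2
      h1 <- stats::rbinom(n_ind, 1L, 0.5)   # latent haplotype copies
      h2 <- stats::rbinom(n_ind, 1L, 0.5)
      block_rows <- matrix(0L, blk$size, n_ind)
      for (j in seq_len(blk$size)) {
        a1 <- abs(h1 - stats::rbinom(n_ind, 1L, e))
        a2 <- abs(h2 - stats::rbinom(n_ind, 1L, e))
        block_rows[j, ] <- a1 + a2
        next_stack <- next_stack + 1L
        loci <- rbind(loci, data.frame(stack_id = next_stack, snp_offset = 7L,
                                       ref = "A", alt = "C"))
        truth <- rbind(truth, data.frame(
          locus_id = paste(next_stack, 7L, sep = "_"),
          type = "linked_block", level = NA_character_, block = b))
      }
      dos <- rbind(dos, block_rows)
    }
  }

  # --- depth and missingness ----------------------------------------------
  S_all <- nrow(dos)
  n_stacks_all <- next_stack
  stack_all <- loci$stack_id
  depth_stack <- matrix(stats::rnbinom(n_stacks_all * n_ind,
                                       size = cfg$depth_size,
                                       mu = cfg$depth_mean),
                        nrow = n_stacks_all)
  depth <- depth_stack[stack_all, , drop = FALSE]
  miss <- depth < cfg$min_call_depth
  if (cfg$mcar_rate > 0) {
    miss <- miss | matrix(stats::runif(S_all * n_ind) < cfg$mcar_rate,
                          nrow = S_all)
  }
  dos[miss] <- NA_integer_
  depth[miss] <- 0L

  g <- genotype_matrix(dos, loci, samples)
  structure(list(genotypes = g,
                 coverage = coverage_matrix(depth, g),
                 groups = groups, truth = truth, seed = cfg$seed),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset (seed %d): %d loci x %d individuals, %d planted loci\n",
              x$seed, n_loci(x$genotypes), n_samples(x$genotypes),
              nrow(x$truth)))
  invisible(x)
}
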