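# shared fixture builders

# genotype matrix from a dosage matrix; default one stack per locus
make_g <- function(dos, stack_id = seq_len(nrow(dos)),
                   snp_offset = rep(0L, nrow(dos)),
                   samples = paste0("s", seq_len(ncol(dos)))) {
  genotype_matrix(dos,
                  data.frame(stack_id = stack_id, snp_offset = snp_offset,
                             ref = "A", alt = "C"),
                  samples)
}

# 3 species x 3 locations x k metadata for samples in cell-major order
make_groups_3x3 <- function(k = 14L) {
  cells <- expand.grid(species = c("spA", "spB", "spC"),
                       location = c("L1", "L2", "L3"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sample_groups(paste0(rep(cells$species, each = k), "_",
                       rep(cells$location, each = k), "_", seq_len(k)),
                rep(cells$species, each = k),
                rep(cells$location, each = k))
}

# constructed LD matrix: blocks at r2 `within` over background `between`,
# plus sampling-like jitter (exact ties would collapse each block into a
# single all-singleton merge and leave the lambda distribution degenerate);
# locus ids "L<i>"
make_ld_blocks <- function(n, blocks, within = 0.9, between = 0.05,
                           jitter = 0.02, seed = 99L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ld <- matrix(0, n, n)
  ld[upper.tri(ld)] <- between + rnorm(n * (n - 1) / 2, 0, jitter)
  for (b in blocks) {
    b <- sort(b)
    idx <- which(upper.tri(diag(length(b))), arr.ind = TRUE)
    ld[cbind(b[idx[, 1L]], b[idx[, 2L]])] <-
      within + rnorm(nrow(idx), 0, jitter)
  }
  ld <- pmin(pmax(ld, 0), 1)
  ld <- ld + t(ld)
  diag(ld) <- 1
  dimnames(ld) <- list(paste0("L", seq_len(n)), paste0("L", seq_len(n)))
  class(ld) <- c("ld_matrix", class(ld))
  ld
}
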