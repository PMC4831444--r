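# Independent Weir-Cockerham oracle: the classic two-level ANOVA on allele
# indicators, written as mean squares (SSG/SSI/SSP with their degrees of
# freedom) rather than the direct variance-component formulas the package
# uses. Scalar, loop-based, first-principles.
oracle_components <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[vapply(groups, length, 1L) >= 2L]
  r <- length(groups)
  if (r < 2L) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  n <- vapply(groups, length, 1L)
  ntot <- sum(n)
  p_i <- vapply(groups, function(g) mean(g) / 2, numeric(1L))
  pbar <- sum(n * p_i) / ntot
  # allele-level sums of squares: 2 alleles per individual, y = allele is alt
  SSG <- sum(vapply(groups, function(g) sum(g == 1L) / 2, numeric(1L)))
  SSI <- 2 * sum(unlist(mapply(function(g, p) (g / 2 - p)^2, groups, p_i,
                               SIMPLIFY = FALSE)))
  SSP <- 2 * sum(n * (p_i - pbar)^2)
  MSG <- SSG / ntot          # df: one per individual (2 alleles - 1)
  MSI <- SSI / (ntot - r)
  MSP <- SSP / (r - 1)
  nc <- (ntot - sum(n^2) / ntot) / (r - 1)
  c(a = (MSP - MSI) / (2 * nc),
    b = (MSI - MSG) / 2,
    c = MSG)
}

oracle_theta <- function(groups) {
  comp <- oracle_components(groups)
  s <- sum(comp)
  if (is.na(s) || s == 0) return(NA_real_)
  comp[["a"]] / s
}

# multilocus ratio-of-sums over a list of per-locus group-dosage lists
oracle_multilocus <- function(loci) {
  comps <- lapply(loci, oracle_components)
  a <- vapply(comps, `[[`, numeric(1L), "a")
  tot <- vapply(comps, sum, numeric(1L))
  ok <- !is.na(tot) & tot != 0
  sum(a[ok]) / sum(tot[ok])
}
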