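# SNP / individual filters. All filters are pure (return a new
# genotype_matrix) and idempotent. The default pipeline order is
# coverage -> rare-allele -> heterozygosity -> first-SNP-per-stack.

# per-stack mean depth across the stack's SNPs, one row per stack
stack_depth <- function(g, coverage) {
  sid <- g$loci$stack_id
  depth <- coverage$depth
  agg <- rowsum(depth, sid, reorder = TRUE)
  counts <- as.vector(table(sid)[rownames(agg)])
  agg / counts
}

#' Retain stacks by per-group coverage support
#'
#' A stack is retained iff at least `min_groups` grouping units contain at
#' least `min_inds` individuals whose per-stack mean depth is `>= min_depth`
#' (boundary inclusive). Filtering operates at the stack level: a stack passes
#' or fails as a unit and all its SNPs follow. The study's two standard
#' settings are depth 10 in >= 15 individuals per location in >= 2 locations
#' (samples pooled by location) and depth 10 in >= 5 individuals per
#' species-x-location cell in >= 7 cells (samples considered individually).
#'
#' @param g a [genotype_matrix()].
#' @param coverage the aligned [coverage_matrix()].
#' @param groups a [sample_groups()].
#' @param min_depth minimum per-stack mean depth for an individual to count.
#' @param min_inds minimum qualifying individuals per grouping unit.
#' @param min_groups minimum qualifying grouping units.
#' @param group_by grouping factor: `"location"` or `"cell"`
#'   (species x location).
#' @return the filtered `genotype_matrix`.
#' @export
filter_loci_by_coverage <- function(g, coverage, groups, min_depth = 10,
                                    min_inds = 15, min_groups = 2,
                                    group_by = c("location", "cell")) {
  group_by <- match.arg(group_by)
  stopifnot(min_depth > 0, min_inds > 0, min_groups > 0)
  labels <- group_labels(g, groups, group_by)
  sd <- stack_depth(g, coverage)                   # stacks x individuals
  qual <- sd >= min_depth
  per_group <- rowsum(t(qual) + 0, labels)         # groups x stacks
  n_ok_groups <- colSums(per_group >= min_inds)
  keep_stacks <- as.integer(rownames(sd))[n_ok_groups >= min_groups]
  subset_loci(g, g$loci$stack_id %in% keep_stacks)
}

#' Remove loci whose minor allele is rare in every grouping unit
#'
#' A locus is removed when its (globally) minor allele is carried by at most
#' one individual in every grouping unit — the study's "present in only one
#' individual per location" rule. Monomorphic loci have no minor allele and
#' are retained here (they are handled downstream by the F_st machinery).
#'
#' @inheritParams filter_loci_by_coverage
#' @param group_by grouping factor, default `"location"`.
#' @return the filtered `genotype_matrix`.
#' @export
filter_rare_alleles <- function(g, groups,
                                group_by = c("location", "species", "cell")) {
  group_by <- match.arg(group_by)
  labels <- group_labels(g, groups, group_by)
  dos <- g$dosages
  alt_count <- rowSums(dos, na.rm = TRUE)
  called <- rowSums(!is.na(dos))
  minor_is_alt <- alt_count <= called  # alt freq <= 0.5 (ties -> alt)
  mono <- alt_count == 0L | alt_count == 2L * called
  carrier <- matrix(FALSE, nrow(dos), ncol(dos))
  ia <- which(minor_is_alt)
  carrier[ia, ] <- !is.na(dos[ia, , drop = FALSE]) & dos[ia, , drop = FALSE] >= 1L
  ib <- which(!minor_is_alt)
  carrier[ib, ] <- !is.na(dos[ib, , drop = FALSE]) & dos[ib, , drop = FALSE] <= 1L
  per_group <- t(rowsum(t(carrier) + 0, labels))   # loci x groups
  rare_everywhere <- apply(per_group <= 1, 1L, all)
  subset_loci(g, !(rare_everywhere & !mono))
}

#' Remove loci with excess observed heterozygosity
#'
#' Drops loci whose heterozygote fraction over non-missing calls strictly
#' exceeds `max_het` (default 0.5, the preparation rule for LD-network
#' analysis). All-missing loci, whose heterozygosity is undefined, are removed
#' with a warning.
#'
#' @inheritParams filter_loci_by_coverage
#' @param max_het maximum tolerated heterozygote fraction.
#' @return the filtered `genotype_matrix`.
#' @export
filter_heterozygosity <- function(g, max_het = 0.5) {
  dos <- g$dosages
  called <- rowSums(!is.na(dos))
  het <- rowSums(dos == 1L, na.rm = TRUE) / called
  all_missing <- called == 0L
  if (any(all_missing)) {
    warning(sum(all_missing), " all-missing locus/loci removed (heterozygosity undefined)")
  }
  subset_loci(g, !all_missing & het <= max_het)
}

#' Keep a single SNP per stack (the first one)
#'
#' Retains, for every stack, the SNP with the smallest offset. Used wherever
#' within-stack SNPs would contribute redundant, tightly linked signal
#' (clustering, LD networks).
#'
#' @inheritParams filter_loci_by_coverage
#' @return the filtered `genotype_matrix` with unique `stack_id`s.
#' @export
select_first_snp_per_stack <- function(g) {
  ord <- order(g$loci$stack_id, g$loci$snp_offset)
  first <- ord[!duplicated(g$loci$stack_id[ord])]
  subset_loci(g, sort(first))
}

#' Drop individuals with too much missing data
#'
#' Individuals whose missing-call fraction strictly exceeds `max_missing`
#' are removed; loci are untouched. The study applies this (at 20%) before
#' tree building, where high-missingness individuals erode bootstrap support.
#'
#' @inheritParams filter_loci_by_coverage
#' @param max_missing maximum tolerated missing fraction per individual.
#' @return the filtered `genotype_matrix`.
#' @export
filter_individuals_by_missingness <- function(g, max_missing = 0.2) {
  frac <- colMeans(is.na(g$dosages))
  subset_samples(g, frac <= max_missing)
}
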