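#' Diploid biallelic genotype matrix
#'
#' The central exchange object of the package: a loci-by-individuals matrix of
#' alternate-allele dosages (0, 1, 2) with `NA` marking missing calls, plus a
#' per-locus annotation table and an ordered sample index. RAD loci are
#' identified by their stack (the de novo assembled read pile) and the 0-based
#' offset of the SNP within the stack; a stack may carry several SNPs.
#'
#' @param dosages integer matrix, loci in rows, individuals in columns; every
#'   non-missing entry must be 0, 1 or 2. Missing calls are `NA`; a missing
#'   call is never conflated with dosage 0.
#' @param loci data.frame with one row per locus and columns `stack_id`
#'   (integer), `snp_offset` (0-based integer position of the SNP within its
#'   stack) and `ref`, `alt` (distinct single-character alleles).
#'   `(stack_id, snp_offset)` pairs must be unique.
#' @param samples character vector of unique sample identifiers, one per
#'   column of `dosages`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `loci` (with a derived `locus_id` column `"<stack>_<offset>"`)
#'   and `samples`.
#' @export
genotype_matrix <- function(dosages, loci, samples) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (!is.data.frame(loci)) stop("`loci` must be a data.frame")
  needed <- c("stack_id", "snp_offset", "ref", "alt")
  missing_cols <- setdiff(needed, names(loci))
  if (length(missing_cols) > 0L) {
    stop("`loci` lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  samples <- as.character(samples)
  if (nrow(dosages) != nrow(loci)) {
    stop("row count of `dosages` (", nrow(dosages),
         ") does not match `loci` (", nrow(loci), ")")
  }
  if (ncol(dosages) != length(samples)) {
    stop("column count of `dosages` (", ncol(dosages),
         ") does not match `samples` (", length(samples), ")")
  }
  if (anyDuplicated(samples)) stop("sample identifiers must be unique")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) > 0L && (min(bad) < 0L || max(bad) > 2L)) {
    stop("non-missing dosages must lie in {0, 1, 2}")
  }
  loci$stack_id <- as.integer(loci$stack_id)
  loci$snp_offset <- as.integer(loci$snp_offset)
  if (any(loci$ref == loci$alt)) stop("ref and alt alleles must differ")
  loci$locus_id <- paste(loci$stack_id, loci$snp_offset, sep = "_")
  if (anyDuplicated(loci$locus_id)) {
    stop("(stack_id, snp_offset) pairs must be unique")
  }
  rownames(dosages) <- loci$locus_id
  colnames(dosages) <- samples
  structure(list(dosages = dosages, loci = loci, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$dosages))
  cat(sprintf("genotype_matrix: %d loci x %d individuals (%d stacks, %.1f%% missing)\n",
              n_loci(x), n_samples(x), length(unique(x$loci$stack_id)),
              100 * miss))
  invisible(x)
}

#' Number of loci / samples in a genotype matrix
#' @param g a `genotype_matrix`
#' @return integer count.
#' @export
n_loci <- function(g) nrow(g$dosages)

#' @rdname n_loci
#' @export
n_samples <- function(g) ncol(g$dosages)

#' @rdname n_loci
#' @export
locus_ids <- function(g) g$loci$locus_id

#' Subset a genotype matrix by loci or samples
#'
#' @param g a `genotype_matrix`
#' @param idx logical, integer or character (locus_id / sample id) index.
#' @return a `genotype_matrix` restricted to the selected loci or samples.
#' @export
subset_loci <- function(g, idx) {
  if (is.character(idx)) idx <- match(idx, g$loci$locus_id)
  keep_d <- g$dosages[idx, , drop = FALSE]
  keep_l <- g$loci[idx, , drop = FALSE]
  rownames(keep_l) <- NULL
  genotype_matrix(keep_d, keep_l[setdiff(names(keep_l), "locus_id")],
                  g$samples)
}

#' @rdname subset_loci
#' @export
subset_samples <- function(g, idx) {
  if (is.character(idx)) idx <- match(idx, g$samples)
  genotype_matrix(g$dosages[, idx, drop = FALSE],
                  g$loci[setdiff(names(g$loci), "locus_id")],
                  g$samples[idx])
}

#' Per-genotype read-depth matrix
#'
#' Read depths aligned cell-by-cell to a [genotype_matrix()]. Depth is 0
#' wherever the genotype call is missing, by construction: a call that was
#' dropped (or never made) carries no usable coverage.
#'
#' @param depth non-negative integer matrix of the same shape as
#'   `g$dosages`.
#' @param g the `genotype_matrix` the depths belong to.
#' @return An object of class `coverage_matrix` (list with `depth`).
#' @export
coverage_matrix <- function(depth, g) {
  depth <- as.matrix(depth)
  storage.mode(depth) <- "integer"
  if (!identical(dim(depth), dim(g$dosages))) {
    stop("depth matrix shape does not match the genotype matrix")
  }
  if (any(depth < 0L, na.rm = TRUE) || anyNA(depth)) {
    stop("depths must be non-negative integers (no NA)")
  }
  if (any(depth[is.na(g$dosages)] != 0L)) {
    stop("depth must be 0 wherever the genotype is missing")
  }
  dimnames(depth) <- dimnames(g$dosages)
  structure(list(depth = depth), class = "coverage_matrix")
}

#' Two-factor sample metadata (species x location)
#'
#' Maps every sample to a species label and a location label. Labels are
#' opaque strings; the 3 species x 3 locations x 14 individuals design of the
#' motivating study is a convention, not a constraint.
#'
#' @param sample character vector of sample identifiers.
#' @param species,location character vectors of the same length.
#' @return An object of class `sample_groups`: a data.frame with columns
#'   `sample`, `species`, `location` and a derived `cell`
#'   (`"<species>.<location>"`).
#' @export
sample_groups <- function(sample, species, location) {
  sample <- as.character(sample)
  species <- as.character(species)
  location <- as.character(location)
  if (length(species) != length(sample) || length(location) != length(sample)) {
    stop("sample, species and location must have equal lengths")
  }
  if (anyDuplicated(sample)) stop("duplicated sample identifiers")
  out <- data.frame(sample = sample, species = species, location = location,
                    cell = paste(species, location, sep = "."),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_groups", "data.frame")
  out
}

#' Grouping labels for the samples of a genotype matrix
#'
#' Returns the chosen factor of the sample metadata in the genotype matrix's
#' sample order — the form [wc_fst()] and friends consume. Errors if any
#' sample lacks metadata.
#'
#' @param g a [genotype_matrix()].
#' @param groups a [sample_groups()].
#' @param by `"location"`, `"species"` or `"cell"` (species x location).
#' @return character vector of labels, one per sample of `g`.
#' @export
group_labels <- function(g, groups, by = c("location", "species", "cell")) {
  by <- match.arg(by)
  i <- match(g$samples, groups$sample)
  if (anyNA(i)) {
    stop("samples without metadata: ",
         paste(utils::head(g$samples[is.na(i)], 5L), collapse = ", "))
  }
  groups[[by]][i]
}
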