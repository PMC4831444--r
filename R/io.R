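#' Read biallelic SNP genotypes and depths from a VCF file
#'
#' Decodes GT into alt-allele dosages and FORMAT/DP into a depth matrix.
#' Multi-allelic records are rejected (with a reported count): the pipeline is
#' defined for biallelic RAD SNPs only. VCF positions are 1-based; internally
#' the SNP offset within its stack is stored 0-based (`snp_offset = POS - 1`).
#' The CHROM field is taken as the stack identifier (integer CHROMs are used
#' as-is, other strings are mapped to a stable integer index).
#'
#' @param path path to a VCF 4.x file (plain text or bgzipped).
#' @param default_depth depth assigned to a called genotype when FORMAT/DP is
#'   absent from the file. The default (10) passes the study's standard
#'   coverage threshold so that depth-free VCFs survive the coverage filter
#'   unchanged; a message is emitted when the default is used.
#' @return list with elements `genotypes` ([genotype_matrix()]),
#'   `coverage` ([coverage_matrix()]) and `n_excluded_multiallelic`.
#' @export
read_vcf <- function(path, default_depth = 10L) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e)))
  if (ncol(v@gt) <= 1L) stop("VCF '", path, "' contains zero samples")
  fix <- v@fix
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  n_multi <- sum(multi)
  if (n_multi > 0L) {
    message(n_multi, " multi-allelic record(s) excluded")
    v <- v[!multi, ]
    fix <- v@fix
  }
  if (nrow(fix) == 0L) stop("no biallelic records in '", path, "'")

  gt <- vcfR::extract.gt(v, element = "GT")
  # tolerate phased or unphased separators; count '1' alleles
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dos[clean == "0/0"] <- 0L
  dos[clean == "0/1" | clean == "1/0"] <- 1L
  dos[clean == "1/1"] <- 2L
  # anything else (./., .), or NA from extract.gt, stays missing

  chrom <- fix[, "CHROM"]
  stack_id <- suppressWarnings(as.integer(chrom))
  if (anyNA(stack_id)) stack_id <- as.integer(factor(chrom, levels = unique(chrom)))
  loci <- data.frame(stack_id = stack_id,
                     snp_offset = as.integer(fix[, "POS"]) - 1L,
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  g <- genotype_matrix(dos, loci, colnames(gt))

  fmt_keys <- unique(unlist(strsplit(v@gt[, 1L], ":", fixed = TRUE)))
  if ("DP" %in% fmt_keys) {
    dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    dp[is.na(dp)] <- 0
    dp <- round(dp)
  } else {
    message("FORMAT/DP absent: assigning depth ", default_depth,
            " to every called genotype")
    dp <- matrix(0, nrow = n_loci(g), ncol = n_samples(g))
    dp[!is.na(g$dosages)] <- default_depth
  }
  dp[is.na(g$dosages)] <- 0
  list(genotypes = g,
       coverage = coverage_matrix(dp, g),
       n_excluded_multiallelic = n_multi)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCF 4.2 file with GT and DP fields. The stack identifier is written
#' as CHROM and the SNP offset converted back to a 1-based POS
#' (`POS = snp_offset + 1`). `read_vcf(write_vcf(g))` is the identity on
#' dosages and missingness.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path.
#' @param coverage optional [coverage_matrix()]; without it, called genotypes
#'   are written with DP 10 and missing ones with DP 0.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path, coverage = NULL) {
  dp <- if (is.null(coverage)) {
    d <- matrix(10L, n_loci(g), n_samples(g))
    d[is.na(g$dosages)] <- 0L
    d
  } else coverage$depth
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  dos <- g$dosages
  cells <- matrix("./.", nrow = nrow(dos), ncol = ncol(dos))
  ok <- !is.na(dos)
  cells[ok] <- gt_code[as.character(dos[ok])]
  cells[] <- paste(cells, dp, sep = ":")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", g$samples), collapse = "\t"))
  body <- paste(g$loci$stack_id, g$loci$snp_offset + 1L, g$loci$locus_id,
                g$loci$ref, g$loci$alt, ".", "PASS", ".", "GT:DP",
                apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write genotypes in Genepop format
#'
#' One `Pop` block per grouping unit, two-digit allele codes (ref = 01,
#' alt = 02), missing genotype = `0000`. This mirrors the exchange format the
#' classical multilocus F_st tools consume.
#'
#' @param g a [genotype_matrix()]; must contain at least one locus.
#' @param groups a [sample_groups()] covering all samples of `g`.
#' @param path output file path.
#' @param by grouping unit defining the POP blocks: `"cell"`
#'   (species x location, default), `"location"` or `"species"`.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(g, groups, path, by = c("cell", "location", "species")) {
  by <- match.arg(by)
  if (n_loci(g) == 0L) stop("refusing to write a Genepop file with zero loci")
  labels <- group_labels(g, groups, by)
  code <- c(`0` = "0101", `1` = "0102", `2` = "0202")
  dos <- g$dosages
  cells <- matrix("0000", nrow = nrow(dos), ncol = ncol(dos))
  ok <- !is.na(dos)
  cells[ok] <- code[as.character(dos[ok])]
  lines <- c(paste0("radscan genotypes (", n_loci(g), " loci)"),
             locus_ids(g))
  for (lev in unique(labels)) {
    lines <- c(lines, "Pop")
    for (j in which(labels == lev)) {
      lines <- c(lines, paste0(g$samples[j], " ,  ",
                               paste(cells[, j], collapse = " ")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# Minimal Genepop reader (loci listed one per line), used for round-trip
# checks of write_genepop. Returns genotypes plus the POP index per sample.
read_genepop <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("not a Genepop file: too short")
  pop_at <- which(toupper(trimws(lines)) == "POP")
  if (length(pop_at) == 0L) stop("not a Genepop file: no Pop line")
  ids <- trimws(lines[2:(pop_at[1L] - 1L)])
  samples <- character(0)
  pop <- integer(0)
  cols <- list()
  block <- 0L
  for (ln in lines[(pop_at[1L]):length(lines)]) {
    if (toupper(trimws(ln)) == "POP") { block <- block + 1L; next }
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(ln, ",", fixed = TRUE)[[1L]]
    nm <- trimws(parts[1L])
    gts <- strsplit(trimws(parts[2L]), "[ \t]+")[[1L]]
    dos <- vapply(gts, function(s) {
      if (s == "0000") return(NA_integer_)
      a <- c(substr(s, 1L, 2L), substr(s, 3L, 4L))
      sum(a == "02")
    }, integer(1L), USE.NAMES = FALSE)
    samples <- c(samples, nm)
    pop <- c(pop, block)
    cols[[length(cols) + 1L]] <- dos
  }
  dosages <- do.call(cbind, cols)
  sid <- as.integer(sub("_.*$", "", ids))
  off <- as.integer(sub("^.*_", "", ids))
  if (anyNA(sid) || anyNA(off)) { sid <- seq_along(ids); off <- rep(0L, length(ids)) }
  g <- genotype_matrix(dosages,
                       data.frame(stack_id = sid, snp_offset = off,
                                  ref = "A", alt = "C"),
                       samples)
  list(genotypes = g, pop = pop)
}

#' Read / write tabular genotype, depth and metadata files
#'
#' Plain-TSV loaders for pipelines that do not start from VCF: a genotype
#' matrix (rows = loci with `stack_id`, `snp_offset`, `ref`, `alt` columns
#' followed by one column per sample; dosage values 0/1/2, missing = `NA`),
#' an aligned depth matrix with the same layout, and a sample metadata table
#' (`sample`, `species`, `location`).
#'
#' @param path input/output TSV path.
#' @return `read_genotype_tsv`: a [genotype_matrix()]. `read_metadata_tsv`:
#'   a [sample_groups()].
#' @export
read_genotype_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("stack_id", "snp_offset", "ref", "alt")
  if (!all(meta_cols %in% names(tab))) {
    stop("genotype TSV must carry columns ", paste(meta_cols, collapse = ", "))
  }
  samples <- setdiff(names(tab), meta_cols)
  genotype_matrix(as.matrix(tab[samples]), tab[meta_cols], samples)
}

#' @rdname read_genotype_tsv
#' @param g a [genotype_matrix()] to serialize.
#' @export
write_genotype_tsv <- function(g, path) {
  tab <- cbind(g$loci[c("stack_id", "snp_offset", "ref", "alt")],
               as.data.frame(g$dosages, check.names = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_genotype_tsv
#' @export
read_metadata_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  sample_groups(tab$sample, tab$species, tab$location)
}
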