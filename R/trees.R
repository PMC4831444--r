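#' Allele-sharing distance between individuals
#'
#' `d(i, j) = 1 - mean over loci of the shared-allele proportion`, computed
#' over loci non-missing in both individuals. For dosages the shared-allele
#' proportion at a locus is `1 - |g_i - g_j| / 2`, so identical genotypes
#' contribute 0 distance and opposite homozygotes contribute 1.
#'
#' @param g a [genotype_matrix()].
#' @return symmetric numeric matrix with zero diagonal, labelled by sample.
#' @export
allele_sharing_distance <- function(g) {
  D <- g$dosages
  N <- n_samples(g)
  out <- matrix(0, N, N, dimnames = list(g$samples, g$samples))
  for (i in seq_len(N - 1L)) {
    gi <- D[, i]
    for (j in (i + 1L):N) {
      diff <- abs(gi - D[, j]) / 2
      d <- mean(diff, na.rm = TRUE)
      if (is.nan(d)) d <- NA_real_   # no shared loci
      out[i, j] <- out[j, i] <- d
    }
  }
  out
}

# Clamp negative NJ branch lengths to zero, moving the deficit onto the
# sibling edge sharing the child node (standard post-processing).
clamp_negative_edges <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0L) break
    e <- neg[1L]
    parent <- tree$edge[e, 1L]
    sibs <- setdiff(which(tree$edge[, 1L] == parent), e)
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sibs) > 0L) {
      tree$edge.length[sibs[1L]] <- max(0, tree$edge.length[sibs[1L]] + deficit)
    }
  }
  tree
}

#' Neighbor-joining tree with locus-resampling bootstrap
#'
#' Builds a neighbor-joining tree from an individual distance matrix and
#' attaches bootstrap support computed by resampling loci with replacement:
#' each replicate redraws loci, recomputes the allele-sharing distance and the
#' NJ tree, and support is the percentage of replicates containing each
#' internal bipartition. Negative branch lengths are clamped to zero with the
#' deficit absorbed by a sibling edge.
#'
#' @param d symmetric distance matrix (e.g. [allele_sharing_distance()]).
#' @param g the [genotype_matrix()] the distances came from; required when
#'   `bootstrap > 0`.
#' @param bootstrap number of bootstrap replicates (0 to skip).
#' @return An object of class `distance_tree`: list with `tree` (an
#'   [ape::nj()] `phylo`), `support` (per internal node, percent, or `NULL`)
#'   and `newick` (serialized tree with support as node labels).
#' @export
nj_tree <- function(d, g = NULL, bootstrap = 0L) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 leaves for a tree")
  tree <- clamp_negative_edges(ape::nj(stats::as.dist(d)))
  support <- NULL
  if (bootstrap > 0L) {
    if (is.null(g)) stop("`g` is required for bootstrapping")
    boots <- vector("list", bootstrap)
    for (b in seq_len(bootstrap)) {
      idx <- sample.int(n_loci(g), replace = TRUE)
      db <- allele_sharing_distance_raw(g$dosages[idx, , drop = FALSE], g$samples)
      boots[[b]] <- ape::nj(stats::as.dist(db))
    }
    counts <- ape::prop.clades(tree, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    support <- round(100 * counts / bootstrap)
    tree$node.label <- support
  }
  structure(list(tree = tree, support = support,
                 newick = ape::write.tree(tree)),
            class = "distance_tree")
}

# distance on a bare dosage matrix (bootstrap fast path)
allele_sharing_distance_raw <- function(D, samples) {
  N <- ncol(D)
  out <- matrix(0, N, N, dimnames = list(samples, samples))
  for (i in seq_len(N - 1L)) {
    gi <- D[, i]
    for (j in (i + 1L):N) {
      d <- mean(abs(gi - D[, j]) / 2, na.rm = TRUE)
      if (is.nan(d)) d <- 0
      out[i, j] <- out[j, i] <- d
    }
  }
  out
}

#' @export
print.distance_tree <- function(x, ...) {
  cat("distance_tree:", length(x$tree$tip.label), "leaves")
  if (!is.null(x$support)) cat(";", length(x$support), "bootstrap-supported nodes")
  cat("\n")
  invisible(x)
}

#' PCA + k-means clustering of individuals
#'
#' Mean-imputes missing dosages per locus, centers, projects individuals onto
#' the top principal components and runs k-means for `k = 1..k_max`. The
#' selected `k` maximizes the mean silhouette width; when even the best
#' multi-cluster solution has mean silhouette below `sil_threshold`, `k = 1`
#' (no structure) is reported. Deterministic for a given `seed`. Used to
#' exercise the percentile-subset contrast that the study ran with an
#' admixture-MCMC clustering tool.
#'
#' @param g a [genotype_matrix()] (at least 3 individuals).
#' @param k_max maximum number of clusters to consider.
#' @param n_pc number of principal components retained.
#' @param sil_threshold minimum mean silhouette width for accepting `k > 1`.
#' @param seed integer seed for the k-means restarts.
#' @return An object of class `cluster_result`: list with `k`, `assignment`
#'   (named integer vector), `scores` (mean silhouette per candidate `k`),
#'   `pcs` (individual x component score matrix).
#' @export
pca_cluster <- function(g, k_max = 6L, n_pc = 10L, sil_threshold = 0.25,
                        seed = 1L) {
  if (n_samples(g) < 3L) stop("need at least 3 individuals to cluster")
  X <- t(g$dosages)
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  na <- which(is.na(X), arr.ind = TRUE)
  if (nrow(na) > 0L) X[na] <- mu[na[, 2L]]
  X <- scale(X, center = TRUE, scale = FALSE)
  keep <- apply(X, 2L, function(v) any(v != 0))
  X <- X[, keep, drop = FALSE]
  n_pc <- min(n_pc, nrow(X) - 1L, ncol(X))
  pcs <- stats::prcomp(X, rank. = n_pc)$x
  k_max <- min(k_max, nrow(pcs) - 1L)
  scores <- stats::setNames(rep(NA_real_, k_max), paste0("k", seq_len(k_max)))
  fits <- vector("list", k_max)
  dmat <- stats::dist(pcs)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  for (k in seq_len(k_max)) {
    if (k == 1L) { fits[[k]] <- rep(1L, nrow(pcs)); next }
    km <- stats::kmeans(pcs, centers = k, nstart = 25L, iter.max = 50L)
    fits[[k]] <- km$cluster
    scores[k] <- mean(cluster::silhouette(km$cluster, dmat)[, "sil_width"])
  }
  best <- if (all(is.na(scores[-1L])) || max(scores[-1L], na.rm = TRUE) < sil_threshold) {
    1L
  } else {
    as.integer(which.max(scores))
  }
  structure(list(k = best,
                 assignment = stats::setNames(fits[[best]], g$samples),
                 scores = scores, pcs = pcs),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result: k =", x$k, "over", length(x$assignment), "individuals\n")
  invisible(x)
}
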