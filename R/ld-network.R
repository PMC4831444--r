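#' Pairwise LD (r-squared) matrix among loci
#'
#' Squared composite (Burrows-type) genotype correlation: the squared Pearson
#' correlation of dosage vectors over pairwise-complete individuals — the
#' standard unphased surrogate for haplotype r-squared in RAD genotypes.
#' Pairs sharing fewer than `min_shared` of the individuals are set to
#' undefined (`NA`). Input is expected pre-filtered (no rare alleles,
#' heterozygosity <= 0.5, one SNP per stack); the computation is quadratic in
#' the locus count, so inputs much beyond ~10,000 loci are impractical.
#'
#' @param g a [genotype_matrix()].
#' @param min_shared minimum fraction of individuals a pair must share.
#' @return An object of class `ld_matrix`: symmetric matrix in `[0, 1]` with
#'   unit diagonal, labelled by locus id.
#' @export
ld_r2_matrix <- function(g, min_shared = 0.8) {
  X <- t(g$dosages)
  r <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))^2
  shared <- crossprod(!is.na(X))
  r[shared < ceiling(min_shared * n_samples(g))] <- NA_real_
  diag(r) <- 1
  dimnames(r) <- list(locus_ids(g), locus_ids(g))
  class(r) <- c("ld_matrix", class(r))
  r
}

# median r2 over all defined pairs within a member set
median_within <- function(ld, members) {
  if (length(members) < 2L) return(NA_real_)
  v <- ld[members, members][upper.tri(diag(length(members)))]
  stats::median(v, na.rm = TRUE)
}

# edges (pairs) within members with r2 >= threshold
edge_count <- function(ld, members, threshold) {
  if (length(members) < 2L) return(0L)
  v <- ld[members, members][upper.tri(diag(length(members)))]
  sum(v >= threshold, na.rm = TRUE)
}

#' Threshold-descending LD merger tree
#'
#' Sweeps the LD threshold from 1 down to 0 on a fixed grid; at each
#' threshold, loci joined by an edge (`r^2 >= threshold`) form single-linkage
#' clusters (connected components). Every merging event — two or more
#' existing clusters fusing at a threshold — creates a new cluster node, so
#' the history is a forest whose member sets nest and whose merge thresholds
#' are non-increasing root-ward.
#'
#' @param ld an [ld_r2_matrix()]; `NA` entries never form edges.
#' @param grid_step threshold decrement per sweep step (default 0.01).
#' @return An object of class `ld_cluster_tree`: list with `nodes` (list of
#'   cluster records: `id`, `members` (locus indices), `formed_at`,
#'   `constituents` (child node ids), `n_edges` edges within the node at its
#'   formation threshold), `n_loci`, `ld`, `grid_step`. Leaves are the
#'   singleton clusters `1..n_loci`.
#' @export
build_ld_tree <- function(ld, grid_step = 0.01) {
  n <- nrow(ld)
  w <- unclass(ld)
  # union-find
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ut <- which(upper.tri(w), arr.ind = TRUE)
  ev <- w[ut]
  oke <- !is.na(ev)
  edges <- cbind(ut[oke, , drop = FALSE], ev[oke])
  edges <- edges[order(-edges[, 3L]), , drop = FALSE]

  nodes <- lapply(seq_len(n), function(i) {
    list(id = i, members = i, formed_at = NA_real_, constituents = integer(0),
         n_edges = 0L)
  })
  node_of_root <- seq_len(n)   # current cluster node per UF root
  thresholds <- seq(1, 0, by = -grid_step)
  if (utils::tail(thresholds, 1L) > 0) thresholds <- c(thresholds, 0)
  ei <- 1L
  for (t in thresholds) {
    touched_old <- list()
    while (ei <= nrow(edges) && edges[ei, 3L] >= t) {
      ra <- find(edges[ei, 1L]); rb <- find(edges[ei, 2L])
      if (ra != rb) {
        olds <- c(touched_old[[as.character(ra)]], node_of_root[ra],
                  touched_old[[as.character(rb)]], node_of_root[rb])
        parent[rb] <- ra
        touched_old[[as.character(ra)]] <- unique(olds)
        touched_old[[as.character(rb)]] <- NULL
      }
      ei <- ei + 1L
    }
    for (key in names(touched_old)) {
      root <- find(as.integer(key))
      olds <- unique(touched_old[[key]])
      if (length(olds) < 2L) next
      members <- sort(unlist(lapply(nodes[olds], `[[`, "members")))
      new_id <- length(nodes) + 1L
      nodes[[new_id]] <- list(id = new_id, members = members, formed_at = t,
                              constituents = olds,
                              n_edges = edge_count(w, members, t))
      node_of_root[root] <- new_id
    }
  }
  structure(list(nodes = nodes, n_loci = n, ld = w, grid_step = grid_step),
            class = "ld_cluster_tree")
}

#' @export
print.ld_cluster_tree <- function(x, ...) {
  internal <- sum(vapply(x$nodes, function(nd) length(nd$constituents) > 0L,
                         logical(1L)))
  cat(sprintf("ld_cluster_tree: %d loci, %d merge nodes\n", x$n_loci, internal))
  if (!is.null(x$lambda)) {
    cat(sprintf("  %d outlier clusters, %d SOCs (phi = %g, E_min = %d)\n",
                sum(x$lambda$outlier, na.rm = TRUE), length(x$socs),
                x$phi, x$e_min))
  }
  invisible(x)
}

#' Flag lambda-outlier clusters and SOCs
#'
#' At every merge, each constituent cluster `C` (of at least 2 loci) receives
#' `lambda = |C| * (median r^2 within C - median r^2 within the merged
#' cluster)` — the drop in internal cohesion it suffers by merging, scaled by
#' its size. A constituent is an *outlier cluster* when its lambda exceeds
#' `median(lambda) + phi * MAD(lambda)` over all merges (MAD with the usual
#' 1.4826 consistency constant) and it carries at least `e_min` edges at its
#' merge threshold. A *single-outlier cluster* (SOC) is an outlier cluster
#' with no other outlier cluster nested inside it.
#'
#' @param tree an [build_ld_tree()] result.
#' @param phi MAD multiplier (study value 4).
#' @param e_min minimum edge count (study value 16).
#' @return the tree, augmented with `lambda` (data.frame: `node`, `merges_into`,
#'   `merge_threshold`, `size`, `n_edges`, `lambda`, `outlier`, `soc`) and
#'   `socs` (list of locus-id vectors, named by node id).
#' @export
lambda_outliers <- function(tree, phi = 4, e_min = 16L) {
  stopifnot(inherits(tree, "ld_cluster_tree"))
  ld <- tree$ld
  rows <- list()
  for (nd in tree$nodes) {
    if (length(nd$constituents) == 0L) next
    med_after <- median_within(ld, nd$members)
    for (child_id in nd$constituents) {
      child <- tree$nodes[[child_id]]
      if (length(child$members) < 2L) next
      med_before <- median_within(ld, child$members)
      rows[[length(rows) + 1L]] <- data.frame(
        node = child_id, merges_into = nd$id, merge_threshold = nd$formed_at,
        size = length(child$members),
        n_edges = edge_count(ld, child$members, nd$formed_at),
        lambda = length(child$members) * (med_before - med_after))
    }
  }
  lam <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node = integer(0), merges_into = integer(0),
               merge_threshold = numeric(0), size = integer(0),
               n_edges = integer(0), lambda = numeric(0))
  if (nrow(lam) > 0L) {
    cut <- stats::median(lam$lambda) + phi * stats::mad(lam$lambda)
    lam$outlier <- lam$lambda > cut & lam$n_edges >= e_min
  } else {
    lam$outlier <- logical(0)
  }
  # SOC: outlier with no outlier nested strictly inside
  out_nodes <- lam$node[lam$outlier]
  members_of <- lapply(tree$nodes, `[[`, "members")
  is_soc <- vapply(out_nodes, function(id) {
    inner <- setdiff(out_nodes, id)
    !any(vapply(inner, function(j) {
      all(members_of[[j]] %in% members_of[[id]]) &&
        length(members_of[[j]]) < length(members_of[[id]])
    }, logical(1L)))
  }, logical(1L))
  lam$soc <- lam$outlier & lam$node %in% out_nodes[is_soc]
  tree$lambda <- lam
  tree$phi <- phi
  tree$e_min <- as.integer(e_min)
  tree$socs <- stats::setNames(
    lapply(out_nodes[is_soc], function(id) {
      rownames(tree$ld)[members_of[[id]]]
    }),
    out_nodes[is_soc])
  tree
}

#' Per-SOC divergence summary
#'
#' For a set of loci forming a single-outlier cluster: the multilocus
#' Weir-Cockerham F_st across the sample groups, the median within-SOC
#' r-squared, and a centroid-separation score — between-group over
#' within-group variance of the individuals' top-principal-component scores
#' computed from the SOC's loci. A group-differentiating SOC shows elevated
#' F_st and centroid separation; a physically linked but group-neutral SOC
#' (the signature the study interpreted as a possible inversion) shows F_st
#' near 0 with high internal r-squared.
#'
#' @param g a [genotype_matrix()].
#' @param groups a [sample_groups()].
#' @param soc character vector of locus ids (non-empty).
#' @param by grouping unit for the F_st contrast, default `"cell"`.
#' @param ld optional precomputed [ld_r2_matrix()] covering the SOC loci.
#' @return list with `n_loci`, `fst`, `median_r2`, `centroid_separation`.
#' @export
soc_divergence <- function(g, groups, soc, by = c("cell", "location", "species"),
                           ld = NULL) {
  by <- match.arg(by)
  if (length(soc) == 0L) stop("empty SOC locus set")
  idx <- match(soc, locus_ids(g))
  if (anyNA(idx)) stop("SOC loci absent from the genotype matrix")
  sub <- subset_loci(g, idx)
  labels <- group_labels(sub, groups, by)
  f <- wc_fst(sub, labels)
  r2 <- if (is.null(ld)) ld_r2_matrix(sub, min_shared = 0) else
    ld[soc, soc, drop = FALSE]
  med_r2 <- stats::median(r2[upper.tri(r2)], na.rm = TRUE)
  # centroid separation on top PCs
  X <- t(sub$dosages)
  mu <- colMeans(X, na.rm = TRUE); mu[is.nan(mu)] <- 0
  na <- which(is.na(X), arr.ind = TRUE)
  if (nrow(na) > 0L) X[na] <- mu[na[, 2L]]
  X <- scale(X, center = TRUE, scale = FALSE)
  k <- min(2L, ncol(X), nrow(X) - 1L)
  pcs <- stats::prcomp(X, rank. = k)$x
  grand <- colMeans(pcs)
  between <- 0; within <- 0
  for (lev in unique(labels)) {
    sel <- labels == lev
    cm <- colMeans(pcs[sel, , drop = FALSE])
    between <- between + sum(sel) * sum((cm - grand)^2)
    within <- within + sum(sweep(pcs[sel, , drop = FALSE], 2L, cm)^2)
  }
  list(n_loci = length(soc), fst = f$fst, median_r2 = med_r2,
       centroid_separation = if (within > 0) between / within else Inf)
}
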