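test_that("r-squared matrix matches closed-form correlation and handles sharing", {
  dos <- rbind(c(0L, 1L, 2L, 2L),
               c(0L, 1L, 2L, 2L),     # duplicate -> r2 = 1
               c(2L, 1L, 0L, 1L))
  g <- make_g(dos, samples = paste0("s", 1:4))
  ld <- ld_r2_matrix(g, min_shared = 0.5)
  expect_equal(unname(diag(ld)), rep(1, 3))
  expect_equal(ld[1, 2], 1)
  expect_equal(ld[1, 3], cor(dos[1, ], dos[3, ])^2)
  expect_true(isSymmetric(unclass(ld)))

  # pairs sharing too few individuals become undefined
  dos2 <- rbind(c(0L, 1L, NA, NA),
                c(NA, NA, 2L, 0L),
                c(0L, 1L, 2L, 0L))
  g2 <- make_g(dos2, samples = paste0("s", 1:4))
  ld2 <- ld_r2_matrix(g2, min_shared = 0.8)
  expect_true(is.na(ld2[1, 2]))

  # independent loci on many individuals have r2 near 0
  set.seed(3)
  big <- matrix(rbinom(2L * 500L, 2L, 0.5), 2L, 500L)
  ldb <- ld_r2_matrix(make_g(big, samples = paste0("s", 1:500)))
  expect_lt(ldb[1, 2], 0.05)
})

test_that("the merger tree is a nested hierarchy with monotone thresholds", {
  # exact-tie fixture: tree structure only (no lambda flags involved)
  ld <- make_ld_blocks(20, list(1:5), within = 0.9, between = 0.1, jitter = 0)
  tree <- build_ld_tree(ld)
  merges <- Filter(function(nd) length(nd$constituents) > 0, tree$nodes)
  # the 5-block appears as a cluster formed at threshold 0.90
  block_node <- Filter(function(nd) setequal(nd$members, 1:5), merges)
  expect_gte(length(block_node), 1L)
  expect_equal(max(vapply(block_node, `[[`, numeric(1), "formed_at")), 0.90)
  # member sets strictly nest along parent links; thresholds non-increasing
  for (nd in merges) {
    for (ch in nd$constituents) {
      expect_true(all(tree$nodes[[ch]]$members %in% nd$members))
      if (length(tree$nodes[[ch]]$constituents) > 0) {
        expect_gte(tree$nodes[[ch]]$formed_at, nd$formed_at)
      }
    }
  }
  # every locus appears in exactly one leaf and in the final cluster
  final <- merges[[length(merges)]]
  expect_setequal(final$members, 1:20)

  # an all-zero LD matrix merges nothing above threshold 0
  ld0 <- make_ld_blocks(6, list(), between = 0, jitter = 0)
  t0 <- build_ld_tree(ld0)
  above0 <- Filter(function(nd) length(nd$constituents) > 0 && nd$formed_at > 0,
                   t0$nodes)
  expect_length(above0, 0L)
})

test_that("tree-implied clusters match independent connected components", {
  set.seed(15)
  n <- 30L
  ld <- matrix(runif(n * n, 0, 0.8), n, n)
  ld <- (ld + t(ld)) / 2; diag(ld) <- 1
  dimnames(ld) <- list(paste0("L", 1:n), paste0("L", 1:n))
  class(ld) <- c("ld_matrix", class(ld))
  tree <- build_ld_tree(ld)
  partition_at <- function(tree, t) {
    # maximal merge nodes formed at a threshold >= t, plus leftover singletons
    nodes <- Filter(function(nd) length(nd$constituents) > 0 &&
                      nd$formed_at >= t, tree$nodes)
    nodes <- Filter(function(nd) {
      !any(vapply(nodes, function(o) {
        length(o$members) > length(nd$members) && all(nd$members %in% o$members)
      }, logical(1L)))
    }, nodes)
    covered <- unlist(lapply(nodes, `[[`, "members"))
    length(nodes) + (tree$n_loci - length(covered))
  }
  counts <- vapply(c(0.9, 0.7, 0.5, 0.3, 0.1, 0), function(t) {
    adj <- unclass(ld) >= t; diag(adj) <- TRUE
    igraph::components(igraph::graph_from_adjacency_matrix(adj, "undirected"))$no
  }, numeric(1L))
  mine <- vapply(c(0.9, 0.7, 0.5, 0.3, 0.1, 0), partition_at,
                 numeric(1L), tree = tree)
  expect_equal(mine, counts)
  expect_true(all(diff(mine) <= 0))
})

test_that("lambda flags a planted block as the single SOC", {
  ld <- make_ld_blocks(40, list(1:12), within = 0.9, between = 0.05)
  tree <- lambda_outliers(build_ld_tree(ld), phi = 4, e_min = 16L)
  expect_length(tree$socs, 1L)
  expect_true(all(paste0("L", 1:12) %in% tree$socs[[1L]]))
  expect_lte(length(tree$socs[[1L]]), 16L)   # at most a few stragglers

  # homogeneous LD: no outliers at phi = 4
  set.seed(7)
  n <- 25L
  flat <- matrix(pmin(pmax(rnorm(n * n, 0.1, 0.02), 0), 1), n, n)
  flat <- (flat + t(flat)) / 2; diag(flat) <- 1
  dimnames(flat) <- list(paste0("L", 1:n), paste0("L", 1:n))
  t2 <- lambda_outliers(build_ld_tree(flat), phi = 4, e_min = 16L)
  expect_length(t2$socs, 0L)

  # an unreachable edge floor silences everything
  t3 <- lambda_outliers(build_ld_tree(ld), phi = 4, e_min = 10000L)
  expect_length(t3$socs, 0L)
})

test_that("two planted blocks give exactly two SOCs across the phi sweep", {
  ld <- make_ld_blocks(60, list(1:12, 21:32), within = 0.85, between = 0.05)
  for (phi in c(2, 4, 6)) {
    tr <- lambda_outliers(build_ld_tree(ld), phi = phi, e_min = 16L)
    expect_length(tr$socs, 2L)
    sets <- lapply(tr$socs, sort)
    expect_setequal(unlist(sets), paste0("L", c(1:12, 21:32)))
  }
})

test_that("SOC flags are invariant to locus order", {
  set.seed(27)
  ld <- make_ld_blocks(30, list(5:14), within = 0.9, between = 0.05)
  perm <- sample(30L)
  ldp <- ld[perm, perm]
  class(ldp) <- class(ld)
  t1 <- lambda_outliers(build_ld_tree(ld), phi = 4, e_min = 16L)
  t2 <- lambda_outliers(build_ld_tree(ldp), phi = 4, e_min = 16L)
  expect_equal(length(t1$socs), length(t2$socs))
  expect_setequal(unname(unlist(t1$socs)), unname(unlist(t2$socs)))
})

test_that("per-SOC divergence separates adaptive from neutral linked clusters", {
  set.seed(33)
  # divergent SOC: loci differentiating locations; neutral SOC: linked block
  cfg <- generator_config(n_stacks = 120, n_per_cell = 12, f_loc = 0,
                          f_sp = 0, mcar_rate = 0, min_call_depth = 1L,
                          seed = 12,
                          planted = data.frame(
                            type = rep("location_divergent", 8L),
                            level = "L1", p_focal = 0.9, p_other = 0.1))
  cfg <- plant_linked_block(cfg, size = 8L, r2 = 0.75)
  ds <- generate_dataset(cfg)
  div_soc <- ds$truth$locus_id[ds$truth$type == "location_divergent"]
  link_soc <- ds$truth$locus_id[ds$truth$type == "linked_block"]
  d1 <- soc_divergence(ds$genotypes, ds$groups, div_soc)
  d2 <- soc_divergence(ds$genotypes, ds$groups, link_soc)
  f_bg <- wc_fst(ds$genotypes, group_labels(ds$genotypes, ds$groups, "cell"))
  expect_gt(d1$fst, f_bg$fst + 0.2)          # adaptive SOC far above background
  expect_lt(abs(d2$fst), 0.05)               # neutral linked SOC stays flat
  expect_gt(d2$median_r2, 0.4)               # ... but is internally correlated
  expect_gt(d1$centroid_separation, d2$centroid_separation)
  expect_error(soc_divergence(ds$genotypes, ds$groups, character(0)), "empty")
})
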