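test_that("a fixed difference between groups gives F_st exactly 1", {
  dos <- matrix(c(rep(0L, 20), rep(2L, 23)), 1)
  g <- make_g(dos, samples = paste0("s", 1:43))
  f <- wc_fst(g, rep(c("BLZ", "HON", "PAN"), c(20, 12, 11)))
  expect_equal(f$loci$fst, 1)
  expect_equal(f$fst, 1)
  expect_equal(f$loci$b, 0)
  expect_equal(f$loci$c, 0)
})

test_that("identical genotype distributions give a non-positive estimate", {
  dos <- matrix(rep(c(rep(0L, 7), rep(1L, 7)), 2), 1)
  g <- make_g(dos, samples = paste0("s", 1:28))
  f <- wc_fst(g, rep(c("a", "b"), each = 14))
  expect_lte(f$fst, 0)
})

test_that("estimator matches the mean-squares ANOVA oracle on all small 2-group configurations", {
  for (sizes in list(c(2L, 2L), c(2L, 3L), c(3L, 3L))) {
    n <- sum(sizes)
    grid <- as.matrix(expand.grid(rep(list(0:2), n)))
    g <- make_g(grid, samples = paste0("s", 1:n))
    grouping <- rep(c("x", "y"), sizes)
    f <- wc_fst(g, grouping)
    for (i in seq_len(nrow(grid))) {
      byg <- split(grid[i, ], grouping)
      comp <- oracle_components(byg)
      expect_equal(unname(f$loci$a[i]), unname(comp[["a"]]), tolerance = 1e-12)
      expect_equal(unname(f$loci$b[i]), unname(comp[["b"]]), tolerance = 1e-12)
      expect_equal(unname(f$loci$c[i]), unname(comp[["c"]]), tolerance = 1e-12)
      ot <- oracle_theta(byg)
      if (is.na(ot)) expect_false(f$loci$defined[i])
      else expect_equal(f$loci$fst[i], ot, tolerance = 1e-12)
    }
  }
})

test_that("estimator handles missing genotypes like the oracle drops them", {
  set.seed(8)
  n <- 12L
  dos <- matrix(sample(c(0:2, NA), 50 * n, replace = TRUE,
                       prob = c(.3, .3, .3, .1)), 50, n)
  g <- make_g(dos, samples = paste0("s", 1:n))
  grouping <- rep(c("x", "y", "z"), each = 4L)
  f <- wc_fst(g, grouping)
  for (i in seq_len(50)) {
    ot <- oracle_theta(split(dos[i, ], grouping))
    if (is.na(ot)) expect_false(f$loci$defined[i])
    else expect_equal(f$loci$fst[i], ot, tolerance = 1e-12)
  }
})

test_that("permuted labels on neutral loci give a near-zero multilocus estimate", {
  set.seed(41)
  L <- 1000L; n <- 60L
  p <- runif(L, 0.1, 0.9)
  dos <- matrix(rbinom(L * n, 2L, rep(p, n)), L, n)
  g <- make_g(dos, samples = paste0("s", 1:n))
  f <- wc_fst(g, sample(rep(c("a", "b", "c"), each = 20L)))
  expect_lt(abs(f$fst), 0.005)
})

test_that("estimate is invariant to relabeling groups and reordering input", {
  set.seed(12)
  dos <- matrix(sample(c(0:2, NA), 30 * 12, replace = TRUE), 30, 12)
  g <- make_g(dos, samples = paste0("s", 1:12))
  grouping <- rep(c("a", "b", "c"), each = 4L)
  f1 <- wc_fst(g, grouping)
  f2 <- wc_fst(g, c(a = "z", b = "q", c = "m")[grouping])   # relabel
  expect_equal(f1$loci$fst, f2$loci$fst)
  perm <- sample(12L)
  f3 <- wc_fst(subset_samples(g, perm), grouping[perm])     # reorder inds
  expect_equal(f1$loci$fst, f3$loci$fst)
  lperm <- sample(30L)
  f4 <- wc_fst(subset_loci(g, lperm), grouping)             # reorder loci
  expect_equal(f1$fst, f4$fst)
})

test_that("multilocus estimate is a ratio of sums, not a mean of ratios", {
  dos1 <- matrix(c(0L, 0L, 1L, 2L, 2L, 1L), 1)
  g1 <- make_g(dos1, samples = paste0("s", 1:6))
  f1 <- wc_fst(g1, rep(c("a", "b"), each = 3L))
  # L copies of one locus give that locus's per-locus estimate
  gL <- make_g(dos1[rep(1L, 7L), , drop = FALSE], samples = paste0("s", 1:6))
  fL <- wc_fst(gL, rep(c("a", "b"), each = 3L))
  expect_equal(fL$fst, f1$loci$fst)
  # two loci with different denominators: ratio-of-sums differs from the mean
  dos2 <- rbind(dos1, c(0L, 1L, 0L, 1L, 1L, 2L))
  g2 <- make_g(dos2, samples = paste0("s", 1:6))
  f2 <- wc_fst(g2, rep(c("a", "b"), each = 3L))
  sums <- colSums(f2$loci[c("a", "b", "c")])
  expect_equal(f2$fst, sums[["a"]] / sum(sums))
})

test_that("pairwise tables cover every pair in every stratum", {
  ds <- generate_dataset(generator_config(n_stacks = 200, n_per_cell = 6,
                                          seed = 9))
  tab <- pairwise_fst_table(ds$genotypes, ds$groups, axis = "location")
  expect_equal(nrow(tab), 4L * 3L)  # strata: all + 3 species; 3 pairs each
  expect_setequal(unique(tab$stratum), c("all", "spA", "spB", "spC"))
  # two identical groups: duplicate one cell's genotypes
  k <- 10L
  base <- matrix(sample(0:2, 40 * k, replace = TRUE), 40, k)
  g <- make_g(cbind(base, base), samples = paste0("s", 1:(2 * k)))
  groups <- sample_groups(g$samples, rep("sp", 2 * k),
                          rep(c("A", "B"), each = k))
  tab2 <- pairwise_fst_table(g, groups, axis = "location")
  expect_lte(max(tab2$fst), 0)
})

test_that("diversity summary reproduces hand-computed values", {
  g <- make_g(matrix(c(0L, 1L, 2L), 1), samples = c("a", "b", "c"))
  groups <- sample_groups(c("a", "b", "c"), rep("sp", 3), rep("X", 3))
  d <- diversity_summary(g, groups)
  expect_equal(d$Ho, 1 / 3)
  expect_equal(d$He, 0.6)          # 2n/(2n-1) * 2*p*q = (6/5)*0.5 with n = 3
  expect_equal(d$Fis, 1 - (1 / 3) / 0.6)

  gm <- make_g(matrix(0L, 2, 4), samples = paste0("s", 1:4))
  gr <- sample_groups(gm$samples, rep("sp", 4), rep("X", 4))
  dm <- diversity_summary(gm, gr)
  expect_equal(dm$Ho, 0)
  expect_equal(dm$He, 0)
  expect_true(is.na(dm$Fis))

  gh <- make_g(matrix(1L, 1, 6), samples = paste0("s", 1:6))
  gh_gr <- sample_groups(gh$samples, rep("sp", 6), rep("X", 6))
  expect_equal(diversity_summary(gh, gh_gr)$Ho, 1)
})

test_that("percentile stratification partitions loci with nearest-rank edges", {
  dos <- matrix(0L, 10, 4)  # placeholder; inject fst values directly
  f <- structure(list(loci = data.frame(locus_id = paste0("L", 1:10),
                                        fst = as.numeric(1:10),
                                        defined = TRUE)),
                 class = "fst_result")
  b <- percentile_stratify(f, breaks = c(60, 70, 80, 90))
  expect_equal(b$bins[["90-100"]], "L10")
  expect_equal(unname(b$counts), c(6L, 1L, 1L, 1L, 1L))
  expect_setequal(unlist(b$bins), paste0("L", 1:10))

  # negative estimates are legitimate and fall in the lowest bins
  f2 <- structure(list(loci = data.frame(locus_id = paste0("L", 1:100),
                                         fst = c(rnorm(60, -0.01, 0.002),
                                                 rnorm(40, 0.05, 0.01)),
                                         defined = TRUE)),
                  class = "fst_result")
  b2 <- percentile_stratify(f2)
  expect_equal(sum(b2$counts), 100L)
  expect_true(all(diff(b2$edges) >= 0))
})
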