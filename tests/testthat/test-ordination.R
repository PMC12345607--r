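test_that("PCoA reproduces closed forms and Euclidean geometry", {
  # two samples at distance d embed at +/- d/2 on one axis
  d <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  res <- pcoa(d)
  expect_identical(ncol(res$coordinates), 1L)
  expect_equal(unname(sort(res$coordinates[, 1])), c(-1.5, 1.5))

  # distances from planar points are reconstructed to machine precision
  withr::with_seed(1, {
    pts <- matrix(rnorm(20), 10, 2)
  })
  dm <- as.matrix(dist(pts))
  res2 <- pcoa(dm)
  rec <- as.matrix(dist(res2$coordinates))
  expect_equal(rec, dm, tolerance = 1e-9, ignore_attr = TRUE)
  # only two meaningful axes for planar data
  expect_identical(ncol(res2$coordinates), 2L)

  # all-zero matrix: no positive eigenvalues
  z <- matrix(0, 4, 4)
  expect_true(all(abs(pcoa(z)$eigenvalues) < 1e-12))
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PCoA agrees with ape's implementation on eigenvalues", {
  skip_if_not_installed("vegan")
  counts <- random_counts(n_taxa = 10, seed = 19)
  d <- as.matrix(beta_dissimilarity(counts, "jaccard"))
  ours <- pcoa(d)
  theirs <- ape::pcoa(as.dist(d))
  k <- min(5, ncol(ours$coordinates))
  expect_equal(ours$eigenvalues[1:k], theirs$values$Eigenvalues[1:k],
               tolerance = 1e-8)
  for (ax in 1:2) {
    expect_equal(abs(ours$coordinates[, ax]),
                 abs(theirs$vectors[, ax]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("pseudo-F on 1-D Euclidean distances equals the classical ANOVA F", {
  withr::with_seed(7, {
    y <- rnorm(18, mean = rep(c(0, 1, 3), each = 6))
  })
  g <- rep(c("a", "b", "c"), each = 6)
  d <- as.matrix(dist(y))
  res <- permanova(d, g, n_permutations = 99, seed = 1)
  f_classic <- summary(aov(y ~ g))[[1]]$`F value`[1]
  expect_equal(res$pseudo_F, f_classic, tolerance = 1e-10)
  expect_equal(res$r2, res$ss_between / (res$ss_between + res$ss_within))
  expect_identical(res$df_between, 2L)
  expect_identical(res$df_within, 15L)
})

test_that("PERMANOVA matches vegan::adonis2 and p-values follow the permutation convention", {
  skip_if_not_installed("vegan")
  counts <- random_counts(n_taxa = 12, seed = 23)
  design <- tiny_design()
  d <- as.matrix(beta_dissimilarity(counts, "jaccard"))
  res <- permanova(d, design$cultivar, n_permutations = 199, seed = 2)
  ad <- vegan::adonis2(as.dist(d) ~ cultivar, data = design, permutations = 199)
  expect_equal(res$pseudo_F, ad$F[1], tolerance = 1e-10)
  expect_equal(res$r2, ad$R2[1], tolerance = 1e-10)
  expect_equal(res$df_between, ad$Df[1], ignore_attr = TRUE)
  # the p-value is a multiple of 1/(1+B) and at least 1/(1+B)
  expect_gte(res$p_value, 1 / 200)
  expect_equal(res$p_value * 200, round(res$p_value * 200))
  # seed-stable
  res2 <- permanova(d, design$cultivar, n_permutations = 199, seed = 2)
  expect_identical(tidy(res), tidy(res2))
})

test_that("two internally identical, mutually distinct groups reach the minimal p", {
  # 10 + 10 samples, zero distance within groups, unit distance between:
  # essentially no random permutation reproduces the split
  n <- 20
  g <- rep(c("x", "y"), each = 10)
  d <- outer(g, g, "!=") * 1
  diag(d) <- 0
  res <- permanova(d, g, n_permutations = 999, seed = 3)
  expect_equal(res$p_value, 1 / 1000)
})

test_that("null permutation p-values are approximately uniform", {
  # structureless 1-D data, many independent tests, KS against uniform
  n_runs <- 500
  pvals <- numeric(n_runs)
  withr::with_seed(99, {
    for (i in seq_len(n_runs)) {
      y <- rnorm(12)
      g <- rep(c("a", "b"), each = 6)
      d <- as.matrix(dist(y))
      pvals[i] <- permanova(d, g, n_permutations = 199,
                            seed = sample.int(1e6, 1))$p_value
    }
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(pvals), 0.4)
  expect_lt(mean(pvals), 0.6)
})

test_that("pairwise PERMANOVA enumerates level pairs consistently with global runs", {
  counts <- random_counts(n_taxa = 10, seed = 29)
  design <- tiny_design()
  d <- as.matrix(beta_dissimilarity(counts, "jaccard"))
  groups <- design$timepoint_day
  pw <- pairwise_permanova(d, groups, n_permutations = 99, seed = 4)
  k <- length(unique(groups))
  expect_equal(nrow(pw), k * (k - 1) / 2)
  # with two levels the pairwise result is the global result
  two <- pairwise_permanova(d, design$biotype, n_permutations = 99, seed = 5)
  glob <- permanova(d, design$biotype, n_permutations = 99, seed = 5)
  expect_equal(two$pseudo_F, glob$pseudo_F, tolerance = 1e-12)
  expect_equal(two$p_value, glob$p_value)
  # each pairwise F matches a from-scratch run on the subset
  pair <- pw[1, ]
  idx <- which(groups %in% c(pair$level_a, pair$level_b))
  redo <- permanova(d[idx, idx], groups[idx], n_permutations = 99, seed = 4)
  expect_equal(pair$pseudo_F, redo$pseudo_F, tolerance = 1e-12)
})

test_that("sequential decomposition matches one-way results and vegan by terms", {
  counts <- random_counts(n_taxa = 12, seed = 31)
  design <- tiny_design()
  d <- as.matrix(beta_dissimilarity(counts, "jaccard"))
  # single factor: sequential == one-way partition
  seq1 <- permanova_sequential(d, design, "cultivar", n_permutations = 49, seed = 1)
  one <- permanova(d, design$cultivar, n_permutations = 49, seed = 1)
  expect_equal(seq1$ss[1], one$ss_between, tolerance = 1e-10)
  expect_equal(seq1$pseudo_F[1], one$pseudo_F, tolerance = 1e-10)

  skip_if_not_installed("vegan")
  seq2 <- permanova_sequential(d, design, c("biotype", "cultivar", "timepoint_day"),
                               n_permutations = 49, seed = 1)
  ad <- vegan::adonis2(
    as.dist(d) ~ biotype + cultivar + timepoint_day,
    data = dplyr::mutate(design, timepoint_day = factor(timepoint_day)),
    permutations = 49, by = "terms"
  )
  expect_equal(seq2$ss[1:3], ad$SumOfSqs[1:3], tolerance = 1e-8)
  expect_equal(seq2$pseudo_F[1:3], ad$F[1:3], tolerance = 1e-8)
  expect_equal(seq2$df[1:3], ad$Df[1:3])
  expect_equal(seq2$ss[4], ad$SumOfSqs[4], tolerance = 1e-8)
})

test_that("tidiers return well-formed tibbles", {
  counts <- random_counts(n_taxa = 8, seed = 37)
  design <- tiny_design()
  d <- beta_dissimilarity(counts, "jaccard")
  td <- tidy(d)
  expect_equal(nrow(td), choose(length(d$sample_ids), 2))
  res <- permanova(d, design$biotype, n_permutations = 49, seed = 1)
  expect_identical(nrow(tidy(res)), 1L)
  expect_named(glance(res), c("pseudo_F", "r2", "p_value", "n_permutations"))
  pc <- pcoa(d)
  expect_identical(nrow(tidy(pc)), nrow(design))
  expect_identical(glance(pc)$n_samples, nrow(design))
})
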