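test_that("jaccard matches hand values and set arithmetic", {
  tbl <- tibble::tibble(
    taxon_id = c("a", "b", "c", "d"),
    s1 = c(1, 1, 1, 0), # {a,b,c}
    s2 = c(0, 1, 1, 1), # {b,c,d}
    s3 = c(1, 1, 1, 0),
    s4 = c(0, 0, 0, 3)
  )
  expect_equal(jaccard(tbl, "s1", "s2"), 0.5)
  expect_equal(jaccard(tbl, "s1", "s3"), 0)
  expect_equal(jaccard(tbl, "s1", "s4"), 1)
  expect_error(jaccard(tbl, "s1", "nope"), "not found")
})

test_that("unweighted UniFrac matches the worked three-leaf example", {
  tree <- ape::read.tree(text = "((X:1,Y:1):1,Z:2);")
  tbl <- tibble::tibble(
    taxon_id = c("X", "Y", "Z"),
    a = c(5, 0, 0), b = c(0, 7, 0), c = c(5, 0, 0)
  )
  expect_equal(unweighted_unifrac(tbl, tree, "a", "b"), 2 / 3)
  expect_equal(unweighted_unifrac(tbl, tree, "a", "c"), 0)
  # weighted, raw: each tip edge contributes 1, the shared internal edge 0
  expect_equal(weighted_unifrac(tbl, tree, "a", "b", normalized = FALSE), 2)
  expect_equal(weighted_unifrac(tbl, tree, "a", "a", normalized = FALSE), 0)
  # missing taxon is named in the error
  tbl2 <- tibble::tibble(taxon_id = c("X", "W"), a = c(1, 1), b = c(1, 0))
  expect_error(unweighted_unifrac(tbl2, tree, "a", "b"), "W")
})

test_that("star-tree UniFrac collapses to Jaccard on presence patterns", {
  n <- 8
  taxa <- paste0("t", seq_len(n))
  star <- ape::read.tree(text = paste0(
    "(", paste0(taxa, ":1", collapse = ","), ");"
  ))
  withr::with_seed(3, {
    for (i in 1:20) {
      m <- matrix(rbinom(n * 2, 1, 0.6), n, 2)
      if (all(m[, 1] == 0) || all(m[, 2] == 0)) next
      tbl <- tibble::tibble(taxon_id = taxa, s1 = m[, 1], s2 = m[, 2])
      expect_equal(
        unweighted_unifrac(tbl, star, "s1", "s2"),
        jaccard(tbl, "s1", "s2")
      )
    }
  })
  # disjoint single-taxon samples on a unit star: both metrics hit 1
  tbl <- tibble::tibble(taxon_id = taxa, s1 = c(1, rep(0, n - 1)),
                        s2 = c(0, 1, rep(0, n - 2)))
  expect_equal(unweighted_unifrac(tbl, star, "s1", "s2"), 1)
  expect_equal(weighted_unifrac(tbl, star, "s1", "s2", normalized = TRUE), 1)
})

test_that("production UniFrac agrees with a per-edge enumeration oracle on small trees", {
  withr::with_seed(42, {
    for (n_leaves in 3:6) {
      for (rep in 1:8) {
        taxa <- paste0("t", seq_len(n_leaves))
        tree <- generate_tree(taxa, seed = n_leaves * 100 + rep)
        counts <- matrix(rpois(n_leaves * 2, 3), n_leaves, 2)
        if (any(colSums(counts) == 0)) counts <- counts + 1
        tbl <- tibble::tibble(taxon_id = taxa, A = counts[, 1], B = counts[, 2])
        pr <- rel_profiles(tbl, "A", "B")
        expect_equal(
          unweighted_unifrac(tbl, tree, "A", "B"),
          oracle_unifrac(tree, pr$a, pr$b, weighted = FALSE),
          tolerance = 1e-12
        )
        expect_equal(
          weighted_unifrac(tbl, tree, "A", "B", normalized = FALSE),
          oracle_unifrac(tree, pr$a, pr$b, weighted = TRUE),
          tolerance = 1e-12
        )
        expect_equal(
          weighted_unifrac(tbl, tree, "A", "B", normalized = TRUE),
          oracle_unifrac(tree, pr$a, pr$b, weighted = TRUE, normalized = TRUE),
          tolerance = 1e-12
        )
      }
    }
  })
})

test_that("UniFrac values are invariant to the position of the root", {
  taxa <- paste0("t", 1:7)
  tree <- generate_tree(taxa, seed = 5)
  counts <- random_counts(n_taxa = 7, seed = 6, n_samples = 2)
  counts$taxon_id <- taxa
  ids <- colnames(counts)[-1]
  rerooted <- ape::root(tree, outgroup = "t3", resolve.root = TRUE)
  expect_equal(
    unweighted_unifrac(counts, tree, ids[1], ids[2]),
    unweighted_unifrac(counts, rerooted, ids[1], ids[2]),
    tolerance = 1e-10
  )
  expect_equal(
    weighted_unifrac(counts, tree, ids[1], ids[2], normalized = FALSE),
    weighted_unifrac(counts, rerooted, ids[1], ids[2], normalized = FALSE),
    tolerance = 1e-10
  )
})

test_that("dissimilarity matrices are symmetric, zero-diagonal and in range", {
  counts <- random_counts(n_taxa = 10, seed = 7)
  tree <- generate_tree(counts$taxon_id, seed = 8)
  for (metric in c("jaccard", "unweighted_unifrac", "weighted_unifrac")) {
    d <- beta_dissimilarity(counts, metric, tree = tree)
    m <- as.matrix(d)
    expect_true(isSymmetric(unname(m)))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0 & m <= 1 + 1e-12))
    # matrix entries agree with the pairwise functions
    ids <- d$sample_ids
    pairfun <- switch(metric,
      jaccard = function(a, b) jaccard(counts, a, b),
      unweighted_unifrac = function(a, b) unweighted_unifrac(counts, tree, a, b),
      weighted_unifrac = function(a, b) weighted_unifrac(counts, tree, a, b)
    )
    expect_equal(m[ids[1], ids[4]], pairfun(ids[1], ids[4]), tolerance = 1e-12)
    expect_equal(m[ids[2], ids[3]], pairfun(ids[2], ids[3]), tolerance = 1e-12)
  }
})

test_that("UniFrac matrices match phyloseq's implementation", {
  skip_if_not_installed("phyloseq")
  counts <- random_counts(n_taxa = 9, seed = 13)
  tree <- generate_tree(counts$taxon_id, seed = 14)
  m <- as.matrix(counts[, -1])
  rownames(m) <- counts$taxon_id
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(m, taxa_are_rows = TRUE),
    phyloseq::phy_tree(tree)
  )
  ours_uu <- as.matrix(beta_dissimilarity(counts, "unweighted_unifrac", tree = tree))
  theirs_uu <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
  expect_equal(ours_uu[rownames(theirs_uu), colnames(theirs_uu)], theirs_uu,
               tolerance = 1e-8)
  ours_wu <- as.matrix(beta_dissimilarity(counts, "weighted_unifrac", tree = tree,
                                          normalized = TRUE))
  theirs_wu <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
  expect_equal(ours_wu[rownames(theirs_wu), colnames(theirs_wu)], theirs_wu,
               tolerance = 1e-8)
})

test_that("dissimilarity round-trips through its TSV serialization", {
  counts <- random_counts(n_taxa = 8, seed = 15)
  d <- beta_dissimilarity(counts, "jaccard")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dissimilarity(d, path)
  back <- read_dissimilarity(path)
  expect_identical(back$sample_ids, d$sample_ids)
  expect_equal(back$values, d$values, tolerance = 1e-12)
})
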