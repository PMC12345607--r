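# Small designs, count tables and trees used across the suite.

tiny_design <- function() {
  generate_design(design_spec(
    biotypes = c("E", "K"),
    cultivars = tibble::tibble(
      cultivar = c("c1", "c2"),
      host_species = c("h1", "h2")
    ),
    timepoints_post = c(2L, 4L),
    replicates_per_cell = 2L
  ))
}

# deterministic hand-built 4-sample table over 3 taxa
hand_counts <- function() {
  tibble::tibble(
    taxon_id = c("X", "Y", "Z"),
    s1 = c(10, 0, 5),
    s2 = c(0, 8, 2),
    s3 = c(4, 4, 4),
    s4 = c(0, 0, 9)
  )
}

# random count table with a seeded generator, modest depths for speed
random_counts <- function(n_taxa = 20, seed = 1, n_samples = NULL,
                          design = NULL) {
  if (is.null(design)) design <- tiny_design()
  if (!is.null(n_samples)) design <- design[seq_len(n_samples), ]
  generate_counts(design, community_params(
    n_taxa = n_taxa, endosymbiont_fraction = 0.7, outbreak_taxa = 2,
    depth_range = c(2000L, 4000L), seed = seed
  ))
}

# brute-force unweighted/weighted UniFrac used as an oracle: walks every edge,
# finds its descendant leaves by path enumeration (independent of the
# production postorder-accumulation code path)
oracle_unifrac <- function(tree, p_a, p_b, weighted = FALSE, normalized = FALSE) {
  ntip <- length(tree$tip.label)
  # leaves below each node, by repeatedly following edges downward
  descendants <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    sort(unlist(lapply(kids, descendants)))
  }
  unique_len <- 0
  total_len <- 0
  wsum <- 0
  for (e in seq_len(nrow(tree$edge))) {
    leaves <- tree$tip.label[descendants(tree$edge[e, 2])]
    b <- tree$edge.length[e]
    pa <- sum(p_a[leaves])
    pb <- sum(p_b[leaves])
    if (weighted) {
      wsum <- wsum + b * abs(pa - pb)
    } else {
      if (pa > 0 || pb > 0) total_len <- total_len + b
      if (xor(pa > 0, pb > 0)) unique_len <- unique_len + b
    }
  }
  if (weighted) {
    if (!normalized) return(wsum)
    depth <- ape::node.depth.edgelength(tree)[seq_len(ntip)]
    names(depth) <- tree$tip.label
    denom <- sum(depth * (p_a[tree$tip.label] + p_b[tree$tip.label]))
    return(wsum / denom)
  }
  if (total_len == 0) 0 else unique_len / total_len
}

# relative-abundance named vectors for two samples of a count tibble
rel_profiles <- function(counts, a, b) {
  m <- as.matrix(counts[, -1])
  rownames(m) <- counts[[1]]
  list(
    a = setNames(m[, a] / sum(m[, a]), rownames(m)),
    b = setNames(m[, b] / sum(m[, b]), rownames(m))
  )
}
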