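# Per-edge abundance machinery shared by the UniFrac metrics.
#
# For a rooted tree and a relative-abundance vector over its tips, every edge
# carries the summed abundance of the leaves below it. Unweighted UniFrac is
# the branch length seen by exactly one of the two samples divided by the
# branch length seen by either; weighted UniFrac is sum_e b_e |pA_e - pB_e|,
# optionally normalized by the abundance-weighted root-to-leaf depth so it
# lands in [0, 1].

# internal: validate tree & match count matrix rows to tips; returns a list
# with the postorder edge matrix, branch lengths and tip abundance alignment
prepare_tree <- function(tree, taxa) {
  if (!inherits(tree, "phylo")) abort_bad_input("`tree` must be an ape `phylo` object.")
  if (is.null(tree$edge.length)) abort_bad_input("`tree` must have branch lengths.")
  if (any(tree$edge.length < 0)) abort_bad_input("negative branch lengths in `tree`.")
  if (anyDuplicated(tree$tip.label)) abort_bad_input("duplicate tip labels in `tree`.")
  tree
}

# internal: edge-wise descendant abundance for each column of a relative
# abundance matrix `p` (tips x samples, rows aligned to tree$tip.label).
# Returns samples-column matrix with one row per edge.
edge_abundance <- function(tree, p) {
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  acc <- matrix(0, nnode, ncol(p))
  acc[seq_len(ntip), ] <- p
  parents <- po$edge[, 1]
  children <- po$edge[, 2]
  for (i in seq_along(parents)) {
    acc[parents[i], ] <- acc[parents[i], ] + acc[children[i], ]
  }
  list(per_edge = acc[po$edge[, 2], , drop = FALSE],
       lengths = po$edge.length)
}

# internal: relative-abundance matrix for the taxa present in `counts`,
# aligned to the tree's tips (tree tips absent from the table get zero)
tree_aligned_profiles <- function(tree, counts, samples) {
  m <- counts_matrix(counts)
  if (!all(samples %in% colnames(m))) {
    abort_bad_input(paste0("sample(s) not in `counts`: ",
                           paste(setdiff(samples, colnames(m)), collapse = ", ")))
  }
  m <- m[, samples, drop = FALSE]
  present <- rownames(m)[rowSums(m) > 0]
  missing <- setdiff(present, tree$tip.label)
  if (length(missing)) {
    abort_bad_input(paste0("taxa missing from the tree: ",
                           paste(missing, collapse = ", ")))
  }
  depths <- colSums(m)
  if (any(depths <= 0)) abort_bad_input("samples must have positive depth.")
  p <- matrix(0, length(tree$tip.label), ncol(m),
              dimnames = list(tree$tip.label, colnames(m)))
  shared <- intersect(rownames(m), tree$tip.label)
  p[shared, ] <- sweep(m[shared, , drop = FALSE], 2, depths, "/")
  p
}

#' Jaccard dissimilarity between two samples
#'
#' Presence/absence dissimilarity `1 - |shared| / |union|` over the taxa with
#' nonzero counts in each sample.
#'
#' @param counts Wide count tibble.
#' @param sample_a,sample_b Sample identifiers (column names of `counts`).
#' @return Dissimilarity in [0, 1].
#' @export
jaccard <- function(counts, sample_a, sample_b) {
  m <- counts_matrix(counts)
  for (s in c(sample_a, sample_b)) {
    if (!s %in% colnames(m)) abort_bad_input(paste0("sample not found: ", s))
  }
  a <- m[, sample_a] > 0
  b <- m[, sample_b] > 0
  uni <- sum(a | b)
  if (uni == 0) abort_bad_input("both samples are empty.")
  1 - sum(a & b) / uni
}

#' Unweighted UniFrac between two samples
#'
#' Fraction of the tree's relevant branch length unique to one sample: an
#' edge belongs to a sample if any leaf below it is present in that sample;
#' edges with no present descendants in either sample are ignored.
#'
#' @inheritParams jaccard
#' @param tree Rooted `phylo` tree with branch lengths whose tips cover every
#'   taxon present in the two samples.
#' @return Dissimilarity in [0, 1].
#' @export
unweighted_unifrac <- function(counts, tree, sample_a, sample_b) {
  tree <- prepare_tree(tree)
  p <- tree_aligned_profiles(tree, counts, c(sample_a, sample_b))
  ea <- edge_abundance(tree, p)
  in_a <- ea$per_edge[, 1] > 0
  in_b <- ea$per_edge[, 2] > 0
  total <- sum(ea$lengths[in_a | in_b])
  if (total == 0) return(0)
  sum(ea$lengths[xor(in_a, in_b)]) / total
}

#' Weighted UniFrac between two samples
#'
#' `sum_e b_e |pA_e - pB_e|` over edges, where `p_e` is the summed relative
#' abundance of the leaves below edge `e`. With `normalized = TRUE` (the
#' default) the raw value is divided by the abundance-weighted mean
#' root-to-leaf distance of the two samples, bounding the result in [0, 1].
#'
#' @inheritParams unweighted_unifrac
#' @param normalized Divide by the abundance-weighted root-to-leaf scaling.
#' @return Dissimilarity (in [0, 1] when normalized).
#' @export
weighted_unifrac <- function(counts, tree, sample_a, sample_b, normalized = TRUE) {
  tree <- prepare_tree(tree)
  p <- tree_aligned_profiles(tree, counts, c(sample_a, sample_b))
  ea <- edge_abundance(tree, p)
  raw <- sum(ea$lengths * abs(ea$per_edge[, 1] - ea$per_edge[, 2]))
  if (!normalized) return(raw)
  tip_depth <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  denom <- sum(tip_depth * (p[, 1] + p[, 2]))
  if (denom == 0) return(0)
  raw / denom
}

#' All-pairs dissimilarity matrix
#'
#' Computes the chosen dissimilarity between every pair of samples in one
#' pass (UniFrac metrics share a single tree traversal over all samples).
#'
#' @param counts Wide count tibble.
#' @param metric One of `"jaccard"`, `"unweighted_unifrac"`,
#'   `"weighted_unifrac"`.
#' @param tree Rooted `phylo` tree; required for the UniFrac metrics.
#' @param normalized For weighted UniFrac, use the normalized variant.
#' @return A `dissimilarity` object: list with `sample_ids` and the symmetric
#'   zero-diagonal `values` matrix. Convert with [as.matrix()] or [tidy()].
#' @export
beta_dissimilarity <- function(counts,
                               metric = c("jaccard", "unweighted_unifrac",
                                          "weighted_unifrac"),
                               tree = NULL, normalized = TRUE) {
  metric <- arg_match(metric)
  m <- counts_matrix(counts)
  ids <- colnames(m)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (metric == "jaccard") {
    pres <- m > 0
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        uni <- sum(pres[, i] | pres[, j])
        if (uni == 0) abort_bad_input("two empty samples encountered.")
        d[i, j] <- d[j, i] <- 1 - sum(pres[, i] & pres[, j]) / uni
      }
    }
  } else {
    if (is.null(tree)) abort_bad_input("UniFrac metrics require `tree`.")
    tree <- prepare_tree(tree)
    p <- tree_aligned_profiles(tree, counts, ids)
    ea <- edge_abundance(tree, p)
    if (metric == "unweighted_unifrac") {
      pres <- ea$per_edge > 0
      for (i in seq_len(n - 1)) {
        for (j in seq(i + 1, n)) {
          either <- pres[, i] | pres[, j]
          tot <- sum(ea$lengths[either])
          d[i, j] <- d[j, i] <-
            if (tot == 0) 0 else sum(ea$lengths[xor(pres[, i], pres[, j])]) / tot
        }
      }
    } else {
      tip_depth <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
      for (i in seq_len(n - 1)) {
        for (j in seq(i + 1, n)) {
          raw <- sum(ea$lengths * abs(ea$per_edge[, i] - ea$per_edge[, j]))
          if (normalized) {
            denom <- sum(tip_depth * (p[, i] + p[, j]))
            raw <- if (denom == 0) 0 else raw / denom
          }
          d[i, j] <- d[j, i] <- raw
        }
      }
    }
  }
  new_dissimilarity(d)
}

# internal constructor
new_dissimilarity <- function(values) {
  stopifnot(isSymmetric(unname(values)), all(diag(values) == 0))
  structure(list(sample_ids = colnames(values), values = values),
            class = "dissim")
}

#' @export
as.matrix.dissim <- function(x, ...) x$values

#' @export
print.dissim <- function(x, ...) {
  cat("dissimilarity matrix over", length(x$sample_ids), "samples\n")
  print(utils::head(x$values[, seq_len(min(6, ncol(x$values))), drop = FALSE]))
  invisible(x)
}

#' @rdname beta_dissimilarity
#' @method tidy dissim
#' @param x A `dissimilarity` object.
#' @param ... Unused.
#' @export
tidy.dissim <- function(x, ...) {
  ids <- x$sample_ids
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble(
    sample_a = ids[idx[, 1]],
    sample_b = ids[idx[, 2]],
    distance = x$values[idx]
  )
}
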