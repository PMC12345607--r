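#' Parameters of the synthetic community generator
#'
#' Describes a community in which one endosymbiont taxon carries most of the
#' reads in every sample (as Buchnera aphidicola does in aphids, its 50-200
#' genome copies per cell inflating its amplicon share), the remaining taxa
#' follow a symmetric Dirichlet-multinomial, and a few "outbreak" taxa are
#' nearly confined to a single replicate plant.
#'
#' @param n_taxa Total number of taxa (>= 2).
#' @param endosymbiont_index Row index of the dominant endosymbiont taxon.
#' @param endosymbiont_fraction Mean per-sample relative abundance of the
#'   endosymbiont, in (0, 1); per-sample values are Beta-distributed around
#'   this mean.
#' @param focal_concentration Beta concentration of the per-sample
#'   endosymbiont fraction; larger values give less sample-to-sample spread.
#'   The default 25 lets 312 samples at mean 0.97 span roughly 0.78-0.9999.
#' @param base_concentration Symmetric Dirichlet concentration of the
#'   non-endosymbiont community; larger values give more even communities.
#' @param outbreak_taxa Number of taxa whose counts are concentrated in one
#'   randomly chosen replicate sample (0 for none).
#' @param outbreak_restriction Target share, in (0, 1], of an outbreak taxon's
#'   total counts that falls inside its single home replicate.
#' @param depth_range Length-2 integer vector `(min, max)`; per-sample read
#'   depths are drawn uniformly from this range. The default matches the
#'   301,562-853,907 per-sample range typical of a MiSeq 16S run.
#' @param seed Integer seed; generation is bit-reproducible for a fixed seed.
#'
#' @return An object of class `community_params` (a list).
#' @export
community_params <- function(n_taxa = 78L,
                             endosymbiont_index = 1L,
                             endosymbiont_fraction = 0.97,
                             focal_concentration = 25,
                             base_concentration = 0.5,
                             outbreak_taxa = 8L,
                             outbreak_restriction = 0.95,
                             depth_range = c(301562L, 853907L),
                             seed = 1L) {
  if (n_taxa < 2) abort_bad_input("`n_taxa` must be at least 2.")
  if (endosymbiont_index < 1 || endosymbiont_index > n_taxa) {
    abort_bad_input("`endosymbiont_index` must index a taxon.")
  }
  if (endosymbiont_fraction < 0 || endosymbiont_fraction >= 1) {
    abort_bad_input("`endosymbiont_fraction` must lie in [0, 1).")
  }
  if (outbreak_taxa < 0 || outbreak_taxa >= n_taxa - 1) {
    abort_bad_input("`outbreak_taxa` must be less than n_taxa - 1.")
  }
  if (outbreak_restriction <= 0 || outbreak_restriction > 1) {
    abort_bad_input("`outbreak_restriction` must lie in (0, 1].")
  }
  if (length(depth_range) != 2 || depth_range[1] > depth_range[2] ||
      depth_range[1] < 1) {
    abort_bad_input("`depth_range` must be (min, max) with 1 <= min <= max.")
  }
  if (base_concentration <= 0 || focal_concentration <= 0) {
    abort_bad_input("concentration parameters must be positive.")
  }
  structure(
    list(
      n_taxa = as.integer(n_taxa),
      endosymbiont_index = as.integer(endosymbiont_index),
      endosymbiont_fraction = endosymbiont_fraction,
      focal_concentration = focal_concentration,
      base_concentration = base_concentration,
      outbreak_taxa = as.integer(outbreak_taxa),
      outbreak_restriction = outbreak_restriction,
      depth_range = as.integer(depth_range),
      seed = as.integer(seed)
    ),
    class = "community_params"
  )
}

# internal: one symmetric Dirichlet draw of length k
rdirichlet_sym <- function(k, alpha) {
  g <- rgamma(k, shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, k) # numerically degenerate alpha; fall back to uniform
  g / sum(g)
}

#' Generate a synthetic taxon-by-sample count table
#'
#' Draws, for every sample in `design`, a read depth uniform on the configured
#' range and a multinomial count vector whose expected composition is: the
#' endosymbiont at a Beta-distributed per-sample fraction; outbreak taxa with
#' almost all of their mass inside one randomly chosen home sample; and the
#' remaining taxa at symmetric-Dirichlet relative abundances (a
#' Dirichlet-multinomial community).
#'
#' @param design Tibble of sample metadata from [generate_design()].
#' @param params A [community_params()].
#' @return A wide count tibble (`taxon_id` plus one integer column per sample).
#'   Taxa are named `taxon_001`, ... except the endosymbiont row, named
#'   `"endosymbiont"`. Attributes `outbreak_taxa` (taxon ids) and
#'   `outbreak_home` (their home sample ids) record the planted outbreaks.
#' @examples
#' design <- generate_design(greenbug_design())
#' counts <- generate_counts(design, community_params(seed = 7))
#' dim(counts)
#' @export
generate_counts <- function(design, params) {
  if (!inherits(params, "community_params")) {
    abort_bad_input("`params` must be created by community_params().")
  }
  if (!is.data.frame(design) || nrow(design) == 0 ||
      !"sample_id" %in% names(design)) {
    abort_bad_input("`design` must be a nonempty metadata data frame with a `sample_id` column.")
  }
  withr::local_seed(params$seed)

  n_taxa <- params$n_taxa
  n_samp <- nrow(design)
  focal <- params$endosymbiont_index
  taxa <- sprintf("taxon_%03d", seq_len(n_taxa))
  taxa[focal] <- "endosymbiont"

  nonfocal <- setdiff(seq_len(n_taxa), focal)
  outbreak <- if (params$outbreak_taxa > 0) {
    sort(sample(nonfocal, params$outbreak_taxa))
  } else integer(0)
  ordinary <- setdiff(nonfocal, outbreak)
  homes <- if (length(outbreak)) sample.int(n_samp, length(outbreak), replace = TRUE) else integer(0)

  depths <- sample.int(params$depth_range[2] - params$depth_range[1] + 1L,
                       n_samp, replace = TRUE) + params$depth_range[1] - 1L

  ef <- params$endosymbiont_fraction
  fc <- params$focal_concentration
  focal_frac <- if (ef == 0) rep(0, n_samp) else rbeta(n_samp, ef * fc, (1 - ef) * fc)

  # Outbreak taxa take the within-non-focal share W in their home sample. The
  # leakage weight elsewhere is solved against the realized non-focal read
  # masses so that the taxon's expected share of its own total inside the home
  # replicate equals the configured restriction:
  #   sum_{s != h} w_t nm_s = (1 - r)/r * W * nm_h,  nm_s = (1 - f_s) depth_s
  r <- params$outbreak_restriction
  W <- 0.2
  nm <- (1 - focal_frac) * depths
  w_else <- vapply(seq_along(outbreak), function(k) {
    h <- homes[k]
    other_mass <- sum(nm[-h])
    if (n_samp < 2 || r == 1 || other_mass == 0) return(0)
    (1 - r) / r * W * nm[h] / other_mass
  }, numeric(1))

  counts <- matrix(0L, n_taxa, n_samp, dimnames = list(taxa, design$sample_id))
  for (s in seq_len(n_samp)) {
    nf <- numeric(n_taxa)
    ob_w <- numeric(length(outbreak))
    if (length(outbreak)) {
      ob_w <- ifelse(homes == s, W, w_else)
      ob_w <- pmin(ob_w, 0.9 / max(1, length(outbreak))) # keep total outbreak mass < 0.9
      nf[outbreak] <- ob_w
    }
    rest <- max(0, 1 - sum(ob_w))
    nf[ordinary] <- rest * rdirichlet_sym(length(ordinary), params$base_concentration)
    p <- nf / sum(nf) * (1 - focal_frac[s])
    p[focal] <- focal_frac[s]
    counts[, s] <- rmultinom(1, depths[s], p)[, 1]
  }

  out <- matrix_to_counts(counts)
  attr(out, "outbreak_taxa") <- taxa[outbreak]
  attr(out, "outbreak_home") <- design$sample_id[homes]
  out
}

#' Generate a random rooted binary tree over a set of taxa
#'
#' Produces a rooted, binary tree with strictly positive branch lengths and
#' the given taxa as leaf labels, for use as the phylogeny behind UniFrac
#' when no estimated tree is available.
#'
#' @param taxa Character vector of unique taxon identifiers (>= 2).
#' @param seed Integer seed.
#' @return An [ape::phylo] object. Serialize with [ape::write.tree()]; the
#'   newick round-trip is lossless.
#' @export
generate_tree <- function(taxa, seed = 1L) {
  taxa <- as.character(taxa)
  if (length(taxa) < 2) abort_bad_input("need at least 2 taxa for a tree.")
  if (anyDuplicated(taxa)) abort_bad_input("duplicate taxon names in `taxa`.")
  withr::local_seed(as.integer(seed))
  tr <- ape::rtree(length(taxa), rooted = TRUE, tip.label = taxa,
                   br = function(n) runif(n, 0.05, 1))
  tr
}
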