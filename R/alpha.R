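#' Shannon entropy of one sample
#'
#' `H = -sum p_i log p_i` in nats, over the nonzero relative abundances
#' `p_i = count_i / total`.
#'
#' @param x Nonnegative count (or abundance) vector with positive total.
#' @return Shannon entropy in nats.
#' @export
shannon <- function(x) {
  if (length(x) == 0) abort_bad_input("empty abundance vector.")
  if (any(x < 0)) abort_bad_input("negative abundances.")
  total <- sum(x)
  if (total <= 0) abort_bad_input("total abundance must be positive.")
  p <- x[x > 0] / total
  -sum(p * log(p))
}

#' Hill number of order 1 (effective number of species)
#'
#' `exp(H)` for Shannon entropy `H`; equals `S` for a perfectly even
#' community of `S` taxa and 1 for a single-taxon community.
#'
#' @inheritParams shannon
#' @return Hill-1 diversity (>= 1 for any nonempty sample).
#' @export
hill1 <- function(x) exp(shannon(x))

#' Observed richness of one sample
#'
#' @inheritParams shannon
#' @return Number of taxa with strictly positive counts.
#' @export
observed_richness <- function(x) {
  if (any(x < 0)) abort_bad_input("negative abundances.")
  sum(x > 0)
}

#' Per-sample alpha diversity table
#'
#' @param counts Wide count tibble (`taxon_id` plus sample columns).
#' @return Tibble with one row per sample: `sample_id`, `shannon` (nats),
#'   `hill1`, `observed_richness`.
#' @examples
#' tbl <- tibble::tibble(taxon_id = c("a", "b"), s1 = c(90, 10), s2 = c(1, 1))
#' alpha_diversity(tbl)
#' @export
alpha_diversity <- function(counts) {
  m <- counts_matrix(counts)
  tibble(
    sample_id = colnames(m),
    shannon = apply(m, 2, shannon),
    hill1 = apply(m, 2, hill1),
    observed_richness = apply(m, 2, observed_richness)
  )
}
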