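#' Remove contaminant and unidentified taxa
#'
#' Drops rows whose taxon identifier matches a known reagent contaminant
#' (Ralstonia is a frequent resident of DNA extraction kits) and, optionally,
#' rows whose identifier marks an unidentified taxon. All other cells are
#' left untouched; absent contaminants make this a no-op.
#'
#' @param counts Wide count tibble (`taxon_id` first, sample columns after).
#' @param contaminant_taxa Character vector of taxon identifiers to drop.
#' @param drop_unidentified Drop rows whose identifier matches
#'   `unidentified_pattern`.
#' @param unidentified_pattern Regular expression (case-insensitive) marking
#'   unidentified taxa.
#' @return The filtered count tibble.
#' @export
filter_contaminants <- function(counts,
                                contaminant_taxa = "Ralstonia",
                                drop_unidentified = FALSE,
                                unidentified_pattern = "^unclassified|^unidentified") {
  counts_matrix(counts) # validate
  keep <- !(counts[[1]] %in% contaminant_taxa)
  if (drop_unidentified) {
    keep <- keep & !grepl(unidentified_pattern, counts[[1]], ignore.case = TRUE)
  }
  counts[keep, , drop = FALSE]
}

#' Zero out per-sample rare counts
#'
#' Within each sample, cells holding strictly less than
#' `threshold_fraction` of that sample's total reads are set to zero (the
#' comparison is strict, so a cell exactly at the threshold is kept). Taxa
#' left with no counts anywhere are dropped. The default 1e-4 implements a
#' "less than 0.01% of the sample's reads" rule.
#'
#' @param counts Wide count tibble.
#' @param threshold_fraction Per-sample relative-abundance threshold in [0, 1).
#' @return The filtered count tibble.
#' @export
filter_rare <- function(counts, threshold_fraction = 1e-4) {
  if (threshold_fraction < 0 || threshold_fraction >= 1) {
    abort_bad_input("`threshold_fraction` must lie in [0, 1).")
  }
  m <- counts_matrix(counts)
  tot <- colSums(m)
  if (any(tot == 0)) {
    abort_bad_input(paste0(
      "zero-depth sample(s): ", paste(colnames(m)[tot == 0], collapse = ", ")
    ))
  }
  rel <- sweep(m, 2, tot, "/")
  m[rel < threshold_fraction] <- 0
  m <- m[rowSums(m) > 0, , drop = FALSE]
  matrix_to_counts(m)
}

#' Normalize sample depths by scaling with ranked subsampling
#'
#' Scales every sample to a common target depth deterministically: counts are
#' multiplied by `target / depth`, integer parts are kept, and the remaining
#' units (target minus the sum of integer parts) are handed out one each to
#' the cells with the largest fractional parts. Fractional-part ties go to
#' the larger scaled count first, then to the earlier taxon. Every output
#' column sums exactly to the target.
#'
#' @param counts Wide count tibble.
#' @param target_depth Positive integer target, or `"min"` (the default) for
#'   the smallest sample depth present.
#' @return Count tibble with all column sums equal to the target depth.
#' @examples
#' tbl <- tibble::tibble(taxon_id = c("a", "b", "c"), s1 = c(60, 30, 10))
#' srs_normalize(tbl, 10) # 6, 3, 1
#' @export
srs_normalize <- function(counts, target_depth = "min") {
  m <- counts_matrix(counts)
  depths <- colSums(m)
  if (identical(target_depth, "min")) target_depth <- min(depths)
  target_depth <- as.numeric(target_depth)
  if (target_depth < 1) abort_bad_input("`target_depth` must be >= 1.")
  low <- depths < target_depth
  if (any(low)) {
    abort_bad_input(paste0(
      "target depth ", format(target_depth, scientific = FALSE),
      " exceeds the depth of sample(s): ",
      paste(colnames(m)[low], collapse = ", ")
    ))
  }
  out <- m
  for (s in seq_len(ncol(m))) {
    scaled <- m[, s] * target_depth / depths[s]
    fl <- floor(scaled)
    rem <- as.integer(round(target_depth - sum(fl)))
    x <- fl
    if (rem > 0) {
      frac <- scaled - fl
      ord <- order(-frac, -scaled, seq_along(scaled), method = "radix")
      bump <- ord[seq_len(rem)]
      x[bump] <- x[bump] + 1
    }
    out[, s] <- x
  }
  storage.mode(out) <- "double"
  matrix_to_counts(out)
}

# internal: one without-replacement subsample of size d from integer counts x,
# by sequential hypergeometric draws over taxa
subsample_counts <- function(x, d) {
  total <- sum(x)
  stopifnot(d <= total)
  out <- numeric(length(x))
  remaining <- total
  need <- d
  for (i in seq_along(x)) {
    if (need == 0) break
    if (x[i] == 0) next
    if (remaining == x[i]) {
      out[i] <- need
      need <- 0
      break
    }
    k <- rhyper(1, x[i], remaining - x[i], need)
    out[i] <- k
    need <- need - k
    remaining <- remaining - x[i]
  }
  out
}

# internal: exact expected richness of a without-replacement subsample of
# size d: sum_i (1 - C(T - n_i, d) / C(T, d)), evaluated with log-binomials
expected_richness <- function(x, d) {
  x <- x[x > 0]
  total <- sum(x)
  stopifnot(d <= total)
  lp_absent <- lchoose(total - x, d) - lchoose(total, d)
  lp_absent[total - x < d] <- -Inf
  sum(1 - exp(lp_absent))
}

#' Rarefaction curves with Monte-Carlo and exact expectations
#'
#' For each sample and each depth `d` on the grid `step, 2*step, ...` (plus
#' the sample's own total), reports the mean observed richness across random
#' without-replacement subsamples of size `d` and the exact hypergeometric
#' expectation `E[S_d] = sum_i (1 - C(T - n_i, d)/C(T, d))`. Depths beyond a
#' sample's total are skipped for that sample, so each curve ends at its own
#' depth.
#'
#' @param counts Wide count tibble.
#' @param step Depth increment of the survey grid.
#' @param max_depth Largest grid depth; defaults to the largest sample total.
#' @param draws Number of random subsamples per depth.
#' @param seed Integer seed for the Monte-Carlo draws.
#' @return Tibble of class `rarefaction_tbl`: `sample_id`, `depth`,
#'   `mean_richness`, `exact_richness`.
#' @export
rarefaction_curve <- function(counts, step = 25000, max_depth = NULL,
                              draws = 10, seed = 1L) {
  if (step < 1) abort_bad_input("`step` must be >= 1.")
  m <- counts_matrix(counts)
  withr::local_seed(as.integer(seed))
  totals <- colSums(m)
  if (is.null(max_depth)) max_depth <- max(totals)
  rows <- purrr::map(seq_len(ncol(m)), function(s) {
    x <- m[, s]
    grid <- unique(c(seq(step, min(max_depth, totals[s]), by = step), totals[s]))
    grid <- grid[grid >= 1]
    purrr::map(grid, function(d) {
      mc <- mean(purrr::map_dbl(seq_len(draws), function(i) {
        sum(subsample_counts(x, d) > 0)
      }))
      tibble(
        sample_id = colnames(m)[s],
        depth = d,
        mean_richness = mc,
        exact_richness = expected_richness(x, d)
      )
    }) %>% bind_rows()
  }) %>% bind_rows()
  class(rows) <- c("rarefaction_tbl", class(rows))
  rows
}

#' @rdname rarefaction_curve
#' @method autoplot rarefaction_tbl
#' @param object A `rarefaction_tbl`.
#' @param ... Unused.
#' @export
autoplot.rarefaction_tbl <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$depth, y = .data$exact_richness, group = .data$sample_id
  )) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "reads subsampled", y = "expected taxa observed",
                  title = "Rarefaction survey")
}
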