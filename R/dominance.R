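#' Restriction fractions: how confined is each taxon?
#'
#' For every taxon, the largest share of its total counts found inside a
#' single treatment (one biotype x cultivar x timepoint cell of the design)
#' and inside a single replicate plant within a treatment. A taxon evenly
#' spread over the experiment scores near `1 / n_cells`; an outbreak taxon
#' confined to one plant scores near 1 on both. The best replicate always
#' lies inside some treatment, so `replicate_fraction <= treatment_fraction`.
#'
#' @param counts Wide count tibble.
#' @param metadata Sample metadata with columns `sample_id`, `biotype`,
#'   `cultivar`, `timepoint_day`, `replicate` (day-0 baselines form their own
#'   cells keyed by biotype, source cultivar and day 0).
#' @return Tibble sorted by decreasing `treatment_fraction`: `taxon_id`,
#'   `treatment_fraction`, `replicate_fraction`, `total_count`. Taxa with no
#'   counts are omitted.
#' @export
restriction_fractions <- function(counts, metadata) {
  m <- counts_matrix(counts)
  need <- c("sample_id", "biotype", "cultivar", "timepoint_day", "replicate")
  if (!is.data.frame(metadata) || !all(need %in% names(metadata))) {
    abort_bad_input(paste0("`metadata` must contain columns: ",
                           paste(need, collapse = ", ")))
  }
  missing <- setdiff(colnames(m), metadata$sample_id)
  if (length(missing)) {
    abort_bad_input(paste0("samples without metadata: ",
                           paste(missing, collapse = ", ")))
  }
  md <- metadata[match(colnames(m), metadata$sample_id), ]
  cell <- paste(md$biotype, md$cultivar, md$timepoint_day, sep = "\r")
  rep_cell <- paste(cell, md$replicate, sep = "\r")

  sum_by <- function(groups) {
    g <- factor(groups, levels = unique(groups))
    t(rowsum(t(m), g)) # taxa x groups
  }
  cell_sums <- sum_by(cell)
  rep_sums <- sum_by(rep_cell)
  totals <- rowSums(m)
  keep <- totals > 0
  tibble(
    taxon_id = rownames(m)[keep],
    treatment_fraction = unname(apply(cell_sums[keep, , drop = FALSE], 1, max) / totals[keep]),
    replicate_fraction = unname(apply(rep_sums[keep, , drop = FALSE], 1, max) / totals[keep]),
    total_count = unname(totals[keep])
  ) %>%
    arrange(desc(.data$treatment_fraction))
}

# internal: resolve per-taxon totals from either a wide count table or an
# explicit totals column
taxon_totals <- function(x, total = NULL) {
  total <- enquo(total)
  if (!quo_is_null(total)) {
    tot <- dplyr::pull(x, !!total)
  } else {
    tot <- rowSums(counts_matrix(x))
  }
  setNames(as.numeric(tot), as.character(x[[1]]))
}

#' Ratio of two taxa's total counts
#'
#' @param x Wide count tibble, or any data frame whose first column is a
#'   taxon identifier when `total` names a totals column.
#' @param taxon_a,taxon_b Taxon identifiers; the ratio is `total_a / total_b`.
#' @param total Optional tidy-select column holding precomputed totals (for
#'   published summary tables); otherwise totals are row sums over samples.
#' @return The abundance ratio at full precision (round for display).
#' @examples
#' gs <- greenbug_genus_summary()
#' round(abundance_ratio(gs, "Buchnera", "Pseudomonas", total = total_count))
#' @export
abundance_ratio <- function(x, taxon_a, taxon_b, total = NULL) {
  tot <- taxon_totals(x, {{ total }})
  for (tx in c(taxon_a, taxon_b)) {
    if (!tx %in% names(tot)) abort_bad_input(paste0("taxon not found: ", tx))
  }
  if (tot[[taxon_b]] == 0) abort_bad_input("denominator taxon has zero total count.")
  unname(tot[[taxon_a]] / tot[[taxon_b]])
}

#' Number of taxa above a total-count threshold
#'
#' @inheritParams abundance_ratio
#' @param threshold Count threshold; the comparison is strict (`total >
#'   threshold`).
#' @return Integer count of taxa, nonincreasing in `threshold`.
#' @export
count_taxa_above <- function(x, threshold, total = NULL) {
  tot <- taxon_totals(x, {{ total }})
  sum(tot > threshold)
}

#' Range of one taxon's per-sample relative abundance
#'
#' @param counts Wide count tibble with positive sample depths.
#' @param taxon Taxon identifier.
#' @return Named numeric vector `c(min = ..., max = ...)` of the taxon's
#'   share of reads across samples.
#' @export
focal_fraction_range <- function(counts, taxon) {
  m <- counts_matrix(counts)
  if (!taxon %in% rownames(m)) abort_bad_input(paste0("taxon not found: ", taxon))
  depths <- colSums(m)
  if (any(depths <= 0)) abort_bad_input("all sample depths must be positive.")
  f <- m[taxon, ] / depths
  c(min = min(f), max = max(f))
}

#' Published genus-level restriction summary for the greenbug microbiome
#'
#' Loads the bundled genus summary from a greenbug (Schizaphis graminum) 16S
#' survey: for each of 79 genus-level groups, the largest fraction of its
#' total counts confined to a single treatment and to a single replicate,
#' plus its total normalized count. Buchnera dominates with about 92 million
#' counts while being the least restricted genus; several minor genera are
#' almost entirely confined to one replicate plant.
#'
#' @return Tibble: `genus`, `treatment_fraction`, `replicate_fraction`,
#'   `total_count`.
#' @export
greenbug_genus_summary <- function() {
  path <- system.file("extdata", "greenbug_genus_restriction.tsv",
                      package = "aphidbiome", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE)
}
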