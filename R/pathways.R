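#' Rank pathways by abundance
#'
#' Adds a dense rank column: rank 1 is the most abundant pathway, ties are
#' broken lexicographically by `pathway_id` so ranking is deterministic and
#' invariant to row order.
#'
#' @param pathways Data frame with columns `pathway_id` and `count`
#'   (an optional `pathway_name` is carried along).
#' @return The input as a tibble, sorted by rank, with a `rank` column.
#' @export
rank_pathways <- function(pathways) {
  if (!is.data.frame(pathways) || nrow(pathways) == 0 ||
      !all(c("pathway_id", "count") %in% names(pathways))) {
    abort_bad_input("`pathways` must be a nonempty data frame with `pathway_id` and `count`.")
  }
  if (anyDuplicated(pathways$pathway_id)) {
    abort_bad_input("duplicate pathway_id in `pathways`.")
  }
  if (any(pathways$count < 0)) abort_bad_input("negative pathway counts.")
  as_tibble(pathways) %>%
    arrange(desc(.data$count), .data$pathway_id) %>%
    mutate(rank = row_number())
}

#' Compare pathway rankings between a focal taxon and the rest
#'
#' Full outer join of two pathway tables on `pathway_id`; each side is ranked
#' among its own present pathways (count > 0). A pathway with no row or a
#' zero count in a subset is absent there (`NA` rank), so the comparison
#' reveals which pathways the focal taxon has lost relative to the rest of
#' the community.
#'
#' @param focal Pathway table (`pathway_id`, `count`, optional
#'   `pathway_name`) for the focal taxon.
#' @param others Pathway table for the rest of the community.
#' @return Tibble of class `rank_comparison`: `pathway_id`, `pathway_name`,
#'   `count_focal`, `rank_focal`, `count_others`, `rank_others`, sorted by
#'   `rank_others` then `rank_focal`.
#' @export
compare_ranks <- function(focal, others) {
  prep <- function(tbl, suffix) {
    present <- tbl[!is.na(tbl$count) & tbl$count > 0, , drop = FALSE]
    ranked <- if (nrow(present)) rank_pathways(present) else
      tibble(pathway_id = character(), count = numeric(), rank = integer())
    keep <- intersect(c("pathway_id", "pathway_name", "count", "rank"), names(ranked))
    ranked <- ranked[, keep]
    names(ranked)[names(ranked) == "count"] <- paste0("count_", suffix)
    names(ranked)[names(ranked) == "rank"] <- paste0("rank_", suffix)
    ranked
  }
  f <- prep(as_tibble(focal), "focal")
  o <- prep(as_tibble(others), "others")
  by <- intersect(intersect(names(f), names(o)), c("pathway_id", "pathway_name"))
  out <- full_join(f, o, by = by) %>%
    mutate(
      count_focal = tidyr::replace_na(.data$count_focal, 0),
      count_others = tidyr::replace_na(.data$count_others, 0)
    ) %>%
    arrange(is.na(.data$rank_others), .data$rank_others, .data$rank_focal)
  class(out) <- c("rank_comparison", class(out))
  out
}

#' Count pathways lost by the focal taxon
#'
#' A pathway is "lost" when it is present in the rest of the community but
#' absent from the focal taxon. Besides the total, reports for each `k` how
#' many of the `k` lowest-ranking pathways (by the others' abundance ranking)
#' are lost — low-ranking pathways are the most dispensable, so a focal taxon
#' under genome reduction loses disproportionately from the bottom of the
#' ranking.
#'
#' @param comparison A [compare_ranks()] result.
#' @param k_list Integer vector of lowest-`k` window sizes. Values exceeding
#'   the number of pathways present in others are clipped with a warning.
#' @return Tibble: `k`, `lost` (lost among the `k` lowest-ranked), plus the
#'   attribute-free convention that the row with `k = n_others` equals the
#'   total number of lost pathways.
#' @export
lost_pathway_summary <- function(comparison, k_list = c(100L, 200L)) {
  if (!inherits(comparison, "rank_comparison")) {
    abort_bad_input("`comparison` must come from compare_ranks().")
  }
  in_others <- comparison[!is.na(comparison$rank_others), , drop = FALSE]
  n_others <- nrow(in_others)
  k_list <- as.integer(k_list)
  if (any(k_list < 1)) abort_bad_input("`k` values must be >= 1.")
  if (any(k_list > n_others)) {
    warning("k value(s) exceed the number of pathways present in others; clipped.",
            call. = FALSE)
    k_list <- pmin(k_list, n_others)
  }
  k_list <- sort(unique(c(k_list, n_others)))
  lost_flag <- is.na(in_others$rank_focal)
  # lowest-ranked = largest rank_others values
  ord <- order(in_others$rank_others, decreasing = TRUE)
  lost_in_window <- cumsum(lost_flag[ord])
  tibble(
    k = k_list,
    lost = lost_in_window[k_list],
    n_others = n_others,
    total_lost = sum(lost_flag)
  )
}

#' Read and write pathway tables
#'
#' TSV with columns `pathway_id`, `pathway_name`, `count`.
#'
#' @param path File path.
#' @return [read_pathway_table()] returns a tibble.
#' @export
read_pathway_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_pathway_table
#' @param pathways Pathway table to write.
#' @export
write_pathway_table <- function(pathways, path) {
  readr::write_tsv(pathways, path)
  invisible(path)
}
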