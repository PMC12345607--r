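#' Read and write taxon-by-sample count tables
#'
#' Count tables are TSV files whose first column is `taxon_id` and whose
#' remaining columns are per-sample integer counts.
#'
#' @param path File path.
#' @return [read_count_table()] returns a wide count tibble.
#' @export
read_count_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  counts_matrix(out) # validate shape
  out
}

#' @rdname read_count_table
#' @param counts Count tibble to write.
#' @export
write_count_table <- function(counts, path) {
  counts_matrix(counts)
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read and write sample metadata
#'
#' CSV with header `sample_id,biotype,host_species,cultivar,timepoint_day,replicate`.
#'
#' @param path File path.
#' @return [read_sample_metadata()] returns a tibble.
#' @export
read_sample_metadata <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname read_sample_metadata
#' @param metadata Metadata tibble to write.
#' @export
write_sample_metadata <- function(metadata, path) {
  readr::write_csv(metadata, path)
  invisible(path)
}

#' Read and write square dissimilarity matrices
#'
#' Square TSV with sample identifiers in both the header and the first
#' column.
#'
#' @param path File path.
#' @return [read_dissimilarity()] returns a `dissimilarity` object.
#' @export
read_dissimilarity <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  new_dissimilarity(m)
}

#' @rdname read_dissimilarity
#' @param d A `dissimilarity` object to write.
#' @export
write_dissimilarity <- function(d, path) {
  stopifnot(inherits(d, "dissim"))
  df <- as_tibble(d$values) %>%
    mutate(sample_id = d$sample_ids, .before = 1)
  readr::write_tsv(df, path)
  invisible(path)
}
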