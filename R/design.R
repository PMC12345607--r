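#' Describe a factorial infestation sampling design
#'
#' A design spec captures the structure of an aphid infestation experiment:
#' aphid biotypes crossed with host cultivars and post-infestation sampling
#' days, a fixed number of replicate plants per cell, plus optional day-0
#' baseline samples taken from the source colony cultivar before placement.
#'
#' @param biotypes Character vector of aphid biotype labels (e.g. `"E"`, `"K"`).
#' @param cultivars Data frame with columns `cultivar` and `host_species`
#'   mapping each cultivar to exactly one host species.
#' @param timepoints_post Positive integer vector of post-infestation sampling
#'   days (day 0 is handled by the baseline arguments).
#' @param replicates_per_cell Number of replicate plants sampled per
#'   biotype x cultivar x timepoint cell.
#' @param baseline_replicates_per_biotype Number of day-0 baseline samples per
#'   biotype, all taken on `baseline_cultivar`.
#' @param baseline_cultivar Cultivar of the source colony used for day-0
#'   baselines; must appear in `cultivars` when baselines are requested.
#'
#' @return An object of class `design_spec` (a list).
#' @seealso [generate_design()], [greenbug_design()]
#' @export
design_spec <- function(biotypes,
                        cultivars,
                        timepoints_post,
                        replicates_per_cell,
                        baseline_replicates_per_biotype = 0L,
                        baseline_cultivar = NULL) {
  if (length(biotypes) == 0) abort_bad_input("`biotypes` must be nonempty.")
  if (!is.data.frame(cultivars) || nrow(cultivars) == 0 ||
      !all(c("cultivar", "host_species") %in% names(cultivars))) {
    abort_bad_input("`cultivars` must be a nonempty data frame with columns `cultivar` and `host_species`.")
  }
  if (anyDuplicated(cultivars$cultivar)) {
    abort_bad_input("each cultivar must map to exactly one host species.")
  }
  if (length(timepoints_post) == 0 || any(timepoints_post <= 0)) {
    abort_bad_input("`timepoints_post` must be positive days post infestation.")
  }
  if (replicates_per_cell < 1) abort_bad_input("`replicates_per_cell` must be >= 1.")
  if (baseline_replicates_per_biotype < 0) {
    abort_bad_input("`baseline_replicates_per_biotype` must be >= 0.")
  }
  if (baseline_replicates_per_biotype > 0) {
    if (is.null(baseline_cultivar) || !baseline_cultivar %in% cultivars$cultivar) {
      abort_bad_input("`baseline_cultivar` must be one of the listed cultivars when baselines are requested.")
    }
  }
  structure(
    list(
      biotypes = as.character(biotypes),
      cultivars = as_tibble(cultivars[, c("cultivar", "host_species")]),
      timepoints_post = as.integer(sort(unique(timepoints_post))),
      replicates_per_cell = as.integer(replicates_per_cell),
      baseline_replicates_per_biotype = as.integer(baseline_replicates_per_biotype),
      baseline_cultivar = baseline_cultivar
    ),
    class = "design_spec"
  )
}

#' Total number of samples implied by a design spec
#'
#' @param spec A [design_spec()].
#' @return Integer sample count:
#'   `|biotypes| * |cultivars| * |timepoints| * replicates + |biotypes| * baselines`.
#' @export
n_samples <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  length(spec$biotypes) * nrow(spec$cultivars) * length(spec$timepoints_post) *
    spec$replicates_per_cell +
    length(spec$biotypes) * spec$baseline_replicates_per_biotype
}

#' The greenbug study design
#'
#' The default design used throughout the package: greenbug (Schizaphis
#' graminum) biotypes E and K on 17 cultivars of five host species (wheat,
#' sorghum, barley, rye, Aegilops triuncialis), sampled 2, 4 and 8 days after
#' infestation from 3 replicate plants per cell, plus 3 day-0 baseline samples
#' per biotype taken from the source colony on wheat cv. Newton: 312 samples
#' in total.
#'
#' @return A [design_spec()].
#' @export
greenbug_design <- function() {
  cultivars <- tibble(
    cultivar = c(
      "Newton", "Custer", "Amigo", "Largo", "CI17882", "GRS1201",
      "TX7000", "TX2737", "TX2783", "DzhugaraBelaya",
      "Wintermalt", "Jao", "Post90",
      "Elbon", "InsaveFA",
      "TA1675", "TA1695"
    ),
    host_species = c(
      rep("wheat", 6),
      rep("sorghum", 4),
      rep("barley", 3),
      rep("rye", 2),
      rep("aegilops", 2)
    )
  )
  design_spec(
    biotypes = c("E", "K"),
    cultivars = cultivars,
    timepoints_post = c(2L, 4L, 8L),
    replicates_per_cell = 3L,
    baseline_replicates_per_biotype = 3L,
    baseline_cultivar = "Newton"
  )
}

#' Expand a design spec into per-sample metadata
#'
#' Enumerates every sample the design implies, one row per replicate plant.
#' Day-0 baseline samples carry the baseline cultivar and `timepoint_day = 0`.
#'
#' @param spec A [design_spec()].
#' @return A tibble with columns `sample_id`, `biotype`, `host_species`,
#'   `cultivar`, `timepoint_day`, `replicate`; exactly [n_samples()] rows.
#' @examples
#' design <- generate_design(greenbug_design())
#' nrow(design) # 312
#' @export
generate_design <- function(spec) {
  if (!inherits(spec, "design_spec")) {
    abort_bad_input("`spec` must be created by design_spec().")
  }
  cells <- tidyr::expand_grid(
    biotype = spec$biotypes,
    cultivar = spec$cultivars$cultivar,
    timepoint_day = spec$timepoints_post,
    replicate = seq_len(spec$replicates_per_cell)
  )
  if (spec$baseline_replicates_per_biotype > 0) {
    baseline <- tidyr::expand_grid(
      biotype = spec$biotypes,
      cultivar = spec$baseline_cultivar,
      timepoint_day = 0L,
      replicate = seq_len(spec$baseline_replicates_per_biotype)
    )
    cells <- bind_rows(baseline, cells)
  }
  out <- cells %>%
    left_join(spec$cultivars, by = "cultivar") %>%
    mutate(
      sample_id = sprintf(
        "%s_%s_d%d_r%d", .data$biotype, .data$cultivar,
        .data$timepoint_day, .data$replicate
      )
    ) %>%
    select("sample_id", "biotype", "host_species", "cultivar",
           "timepoint_day", "replicate") %>%
    arrange(.data$biotype, .data$cultivar, .data$timepoint_day, .data$replicate)
  stopifnot(!anyDuplicated(out$sample_id))
  out
}
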