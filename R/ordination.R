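#' Principal coordinates analysis
#'
#' Classical metric scaling: eigendecomposition of the Gower double-centred
#' matrix `-1/2 C D^2 C` (`C = I - 11'/n`). Coordinates come from the
#' positive eigenvalues (axis `k` scaled by `sqrt(lambda_k)`); negative
#' eigenvalues, which arise for non-Euclidean dissimilarities, are reported
#' but contribute no axes.
#'
#' @param d A `dissimilarity` object (see [beta_dissimilarity()]) or a
#'   symmetric matrix with zero diagonal.
#' @param n_axes Maximum number of axes to return.
#' @return A `pcoa_result`: list with `sample_ids`, `eigenvalues` (all,
#'   descending) and the `coordinates` matrix (samples x axes).
#' @export
pcoa <- function(d, n_axes = NULL) {
  dm <- if (inherits(d, "dissim")) d$values else as.matrix(d)
  if (!isSymmetric(unname(dm))) abort_bad_input("`d` must be symmetric.")
  n <- nrow(dm)
  ids <- rownames(dm) %||% paste0("s", seq_len(n))
  a <- -0.5 * dm^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  eig <- eigen(g, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-10
  pos <- which(eig$values > tol)
  if (!is.null(n_axes)) pos <- pos[seq_len(min(n_axes, length(pos)))]
  coords <- if (length(pos)) {
    eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(eig$values[pos]), length(pos))
  } else {
    matrix(0, n, 0)
  }
  dimnames(coords) <- list(ids, if (length(pos)) paste0("Axis", seq_along(pos)) else NULL)
  structure(
    list(sample_ids = ids, eigenvalues = eig$values, coordinates = coords),
    class = "pcoa_result"
  )
}

#' @export
print.pcoa_result <- function(x, ...) {
  pos <- sum(x$eigenvalues > 0)
  rel <- x$eigenvalues[x$eigenvalues > 0] / sum(x$eigenvalues[x$eigenvalues > 0])
  cat("PCoA over", length(x$sample_ids), "samples:", pos, "positive axes\n")
  cat("variance explained by first axes:",
      paste0(round(100 * utils::head(rel, 3), 1), "%", collapse = ", "), "\n")
  invisible(x)
}

#' @rdname pcoa
#' @method tidy pcoa_result
#' @param x A `pcoa_result`.
#' @param ... Unused.
#' @export
tidy.pcoa_result <- function(x, ...) {
  as_tibble(x$coordinates) %>%
    mutate(sample_id = x$sample_ids, .before = 1)
}

#' @rdname pcoa
#' @method glance pcoa_result
#' @export
glance.pcoa_result <- function(x, ...) {
  pos <- x$eigenvalues[x$eigenvalues > 0]
  tibble(
    n_samples = length(x$sample_ids),
    n_positive_axes = length(pos),
    prop_axis1 = if (length(pos)) pos[1] / sum(pos) else NA_real_,
    min_eigenvalue = min(x$eigenvalues)
  )
}

#' @rdname pcoa
#' @method autoplot pcoa_result
#' @param object A `pcoa_result`.
#' @param colour Optional vector (length = samples) used to colour points.
#' @export
autoplot.pcoa_result <- function(object, colour = NULL, ...) {
  df <- tidy(object)
  if (ncol(object$coordinates) < 2) abort_bad_input("need at least 2 axes to plot.")
  pos <- object$eigenvalues[object$eigenvalues > 0]
  pct <- round(100 * pos[1:2] / sum(pos), 1)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Axis1, y = .data$Axis2))
  if (!is.null(colour)) {
    df$colour <- colour
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Axis1, y = .data$Axis2,
                                          colour = .data$colour))
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = paste0("Axis 1 (", pct[1], "%)"),
                  y = paste0("Axis 2 (", pct[2], "%)"))
}

# internal: one-way pseudo-F from squared distances.
# SS_total = sum_{i<j} d_ij^2 / n ; SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g
pseudo_f_oneway <- function(d2, groups) {
  n <- nrow(d2)
  g <- as.integer(factor(groups))
  k <- max(g)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (lev in seq_len(k)) {
    idx <- which(g == lev)
    if (length(idx) > 1) {
      sub <- d2[idx, idx]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ss_between <- ss_total - ss_within
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  list(f = f, ss_between = ss_between, ss_within = ss_within,
       df_between = k - 1L, df_within = n - k)
}

#' One-way PERMANOVA
#'
#' Permutational multivariate analysis of variance on a dissimilarity matrix:
#' the total sum of squared distances is partitioned into between- and
#' within-group components, giving a pseudo-F statistic whose null
#' distribution is obtained by permuting group labels. The p-value uses the
#' `(1 + #{F_perm >= F_obs}) / (1 + n_permutations)` convention, so the
#' smallest attainable p is `1 / (1 + n_permutations)`.
#'
#' @param d A `dissimilarity` object or symmetric matrix.
#' @param groups Vector of group labels, one per sample (>= 2 groups, each
#'   nonempty).
#' @param n_permutations Number of label permutations.
#' @param seed Integer seed for the permutations.
#' @param factor_name Label recorded in the result.
#' @return A `permanova_result`: factor, degrees of freedom, sums of squares,
#'   pseudo-F, R2, p-value and permutation count. Use [tidy()] for a tibble.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = 1L,
                      factor_name = "groups") {
  dm <- if (inherits(d, "dissim")) d$values else as.matrix(d)
  if (!isSymmetric(unname(dm))) abort_bad_input("`d` must be symmetric.")
  n <- nrow(dm)
  if (length(groups) != n) abort_bad_input("`groups` must have one label per sample.")
  tab <- table(groups)
  if (length(tab) < 2) abort_bad_input("need at least 2 groups.")
  if (any(tab == 0)) abort_bad_input("empty group level.")
  d2 <- dm^2
  obs <- pseudo_f_oneway(d2, groups)
  withr::local_seed(as.integer(seed))
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    fp <- pseudo_f_oneway(d2, groups[sample.int(n)])$f
    if (fp >= obs$f) exceed <- exceed + 1L
  }
  structure(
    list(
      factor = factor_name,
      df_between = obs$df_between,
      df_within = obs$df_within,
      ss_between = obs$ss_between,
      ss_within = obs$ss_within,
      pseudo_F = obs$f,
      r2 = obs$ss_between / (obs$ss_between + obs$ss_within),
      p_value = (1 + exceed) / (1 + n_permutations),
      n_permutations = as.integer(n_permutations)
    ),
    class = "permanova_result"
  )
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA (%s): pseudo-F(%d, %d) = %.4g, R2 = %.4f, p = %.4g (%d permutations)\n",
    x$factor, x$df_between, x$df_within, x$pseudo_F, x$r2, x$p_value,
    x$n_permutations
  ))
  invisible(x)
}

#' @rdname permanova
#' @method tidy permanova_result
#' @param x A `permanova_result`.
#' @param ... Unused.
#' @export
tidy.permanova_result <- function(x, ...) {
  tibble(
    factor = x$factor,
    df_between = x$df_between,
    df_within = x$df_within,
    ss_between = x$ss_between,
    ss_within = x$ss_within,
    pseudo_F = x$pseudo_F,
    r2 = x$r2,
    p_value = x$p_value,
    n_permutations = x$n_permutations
  )
}

#' @rdname permanova
#' @method glance permanova_result
#' @export
glance.permanova_result <- function(x, ...) {
  tibble(pseudo_F = x$pseudo_F, r2 = x$r2, p_value = x$p_value,
         n_permutations = x$n_permutations)
}

#' Pairwise PERMANOVA over factor levels
#'
#' Runs [permanova()] on the sub-matrix of every unordered pair of levels.
#' P-values are reported raw (no multiplicity adjustment).
#'
#' @inheritParams permanova
#' @param levels Optional subset of levels to compare (default: all observed).
#' @return Tibble with one tidy row per level pair, plus `level_a`, `level_b`.
#' @export
pairwise_permanova <- function(d, groups, levels = NULL,
                               n_permutations = 999, seed = 1L) {
  dm <- if (inherits(d, "dissim")) d$values else as.matrix(d)
  levels <- levels %||% sort(unique(as.character(groups)))
  if (length(levels) < 2) abort_bad_input("need at least 2 levels.")
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  purrr::map(pairs, function(pr) {
    idx <- which(groups %in% pr)
    res <- permanova(dm[idx, idx], groups[idx], n_permutations = n_permutations,
                     seed = seed, factor_name = paste(pr, collapse = " vs "))
    tidy(res) %>% mutate(level_a = pr[1], level_b = pr[2], .before = 1)
  }) %>% bind_rows()
}

#' Sequential (Type-I) PERMANOVA decomposition
#'
#' Multi-factor partition of a dissimilarity matrix in model-declaration
#' order, via the linear-model formulation on the Gower-centred matrix `G`:
#' each term's sum of squares is the increment in `trace(H G)` as its columns
#' join the design, and each term is tested against the residual by permuting
#' sample labels. This matches the sequential ("by terms") convention of
#' distance-based ANOVA programs. Interactions can be requested with `:` in
#' `factors` (e.g. `"biotype:host_species"`).
#'
#' @param d A `dissimilarity` object or symmetric matrix.
#' @param metadata Data frame of sample metadata aligned to the matrix order.
#' @param factors Character vector of metadata column names (or `a:b`
#'   interactions) in the order they enter the model.
#' @param n_permutations Number of permutations.
#' @param seed Integer seed.
#' @return Tibble with one row per term plus a `Residual` row: `term`, `df`,
#'   `ss`, `r2`, `pseudo_F`, `p_value`.
#' @export
permanova_sequential <- function(d, metadata, factors, n_permutations = 999,
                                 seed = 1L) {
  dm <- if (inherits(d, "dissim")) d$values else as.matrix(d)
  n <- nrow(dm)
  if (nrow(metadata) != n) abort_bad_input("`metadata` must align with `d`.")
  term_values <- lapply(factors, function(f) {
    parts <- strsplit(f, ":", fixed = TRUE)[[1]]
    bad <- setdiff(parts, names(metadata))
    if (length(bad)) abort_bad_input(paste0("unknown factor(s): ", paste(bad, collapse = ", ")))
    interaction(metadata[parts], drop = TRUE)
  })
  a <- -0.5 * dm^2
  g_mat <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)

  # trace(H G) for the cumulative design after each term
  fit_traces <- function(perm) {
    x <- matrix(1, n, 1)
    traces <- numeric(length(term_values))
    dfs <- integer(length(term_values))
    for (k in seq_along(term_values)) {
      mm <- stats::model.matrix(~f, data.frame(f = term_values[[k]][perm]))[, -1, drop = FALSE]
      x <- cbind(x, mm)
      qx <- qr(x)
      q_mat <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
      traces[k] <- sum((crossprod(q_mat, g_mat) * t(q_mat)))
      dfs[k] <- qx$rank - 1L
    }
    list(traces = traces, dfs = dfs)
  }

  ss_total <- sum(diag(g_mat))
  obs <- fit_traces(seq_len(n))
  ss_terms <- diff(c(0, obs$traces))
  df_terms <- diff(c(0L, obs$dfs))
  ss_resid <- ss_total - obs$traces[length(obs$traces)]
  df_resid <- n - 1L - obs$dfs[length(obs$dfs)]
  f_obs <- (ss_terms / df_terms) / (ss_resid / df_resid)

  withr::local_seed(as.integer(seed))
  exceed <- integer(length(ss_terms))
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(n)
    pb <- fit_traces(perm)
    ss_p <- diff(c(0, pb$traces))
    ss_rp <- ss_total - pb$traces[length(pb$traces)]
    f_p <- (ss_p / df_terms) / (ss_rp / df_resid)
    exceed <- exceed + (f_p >= f_obs)
  }
  bind_rows(
    tibble(
      term = factors, df = df_terms, ss = ss_terms,
      r2 = ss_terms / ss_total, pseudo_F = f_obs,
      p_value = (1 + exceed) / (1 + n_permutations)
    ),
    tibble(term = "Residual", df = df_resid, ss = ss_resid,
           r2 = ss_resid / ss_total, pseudo_F = NA_real_, p_value = NA_real_)
  )
}
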