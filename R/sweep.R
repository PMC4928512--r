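#' Density grid for the network sweep
#'
#' Evenly spaced connection densities, endpoints inclusive, rounded to 4
#' decimals so the grid is bit-identical across platforms. The reference
#' grid is 10% to 90% in 5% steps — 17 levels.
#'
#' @param low,high Grid endpoints in (0, 1], `low <= high`.
#' @param step Positive increment.
#' @return Numeric vector of densities.
#' @export
density_grid <- function(low = 0.10, high = 0.90, step = 0.05) {
  check_number(low, "low", lower = 0, upper = 1, strict_lower = TRUE)
  check_number(high, "high", lower = low, upper = 1)
  check_number(step, "step", lower = 0, strict_lower = TRUE)
  levels <- round(seq(low, high + step / 2, by = step), 4)
  levels <- levels[levels <= high + 1e-9]
  if (length(levels) == 0L) abort("empty density grid")
  levels
}

#' Network parameters of one group across the density grid
#'
#' For each density level: threshold the group's connectivity matrix, then
#' compute clustering coefficient, global efficiency, characteristic path
#' length, and the small-world ratios gamma, lambda, sigma against rewired
#' nulls.
#'
#' @param series A [subject_series()].
#' @param grid Densities from [density_grid()].
#' @param mode `"weighted"` (default) or `"binary"` metrics.
#' @param ranking Edge ranking for thresholding; see
#'   [proportional_threshold()].
#' @param n_randomizations Rewired nulls per density (reference value 1000).
#' @param seed Integer seed for the null generation.
#' @return A `metric_profile` tibble: one row per density with columns
#'   `group`, `density`, `C`, `E`, `L`, `gamma`, `lambda`, `sigma`,
#'   `unreachable_frac`.
#' @export
metric_profile <- function(series, grid = density_grid(),
                           mode = c("weighted", "binary"),
                           ranking = c("signed", "absolute"),
                           n_randomizations = 1000, seed = 1L) {
  mode <- match.arg(mode)
  ranking <- match.arg(ranking)
  C <- pearson_connectivity(series)
  rows <- purrr::map(seq_along(grid), function(i) {
    g <- proportional_threshold(C, grid[i], mode = mode, ranking = ranking)
    sw <- small_worldness(g, n_randomizations, seed = seed + i - 1L)
    mt <- network_metrics(g)
    tibble(group = group_label(series), density = grid[i],
           C = mt$C, E = mt$E, L = mt$L,
           gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma,
           unreachable_frac = mt$unreachable_frac)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("metric_profile", class(out))
  out
}

#' @describeIn metric_profile Plot metrics against density.
#' @param object A `metric_profile` (or row-bound profiles of several
#'   groups).
#' @param ... Unused.
#' @export
autoplot.metric_profile <- function(object, ...) {
  as_tibble(object) |>
    tidyr::pivot_longer(c("C", "E", "L", "sigma"), names_to = "metric") |>
    ggplot2::ggplot(ggplot2::aes(.data$density, .data$value,
                                 colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "connection density", y = NULL) +
    ggplot2::theme_minimal()
}

#' Densities at which networks keep small-world organization
#'
#' Group comparisons of network parameters are only meaningful at densities
#' where the networks retain small-world topology, so the sweep is screened
#' first: per group, the grid levels with `sigma > threshold`; the analysis
#' mask for a comparison is the intersection across its groups.
#'
#' @param profiles One `metric_profile` or a row-bound set covering several
#'   groups on a common grid.
#' @param threshold Small-worldness cutoff (default 1).
#' @return List with `per_group` (tibble `group`, `density`, `valid`) and
#'   `mask` (densities valid in every group; may be empty).
#' @export
small_world_validity_screen <- function(profiles, threshold = 1) {
  tbl <- as_tibble(profiles) |>
    dplyr::mutate(valid = .data$sigma > threshold)
  per_group <- tbl |> dplyr::select("group", "density", "valid")
  mask <- tbl |>
    dplyr::group_by(.data$density) |>
    dplyr::summarise(all_valid = all(.data$valid), .groups = "drop") |>
    dplyr::filter(.data$all_valid) |>
    dplyr::pull("density")
  if (length(mask) == 0L) {
    warn("no density level is small-world valid in every group")
  }
  list(per_group = per_group, mask = mask)
}

#' Permutation test of network-parameter group differences per density
#'
#' At each density level, the observed difference (group A - group B) in a
#' network parameter is compared against the permutation distribution
#' obtained by recomputing both groups' networks under each relabeling of
#' the shared [make_scheme()] scheme — the same relabelings the edgewise
#' test uses, so the two analyses share one null. Two-tailed p-values with
#' add-one smoothing (exact proportions for exhaustive schemes). No
#' across-density multiplicity correction is applied; results are reported
#' per level, with significant levels summarized as maximal consecutive
#' runs by [significant_ranges()].
#'
#' @param seriesA,seriesB The two groups, identical region order.
#' @param grid Densities to test.
#' @param scheme Shared [make_scheme()] permutation scheme.
#' @param metrics Character subset of `c("C", "E", "L")` (default C and E).
#' @param mode,ranking Passed to [proportional_threshold()].
#' @return A `metric_comparison` tibble: `metric`, `density`, `observed_a`,
#'   `observed_b`, `delta`, `p`; attribute `scheme_checksum`.
#' @export
permute_metric_test <- function(seriesA, seriesB, grid = density_grid(),
                                scheme = NULL, metrics = c("C", "E"),
                                mode = c("weighted", "binary"),
                                ranking = c("signed", "absolute")) {
  mode <- match.arg(mode)
  ranking <- match.arg(ranking)
  metrics <- match.arg(metrics, c("C", "E", "L"), several.ok = TRUE)
  scheme <- scheme %||% make_scheme(nrow(seriesA), nrow(seriesB))
  prep <- pool_series(seriesA, seriesB, scheme)
  p <- length(prep$codes)

  metrics_at <- function(mat) {
    g_list <- lapply(grid, function(d) {
      proportional_threshold(
        new_connectivity_matrix(mat, prep$codes, NA_integer_),
        d, mode = mode, ranking = ranking)
    })
    vals <- vapply(g_list, function(g) {
      out <- c(C = NA_real_, E = NA_real_, L = NA_real_)
      if ("C" %in% metrics) out["C"] <- clustering_coefficient(g)$C
      if (any(c("E", "L") %in% metrics)) {
        d <- shortest_path_lengths(g)
        if ("E" %in% metrics) out["E"] <- global_efficiency(d)
        if ("L" %in% metrics) out["L"] <- characteristic_path_length(d)$L
      }
      out[metrics]
    }, numeric(length(metrics)))
    matrix(vals, nrow = length(metrics), ncol = length(grid))  # metrics x densities
  }
  group_stats <- function(rows_a) {
    a <- prep$pooled[rows_a, , drop = FALSE]
    b <- prep$pooled[-rows_a, , drop = FALSE]
    ca <- suppressWarnings(stats::cor(a))
    cb <- suppressWarnings(stats::cor(b))
    ca[is.na(ca)] <- 0
    cb[is.na(cb)] <- 0
    diag(ca) <- 1
    diag(cb) <- 1
    list(a = metrics_at(ca), b = metrics_at(cb))
  }

  obs <- group_stats(seq_len(scheme$nA))
  obs_delta <- obs$a - obs$b  # metrics x densities
  count <- matrix(0, nrow(obs_delta), ncol(obs_delta))
  for (kk in seq_len(scheme$n_permutations)) {
    st <- group_stats(scheme$assign_A[kk, ])
    count <- count + (abs(st$a - st$b) >= abs(obs_delta))
  }
  pmat <- perm_pvalue(count, scheme$n_permutations, scheme$exhaustive)
  out <- tidyr::expand_grid(metric = metrics, density = grid) |>
    dplyr::arrange(match(.data$metric, metrics)) |>
    dplyr::mutate(
      observed_a = as.vector(t(obs$a)),
      observed_b = as.vector(t(obs$b)),
      delta = as.vector(t(obs_delta)),
      p = as.vector(t(pmat))
    )
  structure(out, scheme_checksum = scheme_checksum(scheme),
            group_a = group_label(seriesA), group_b = group_label(seriesB),
            class = c("metric_comparison", class(tibble())))
}

#' @describeIn permute_metric_test Plot per-density p-values per metric.
#' @param object A `metric_comparison`.
#' @export
autoplot.metric_comparison <- function(object, ...) {
  as_tibble(object) |>
    ggplot2::ggplot(ggplot2::aes(.data$density, .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0.005, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "connection density", y = "permutation p") +
    ggplot2::theme_minimal()
}

#' Maximal runs of consecutive significant densities
#'
#' Summarizes a [permute_metric_test()] result the way density intervals
#' are conventionally reported (e.g. "significant over 25-90%"): per
#' metric, maximal runs of consecutive grid levels with `p < alpha`.
#'
#' @param comparison A `metric_comparison`.
#' @param alpha Significance level (conventional value 0.005 for parameter
#'   comparisons).
#' @return Tibble: `metric`, `from`, `to`, `n_levels`.
#' @export
significant_ranges <- function(comparison, alpha = 0.005) {
  if (!any(comparison$p < alpha)) {
    return(tibble(metric = character(), from = numeric(), to = numeric(),
                  n_levels = integer()))
  }
  as_tibble(comparison) |>
    dplyr::group_by(.data$metric) |>
    dplyr::arrange(.data$density, .by_group = TRUE) |>
    dplyr::mutate(sig = .data$p < alpha,
                  run = cumsum(c(TRUE, diff(.data$sig) != 0))) |>
    dplyr::filter(.data$sig) |>
    dplyr::group_by(.data$metric, .data$run) |>
    dplyr::summarise(from = min(.data$density), to = max(.data$density),
                     n_levels = dplyr::n(), .groups = "drop") |>
    dplyr::select(-"run")
}
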