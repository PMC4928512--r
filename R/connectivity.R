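#' Metabolic connectivity: cross-subject Pearson correlation matrix
#'
#' Computes a group's metabolic connectivity matrix: entry (i, j) is the
#' Pearson correlation between region i and region j uptake values across
#' the group's subjects. Unlike fMRI connectivity this is a group-level
#' object — one matrix per group, not per subject — because the "series"
#' dimension is subjects, not time.
#'
#' @param series A [subject_series()] with at least 3 subjects; every region
#'   column must have nonzero variance.
#' @return A `connectivity_matrix`: list with `values` (symmetric matrix,
#'   unit diagonal), `region_ids`, `n_subjects`, `group_label`.
#' @export
pearson_connectivity <- function(series) {
  stopifnot(inherits(series, "subject_series"))
  m <- series_matrix(series)
  if (nrow(m) < 3L) abort("at least 3 subjects are required for correlation")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    abort(sprintf("zero-variance region column(s): %s",
                  paste(colnames(m)[sds == 0], collapse = ", ")))
  }
  values <- stats::cor(m)
  diag(values) <- 1
  new_connectivity_matrix(values, region_ids(series), nrow(m),
                          group_label(series))
}

#' @noRd
new_connectivity_matrix <- function(values, region_ids, n_subjects,
                                    group_label = NA_character_) {
  dimnames(values) <- list(as.character(region_ids), as.character(region_ids))
  structure(
    list(values = values, region_ids = as.integer(region_ids),
         n_subjects = as.integer(n_subjects),
         group_label = as.character(group_label)),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> group '%s': %d x %d regions, n = %d subjects\n",
              x$group_label, nrow(x$values), ncol(x$values), x$n_subjects))
  invisible(x)
}

#' @describeIn pearson_connectivity Tidy the upper triangle into an edge
#'   tibble (`region_i`, `region_j`, `r`), canonical i < j order.
#' @param x A `connectivity_matrix`.
#' @param ... Unused.
#' @export
tidy.connectivity_matrix <- function(x, ...) {
  ij <- edge_index(length(x$region_ids))
  tibble(
    region_i = x$region_ids[ij[, "i"]],
    region_j = x$region_ids[ij[, "j"]],
    r = upper_vec(x$values)
  )
}

#' @describeIn pearson_connectivity One-row summary (regions, subjects,
#'   mean/min/max off-diagonal correlation).
#' @export
glance.connectivity_matrix <- function(x, ...) {
  r <- upper_vec(x$values)
  tibble(group = x$group_label, n_regions = length(x$region_ids),
         n_subjects = x$n_subjects, mean_r = mean(r),
         min_r = min(r), max_r = max(r))
}

#' @describeIn pearson_connectivity Correlation-matrix heatmap.
#' @param object A `connectivity_matrix`.
#' @export
autoplot.connectivity_matrix <- function(object, ...) {
  df <- tidy(object)
  df2 <- df |> dplyr::rename(region_i = "region_j", region_j = "region_i")
  dplyr::bind_rows(df, df2) |>
    ggplot2::ggplot(ggplot2::aes(factor(.data$region_i, levels = object$region_ids),
                                 factor(.data$region_j, levels = object$region_ids),
                                 fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = sprintf("Metabolic connectivity: %s", object$group_label)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Fisher z-transform of a connectivity matrix
#'
#' Entrywise `atanh(r)`, the variance-stabilizing scale sometimes preferred
#' for comparing correlations. The diagonal (r = 1) is undefined under the
#' transform and is set to `NA`; it is excluded from every downstream
#' statistic anyway.
#'
#' @param C A `connectivity_matrix` with all off-diagonal |r| < 1.
#' @return A matrix of z values with `NA` diagonal.
#' @export
fisher_z <- function(C) {
  stopifnot(inherits(C, "connectivity_matrix"))
  v <- C$values
  off <- v[upper.tri(v) | lower.tri(v)]
  if (any(abs(off) >= 1)) abort("degenerate correlation: |r| = 1 off the diagonal")
  z <- atanh(v)
  diag(z) <- NA_real_
  z
}

#' Write / read a connectivity matrix as TSV
#'
#' Square layout with region codes as header row and first column.
#' @param C A `connectivity_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_connectivity <- function(C, path) {
  df <- as.data.frame(C$values)
  df <- cbind(region = rownames(C$values), df)
  readr::write_tsv(as_tibble(df), path)
  invisible(path)
}

#' @rdname write_connectivity
#' @param n_subjects,group_label Metadata not stored in the TSV itself.
#' @export
read_connectivity <- function(path, n_subjects = NA_integer_,
                              group_label = NA_character_) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    region = readr::col_character(), .default = readr::col_double()
  ))
  m <- as.matrix(df[, -1L])
  codes <- as.integer(df$region)
  new_connectivity_matrix(m, codes, n_subjects, group_label)
}

#' Connectivity edge list as TSV (region_i, region_j, r)
#' @inheritParams write_connectivity
#' @export
write_edge_list <- function(C, path) {
  readr::write_tsv(tidy(C), path)
  invisible(path)
}
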