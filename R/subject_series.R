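#' Subject-by-region uptake table for one group
#'
#' The unit of resampling in the whole analysis: one row per subject, one
#' column per atlas region (columns named by region code), mean normalized
#' FDG uptake in the cells. Region order must be identical across all groups
#' being compared; correlations across subjects of one such table form the
#' group's metabolic connectivity matrix.
#'
#' @param values Numeric matrix or data frame, subjects x regions, no
#'   missing values.
#' @param region_ids Integer region codes, one per column, in fixed order.
#' @param group_label Group name (e.g. `"EAD"`, `"young"`).
#' @param subject_ids Optional character ids; defaults to `S1..Sn`.
#'
#' @return A tibble of class `subject_series` with a leading `subject_id`
#'   column, region columns named by code, and attributes `group_label` and
#'   `region_ids`.
#' @export
subject_series <- function(values, region_ids, group_label,
                           subject_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values) || !all(is.finite(values))) {
    abort("uptake values must be finite with no missing entries")
  }
  region_ids <- as.integer(region_ids)
  if (length(region_ids) != ncol(values)) {
    abort("`region_ids` must match the number of columns")
  }
  subject_ids <- as.character(subject_ids %||% paste0("S", seq_len(nrow(values))))
  if (length(subject_ids) != nrow(values)) {
    abort("`subject_ids` must match the number of rows")
  }
  colnames(values) <- as.character(region_ids)
  out <- dplyr::bind_cols(tibble(subject_id = subject_ids),
                          as_tibble(values))
  new_subject_series(out, group_label, region_ids)
}

#' @noRd
new_subject_series <- function(tbl, group_label, region_ids) {
  structure(tbl,
            group_label = as.character(group_label),
            region_ids = as.integer(region_ids),
            class = c("subject_series", class(tibble())))
}

#' @export
print.subject_series <- function(x, ...) {
  cat(sprintf("<subject_series> group '%s': %d subjects x %d regions\n",
              group_label(x), nrow(x), length(region_ids(x))))
  NextMethod()
}

#' Group label of a subject series
#' @param series A `subject_series`.
#' @return Character scalar.
#' @export
group_label <- function(series) attr(series, "group_label")

#' Region codes of a subject series or connectivity object
#' @param x A `subject_series` or `connectivity_matrix`.
#' @return Integer vector.
#' @export
region_ids <- function(x) {
  if (inherits(x, "connectivity_matrix")) return(x$region_ids)
  attr(x, "region_ids")
}

#' Numeric subjects-by-regions matrix of a series
#' @param series A `subject_series`.
#' @return Numeric matrix with subject ids as rownames.
#' @export
series_matrix <- function(series) {
  m <- as.matrix(series[, as.character(region_ids(series)), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- series$subject_id
  m
}

#' Write / read a subject series as TSV
#'
#' First column `subject_id`, remaining columns region codes; one file per
#' group. The group label travels in a `# group:` header comment line.
#'
#' @param series A `subject_series`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_subject_series <- function(series, path) {
  writeLines(sprintf("# group: %s", group_label(series)), path)
  readr::write_tsv(as_tibble(as.data.frame(series)), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_subject_series
#' @param group_label Override for the group label; defaults to the file's
#'   `# group:` header (or the file name stem).
#' @export
read_subject_series <- function(path, group_label = NULL) {
  first <- readLines(path, n = 1L)
  if (is.null(group_label)) {
    group_label <- if (grepl("^# group:", first)) {
      trimws(sub("^# group:", "", first))
    } else {
      sub("\\.[^.]*$", "", basename(path))
    }
  }
  tbl <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    subject_id = readr::col_character(), .default = readr::col_double()
  ))
  codes <- as.integer(setdiff(names(tbl), "subject_id"))
  subject_series(as.matrix(tbl[, as.character(codes)]), codes, group_label,
                 subject_ids = tbl$subject_id)
}
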