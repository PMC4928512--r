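#' Region atlas: a label volume plus an ordered label table
#'
#' A `region_atlas` pairs an integer 3-D label volume (0 = background) with
#' an ordered label table. The table drives region ordering everywhere
#' downstream: regions are kept in ascending code order so matrix indexing
#' is deterministic across runs.
#'
#' @param label_table Data frame with columns `code` (positive integer),
#'   `name` (character) and `cerebellar` (0/1 or logical).
#' @param label_volume Optional 3-D integer array of region codes
#'   (0 = background). May be `NULL` when only the table is needed
#'   (e.g. when working from precomputed uptake tables).
#'
#' @return A `region_atlas` object.
#' @export
region_atlas <- function(label_table, label_volume = NULL) {
  label_table <- as_tibble(label_table)
  req <- c("code", "name", "cerebellar")
  if (!all(req %in% names(label_table))) {
    abort("`label_table` needs columns code, name, cerebellar")
  }
  label_table <- label_table |>
    dplyr::mutate(
      code = as.integer(.data$code),
      cerebellar = as.logical(as.integer(.data$cerebellar))
    ) |>
    dplyr::arrange(.data$code)
  if (anyDuplicated(label_table$code)) abort("duplicate region codes")
  if (!is.null(label_volume)) {
    label_volume <- as.array(label_volume)
    if (length(dim(label_volume)) != 3L) abort("`label_volume` must be 3-D")
    used <- setdiff(unique(as.integer(label_volume)), 0L)
    missing <- setdiff(used, label_table$code)
    if (length(missing)) {
      abort(sprintf("label volume contains codes absent from the table: %s",
                    paste(missing, collapse = ", ")))
    }
  }
  structure(
    list(label_table = label_table, label_volume = label_volume),
    class = "region_atlas"
  )
}

#' @export
print.region_atlas <- function(x, ...) {
  cat(sprintf(
    "<region_atlas> %d regions (%d cerebellar)%s\n",
    nrow(x$label_table), sum(x$label_table$cerebellar),
    if (is.null(x$label_volume)) ", no label volume"
    else sprintf(", volume %s", paste(dim(x$label_volume), collapse = "x"))
  ))
  invisible(x)
}

#' Load the packaged AAL label table
#'
#' The standard 116-region Automated Anatomical Labeling (AAL) nomenclature,
#' codes 1..116 in the conventional order. Cerebellar regions (names starting
#' with `Cerebelum` or `Vermis`) are flagged; excluding them leaves the
#' 90-region cerebral parcellation used for connectivity matrices.
#'
#' @return A `region_atlas` with the 116-row label table and no label volume.
#' @export
aal_atlas <- function() {
  path <- system.file("extdata", "aal116_labels.tsv", package = "metconn",
                      mustWork = TRUE)
  region_atlas(read_label_table(path))
}

#' Read a region label table from TSV
#'
#' @param path TSV file with columns `code`, `name`, `cerebellar` (0/1).
#' @return A tibble.
#' @export
read_label_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    code = readr::col_integer(),
    name = readr::col_character(),
    cerebellar = readr::col_integer()
  ))
}

#' Drop cerebellar regions from an atlas
#'
#' Restricts the atlas to non-cerebellar regions, preserving order. On the
#' packaged AAL table this leaves exactly 90 regions, the parcellation on
#' which connectivity matrices are defined. The cerebellum is dropped from
#' the network (it serves only as the intensity reference region) but any
#' label volume is kept intact so cerebellar normalization remains possible.
#'
#' @param atlas A `region_atlas`.
#' @return A `region_atlas` whose table contains only non-cerebellar regions.
#' @export
exclude_cerebellum <- function(atlas) {
  stopifnot(inherits(atlas, "region_atlas"))
  keep <- atlas$label_table |> dplyr::filter(!.data$cerebellar)
  if (nrow(keep) == 0L) abort("empty parcellation")
  structure(
    list(label_table = keep, label_volume = atlas$label_volume,
         reference_table = atlas$label_table),
    class = "region_atlas"
  )
}

#' Region codes of an atlas, in fixed order
#' @param atlas A `region_atlas`.
#' @return Integer vector of codes.
#' @export
region_codes <- function(atlas) atlas$label_table$code

#' Codes of cerebellar regions known to an atlas
#'
#' Looks in the current label table and, after [exclude_cerebellum()], in the
#' retained full table, so the reference region stays addressable.
#' @noRd
cerebellar_codes <- function(atlas) {
  tab <- atlas$reference_table %||% atlas$label_table
  tab$code[tab$cerebellar]
}

#' Deterministic synthetic region centroids
#'
#' Lays region centroids out on an ellipsoid, left-hemisphere regions
#' (`_L` suffix) at negative x. These are synthetic stand-in coordinates for
#' viewer export layout only — they carry no anatomical meaning and are not
#' MNI coordinates. Supply a real centroid table for figures of real data.
#'
#' @param atlas A `region_atlas`.
#' @return Tibble with columns `code`, `name`, `x`, `y`, `z`.
#' @export
synthetic_centroids <- function(atlas) {
  tab <- atlas$label_table
  n <- nrow(tab)
  idx <- seq_len(n)
  left <- grepl("_L$", tab$name)
  right <- grepl("_R$", tab$name)
  # golden-angle spiral on a hemisphere-ish shell; midline regions at x ~ 0
  t <- (idx - 0.5) / n
  phi <- idx * 2.399963
  x <- abs(cos(phi)) * 55 * sqrt(1 - (2 * t - 1)^2)
  x[left] <- -x[left]
  x[!left & !right] <- 0
  tibble(
    code = tab$code, name = tab$name,
    x = round(x, 1),
    y = round(90 * t - 50, 1),
    z = round(60 * sin(phi) * sqrt(t), 1)
  )
}
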