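#' Read and validate a pipeline configuration
#'
#' Configurations are YAML (or JSON) with the fields of the demo config
#' shipped at `system.file("extdata", "demo_config.yaml", package =
#' "metconn")`: input mode (`tables`, `volumes` or `synthetic`), group
#' definitions, optional atlas paths, smoothing settings, comparison
#' pairs, permutation count and seed, density grid, metric mode, and
#' significance thresholds. Referenced files must exist at validation
#' time.
#'
#' @param path Path to a YAML/JSON config, or a pre-built list.
#' @return Validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  defaults <- list(
    mode = "tables", smoothing = list(enabled = FALSE, fwhm_mm = 16),
    n_permutations = 10000, seed = 1L,
    density = list(low = 0.10, high = 0.90, step = 0.05),
    metric_mode = "weighted", ranking = "signed",
    n_randomizations = 1000,
    alpha_edges = 0.05, edge_correction = "fwe", alpha_metrics = 0.005,
    output_dir = "metconn_output"
  )
  cfg <- utils::modifyList(defaults, cfg)
  if (!cfg$mode %in% c("tables", "volumes", "synthetic")) {
    abort("mode must be tables, volumes or synthetic")
  }
  if (cfg$mode != "synthetic") {
    if (is.null(cfg$groups) || length(cfg$groups) < 2L) {
      abort("config needs at least two groups")
    }
    files <- unlist(lapply(cfg$groups, function(g) g$files %||% g$table))
    missing <- files[!file.exists(files)]
    if (length(missing)) {
      abort(sprintf("missing input file(s): %s", paste(missing, collapse = ", ")))
    }
  }
  if (is.null(cfg$comparisons)) abort("config needs comparison pairs")
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full metabolic-connectivity pipeline from a config
#'
#' Composes the whole analysis: load (or simulate) each group's
#' subject-by-region table, compute per-group connectivity matrices and
#' density-sweep metric profiles, and for each configured comparison pair
#' run the edgewise permutation test and the per-density network-parameter
#' test with one shared permutation scheme. All artifacts are written
#' under `output_dir` as TSV/JSON plus BrainNet-style .node/.edge files,
#' with a run log naming seeds and the config hash; reruns with the same
#' config are bit-identical.
#'
#' @param config A `pipeline_config`, or a path/list accepted by
#'   [read_pipeline_config()].
#' @return Invisible list with `series`, `connectivity`, `profiles`,
#'   `edge_tests`, `metric_tests`, `significant`, `output_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else read_pipeline_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$output_dir, "run_log.txt")
  cfg_hash <- sum(utf8ToInt(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE))) %% 1e9
  logf <- function(stage, ...) {
    msg <- sprintf("[%s] config=%d seed=%d %s", stage, cfg_hash,
                   as.integer(cfg$seed), sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    logf(name, "done in %.1fs", proc.time()[["elapsed"]] - t0)
    out
  }

  series <- stage("load", load_groups(cfg))
  conn <- stage("connectivity", {
    out <- lapply(series, pearson_connectivity)
    for (nm in names(out)) {
      write_connectivity(out[[nm]], file.path(cfg$output_dir,
                                              paste0("connectivity_", nm, ".tsv")))
    }
    out
  })
  grid <- density_grid(cfg$density$low, cfg$density$high, cfg$density$step)
  profiles <- stage("profiles", {
    out <- purrr::imap(series, function(s, nm) {
      metric_profile(s, grid, mode = cfg$metric_mode, ranking = cfg$ranking,
                     n_randomizations = cfg$n_randomizations,
                     seed = cfg$seed)
    })
    readr::write_tsv(dplyr::bind_rows(out),
                     file.path(cfg$output_dir, "metric_profiles.tsv"))
    out
  })

  edge_tests <- list()
  metric_tests <- list()
  signif <- list()
  for (cmp in cfg$comparisons) {
    a <- cmp[[1L]]; b <- cmp[[2L]]
    key <- paste0(a, "_vs_", b)
    scheme <- make_scheme(nrow(series[[a]]), nrow(series[[b]]),
                          cfg$n_permutations, cfg$seed)
    edge_tests[[key]] <- stage(paste0("edges:", key), {
      et <- permute_edge_test(series[[a]], series[[b]], scheme)
      write_edge_test(et, file.path(cfg$output_dir, paste0("edges_", key, ".tsv")))
      et
    })
    signif[[key]] <- stage(paste0("significant:", key), {
      se <- significant_edges(edge_tests[[key]], cfg$alpha_edges,
                              cfg$edge_correction)
      readr::write_tsv(se, file.path(cfg$output_dir,
                                     paste0("significant_edges_", key, ".tsv")))
      coords <- pipeline_coords(cfg, series[[a]])
      nv <- node_uptake_difference(series[[a]], series[[b]])
      export_brainnet(se, coords, nv,
                      file.path(cfg$output_dir, paste0("brainnet_", key)))
      se
    })
    metric_tests[[key]] <- stage(paste0("metrics:", key), {
      mc <- permute_metric_test(series[[a]], series[[b]], grid, scheme,
                                mode = cfg$metric_mode, ranking = cfg$ranking)
      readr::write_tsv(mc, file.path(cfg$output_dir,
                                     paste0("metric_test_", key, ".tsv")))
      rng <- significant_ranges(mc, cfg$alpha_metrics)
      jsonlite::write_json(rng, file.path(cfg$output_dir,
                                          paste0("significant_ranges_", key, ".json")),
                           dataframe = "rows", digits = NA)
      mc
    })
  }
  invisible(list(series = series, connectivity = conn, profiles = profiles,
                 edge_tests = edge_tests, metric_tests = metric_tests,
                 significant = signif, output_dir = cfg$output_dir))
}

#' @noRd
load_groups <- function(cfg) {
  if (cfg$mode == "synthetic") {
    syn <- cfg$synthetic %||% list()
    spec <- cohort_spec(
      n_case = syn$n_case %||% 74, n_control = syn$n_control %||% 20,
      n_regions = syn$n_regions %||% 90, seed = cfg$seed
    )
    pair <- simulate_cohort_pair(
      spec,
      planted_r_case = syn$planted_r_case %||% 0.1,
      global_attenuation = syn$global_attenuation %||% 1
    )
    return(list(case = pair$case, control = pair$control))
  }
  out <- list()
  for (nm in names(cfg$groups)) {
    g <- cfg$groups[[nm]]
    if (cfg$mode == "tables") {
      out[[nm]] <- read_subject_series(g$table, group_label = nm)
    } else {
      atlas <- region_atlas(read_label_table(cfg$atlas$labels),
                            RNifti::readNifti(cfg$atlas$volume))
      atlas90 <- exclude_cerebellum(atlas)
      vols <- lapply(g$files, read_pet_volume)
      fw <- if (isTRUE(cfg$smoothing$enabled)) cfg$smoothing$fwhm_mm else NULL
      out[[nm]] <- build_subject_series(vols, atlas90, nm, smooth_fwhm_mm = fw)
    }
  }
  out
}

#' @noRd
pipeline_coords <- function(cfg, series) {
  if (!is.null(cfg$atlas$centroids)) {
    readr::read_tsv(cfg$atlas$centroids, show_col_types = FALSE)
  } else {
    tab <- tibble(code = region_ids(series),
                  name = paste0("R", region_ids(series)),
                  cerebellar = 0L)
    synthetic_centroids(region_atlas(tab))
  }
}

#' Between-group difference in mean regional uptake
#'
#' The per-region metabolic contrast used to colour nodes in renderings:
#' group A's mean normalized uptake minus group B's, per region.
#'
#' @param seriesA,seriesB [subject_series()] with identical region order.
#' @return Tibble `code`, `uptake_diff`.
#' @export
node_uptake_difference <- function(seriesA, seriesB) {
  stopifnot(identical(region_ids(seriesA), region_ids(seriesB)))
  tibble(code = region_ids(seriesA),
         uptake_diff = unname(colMeans(series_matrix(seriesA)) -
                                colMeans(series_matrix(seriesB))))
}

#' Export a significant edge set as BrainNet-style .node/.edge files
#'
#' `.node`: one row per region — x, y, z, colour value (regional uptake
#' difference), size value (count of significant edges at the region), and
#' label. `.edge`: the N x N signed connectivity-difference matrix masked
#' to the significant edges. Both are whitespace-delimited text accepted
#' by surface-rendering viewers.
#'
#' @param edges A [significant_edges()] result.
#' @param node_coords Tibble with `code`, `name`, `x`, `y`, `z` covering
#'   every region.
#' @param node_values Tibble with `code`, `uptake_diff` (node colour), e.g.
#'   from [node_uptake_difference()]; defaults to zeros.
#' @param path_prefix Output prefix; writes `<prefix>.node` and
#'   `<prefix>.edge`.
#' @return Character vector of the two paths, invisibly.
#' @export
export_brainnet <- function(edges, node_coords, node_values = NULL,
                            path_prefix = "brainnet") {
  deg <- edge_degree(edges)
  codes <- deg$code
  node_coords <- as_tibble(node_coords)
  if (!all(codes %in% node_coords$code)) {
    abort("missing coordinate for some regions")
  }
  node_coords <- node_coords[match(codes, node_coords$code), ]
  node_values <- node_values %||% tibble(code = codes, uptake_diff = 0)
  node_values <- node_values[match(codes, node_values$code), ]
  node_df <- data.frame(
    x = node_coords$x, y = node_coords$y, z = node_coords$z,
    color = node_values$uptake_diff, size = deg$degree,
    label = gsub("\\s", "_", node_coords$name)
  )
  node_path <- paste0(path_prefix, ".node")
  edge_path <- paste0(path_prefix, ".edge")
  utils::write.table(node_df, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  n <- length(codes)
  m <- matrix(0, n, n)
  if (nrow(edges) > 0L) {
    ii <- match(edges$region_i, codes)
    jj <- match(edges$region_j, codes)
    m[cbind(ii, jj)] <- edges$delta
    m[cbind(jj, ii)] <- edges$delta
  }
  utils::write.table(m, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(node_path, edge_path))
}
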