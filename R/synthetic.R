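#' Modular correlation structure for synthetic cohorts
#'
#' Builds a region-by-region correlation matrix with block (module)
#' structure: `within_r` inside modules, `between_r` across modules, plus
#' optional per-edge overrides for planted effects. If overrides break
#' positive semi-definiteness, the matrix is repaired by eigenvalue
#' clipping (floor 1e-8) and rescaled to unit diagonal; a repair that moves
#' any entry by more than 0.1 aborts, since the requested structure is then
#' infeasible rather than merely rough.
#'
#' The default module layout mimics coarse lobes (6 modules over 90
#' regions) so planted cross-module effects — e.g. the cingulate-occipital
#' weakening the analysis is designed to detect — have a named home; module
#' names are labels only, with no anatomical claim.
#'
#' @param n_regions Number of regions.
#' @param modules Integer module assignment per region, or a module count
#'   (regions split as evenly as possible, in order).
#' @param within_r,between_r Correlations inside / across modules
#'   (|r| < 1).
#' @param planted_edges Optional tibble/data.frame with columns `i`, `j`,
#'   `r`: entry overrides applied before PSD repair.
#' @return Correlation matrix with attribute `modules`.
#' @export
modular_covariance <- function(n_regions, modules = 6L, within_r = 0.6,
                               between_r = 0.15, planted_edges = NULL) {
  check_number(n_regions, "n_regions", lower = 2)
  if (length(modules) == 1L) {
    modules <- sort(rep_len(seq_len(modules), n_regions))
  }
  if (length(modules) != n_regions) {
    abort("`modules` must assign every region to a module")
  }
  if (abs(within_r) >= 1 || abs(between_r) >= 1) abort("|r| must be < 1")
  same <- outer(modules, modules, `==`)
  sigma <- ifelse(same, within_r, between_r)
  diag(sigma) <- 1
  if (!is.null(planted_edges)) {
    pe <- as.data.frame(planted_edges)
    if (!all(c("i", "j", "r") %in% names(pe))) {
      abort("`planted_edges` needs columns i, j, r")
    }
    if (any(abs(pe$r) >= 1)) abort("|r| must be < 1")
    for (k in seq_len(nrow(pe))) {
      sigma[pe$i[k], pe$j[k]] <- pe$r[k]
      sigma[pe$j[k], pe$i[k]] <- pe$r[k]
    }
  }
  repaired <- nearest_psd(sigma)
  if (max(abs(repaired - sigma)) > 0.1) {
    abort("infeasible structure: PSD repair moved an entry by more than 0.1")
  }
  structure(repaired, modules = modules)
}

#' Nearest-PSD repair by eigenvalue clipping, unit diagonal restored
#' @noRd
nearest_psd <- function(sigma, floor = 1e-8) {
  e <- eigen(sigma, symmetric = TRUE)
  if (min(e$values) >= floor) return(sigma)
  vals <- pmax(e$values, floor)
  m <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(m))
  m <- m / tcrossprod(d)
  diag(m) <- 1
  (m + t(m)) / 2
}

#' Simulate one group's subject-by-region table
#'
#' Subjects are independent draws from a multivariate normal with the
#' given correlation structure, scaled by `noise_sd` and shifted by the
#' region means — the minimal generative model whose Pearson correlation
#' matrix is exactly controllable.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param covariance Correlation matrix, e.g. from [modular_covariance()].
#' @param means Region mean uptake: scalar or one value per region
#'   (default 1, i.e. cerebellum-normalized scale).
#' @param noise_sd Subject-level standard deviation (default 0.1, ~10%
#'   of the normalized mean, a realistic between-subject spread for
#'   normalized uptake).
#' @param seed Integer seed.
#' @param group_label Label carried on the series.
#' @param region_ids Region codes (default 1..n_regions).
#' @return A [subject_series()].
#' @export
simulate_group <- function(n_subjects, covariance, means = 1, noise_sd = 0.1,
                           seed = 1L, group_label = "group",
                           region_ids = NULL) {
  check_number(n_subjects, "n_subjects", lower = 3)
  p <- nrow(covariance)
  means <- rep_len(means, p)
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) abort("covariance is not positive semi-definite")
  vals <- withr::with_seed(seed, {
    MASS::mvrnorm(n_subjects, mu = rep(0, p), Sigma = covariance)
  })
  vals <- sweep(vals * noise_sd, 2L, means, `+`)
  subject_series(vals, region_ids %||% seq_len(p), group_label)
}

#' Default cohort specification
#'
#' Two-group design mirroring the early-onset-disease vs young-control
#' comparison: 74 case and 20 control subjects over 90 regions in 6
#' modules, base structure `within_r = 0.6`, `between_r = 0.15`, with 10
#' designated cross-module edges raised to r = 0.6 in the base (control)
#' structure — the edges the case group's effect will weaken.
#'
#' @param n_case,n_control Group sizes (defaults 74 and 20).
#' @param n_regions,n_modules Parcellation size and module count.
#' @param within_r,between_r Base block correlations.
#' @param n_planted Number of designated cross-module edges (default 10).
#' @param planted_base_r Their correlation in the control structure
#'   (default 0.6).
#' @param noise_sd,means Passed to [simulate_group()].
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_case = 74, n_control = 20, n_regions = 90,
                        n_modules = 6, within_r = 0.6, between_r = 0.15,
                        n_planted = 10, planted_base_r = 0.6,
                        noise_sd = 0.1, means = 1, seed = 1L) {
  modules <- sort(rep_len(seq_len(n_modules), n_regions))
  # designated cross-module pairs: first regions of module 2 vs module 4
  # (stand-ins for e.g. cingulate vs occipital blocks)
  m2 <- which(modules == min(2L, max(modules)))
  m4 <- which(modules == min(4L, max(modules)))
  k <- n_planted
  if (k > length(m2) * length(m4)) abort("too many planted edges for the module sizes")
  s <- seq_len(k) - 1L
  # diagonal assignment keeps the k pairs distinct and spread over both modules
  pairs <- tibble(
    i = m2[(s %% length(m2)) + 1L],
    j = m4[((s + s %/% length(m2)) %% length(m4)) + 1L],
    r = planted_base_r
  )
  structure(
    list(n_case = n_case, n_control = n_control, n_regions = n_regions,
         modules = modules, within_r = within_r, between_r = between_r,
         planted_edges = pairs, noise_sd = noise_sd, means = means,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Simulate a case/control cohort pair with planted effects
#'
#' The control group is drawn from the base modular structure. The case
#' group's structure weakens the designated cross-module edges from their
#' base correlation down to `planted_r_case` (default 0.1) and optionally
#' attenuates the whole block structure by `global_attenuation`
#' (1 = none, 0.5 = halved) — emulating, respectively, focal connectivity
#' loss and the global network weakening that lowers clustering and
#' efficiency.
#'
#' @param spec A [cohort_spec()].
#' @param planted_r_case Case-group correlation on the designated edges
#'   (default 0.1; set equal to the base value for a null pair).
#' @param global_attenuation Multiplier on the case group's block
#'   correlations, within and between modules (default 1 = no global
#'   effect).
#' @param seed Overrides `spec$seed` when given.
#' @return Named list: `case`, `control` ([subject_series()]),
#'   `planted_edges` tibble, `spec`.
#' @export
simulate_cohort_pair <- function(spec = cohort_spec(), planted_r_case = 0.1,
                                 global_attenuation = 1, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  seed <- as.integer(seed %||% spec$seed)
  base_cov <- modular_covariance(spec$n_regions, spec$modules,
                                 spec$within_r, spec$between_r,
                                 spec$planted_edges)
  case_within <- spec$within_r * global_attenuation
  case_between <- spec$between_r * global_attenuation
  case_edges <- spec$planted_edges |> dplyr::mutate(r = planted_r_case)
  case_cov <- modular_covariance(spec$n_regions, spec$modules,
                                 case_within, case_between, case_edges)
  control <- simulate_group(spec$n_control, base_cov, spec$means,
                            spec$noise_sd, seed = seed,
                            group_label = "control")
  case <- simulate_group(spec$n_case, case_cov, spec$means, spec$noise_sd,
                         seed = seed + 1L, group_label = "case")
  list(case = case, control = control,
       planted_edges = spec$planted_edges |> dplyr::select("i", "j"),
       spec = spec)
}

#' Simulate a toy phantom volume over an atlas
#'
#' Voxel value = the planted mean of its region plus Gaussian noise;
#' background stays 0. Exercises the ROI front end (smoothing,
#' normalization, extraction) with known ground truth.
#'
#' @param atlas A `region_atlas` with a label volume.
#' @param region_means Named numeric (names = region codes) or vector in
#'   atlas order covering every atlas region.
#' @param noise_sd Voxel noise SD (default 0).
#' @param seed Integer seed.
#' @param voxel_size_mm Voxel size for the resulting volume.
#' @return A `pet_volume`.
#' @export
simulate_phantom_volume <- function(atlas, region_means, noise_sd = 0,
                                    seed = 1L, voxel_size_mm = c(2, 2, 2)) {
  stopifnot(inherits(atlas, "region_atlas"))
  if (is.null(atlas$label_volume)) abort("atlas has no label volume")
  codes <- (atlas$reference_table %||% atlas$label_table)$code
  if (is.null(names(region_means))) {
    if (length(region_means) != length(codes)) {
      abort("missing region mean: provide one value per atlas region")
    }
    region_means <- setNames(region_means, codes)
  }
  if (!all(as.character(codes) %in% names(region_means))) {
    abort("missing region mean for some atlas regions")
  }
  lab <- atlas$label_volume
  arr <- array(0, dim = dim(lab))
  nz <- lab != 0
  arr[nz] <- region_means[as.character(lab[nz])]
  if (noise_sd > 0) {
    arr[nz] <- arr[nz] + withr::with_seed(seed, rnorm(sum(nz), 0, noise_sd))
  }
  pet_volume(arr, voxel_size_mm)
}

#' Toy atlas with a few cerebral and cerebellar regions
#'
#' Small 3-D label volume of axis-aligned blocks, the last `n_cerebellar`
#' regions flagged cerebellar — enough structure to exercise the ROI front
#' end without real anatomy.
#'
#' @param dim Volume dimensions (default `c(12, 12, 12)`).
#' @param n_regions Total region count (default 5).
#' @param n_cerebellar How many of the last regions are cerebellar
#'   (default 1).
#' @return A `region_atlas` with a label volume.
#' @export
toy_atlas <- function(dim = c(12, 12, 12), n_regions = 5L,
                      n_cerebellar = 1L) {
  if (n_cerebellar >= n_regions) abort("need at least one cerebral region")
  lab <- array(0L, dim = dim)
  # split the x axis into n_regions slabs, leaving a 1-voxel background rim
  xs <- round(seq(2, dim[1], length.out = n_regions + 1L))
  for (r in seq_len(n_regions)) {
    lab[xs[r]:(xs[r + 1L] - (r < n_regions)), 2:(dim[2] - 1), 2:(dim[3] - 1)] <- r
  }
  region_atlas(
    tibble(code = seq_len(n_regions),
           name = c(paste0("Region_", seq_len(n_regions - n_cerebellar)),
                    paste0("Cerebelum_", seq_len(n_cerebellar))),
           cerebellar = c(rep(0L, n_regions - n_cerebellar),
                          rep(1L, n_cerebellar))),
    lab
  )
}
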