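test_that("modular covariance builds the expected block structure", {
  id <- modular_covariance(6, modules = 6, within_r = 0, between_r = 0)
  expect_equal(unclass(id), diag(6), ignore_attr = TRUE)

  m <- modular_covariance(4, modules = c(1, 1, 2, 2), within_r = 0.8,
                          between_r = 0.2)
  expected <- matrix(0.2, 4, 4)
  expected[1:2, 1:2] <- 0.8
  expected[3:4, 3:4] <- 0.8
  diag(expected) <- 1
  expect_equal(unclass(m), expected, ignore_attr = TRUE)
  expect_gte(min(eigen(m, symmetric = TRUE, only.values = TRUE)$values), 0)

  # a feasible override changes exactly that entry (and its transpose)
  m2 <- modular_covariance(4, modules = c(1, 1, 2, 2), within_r = 0.8,
                           between_r = 0.2,
                           planted_edges = data.frame(i = 1, j = 3, r = 0.4))
  diff <- abs(unclass(m2) - expected) > 1e-9
  expect_equal(which(diff), c(3L, 9L))  # (3,1) and (1,3), column-major
  expect_equal(m2[1, 3], 0.4)

  expect_error(
    modular_covariance(3, modules = c(1, 1, 1), within_r = 0.9,
                       planted_edges = data.frame(i = c(1, 2), j = c(3, 3),
                                                  r = c(-0.9, 0.9))),
    "infeasible structure")
})

test_that("simulated groups are seed-deterministic with calibrated correlations", {
  sigma <- diag(10)
  s1 <- simulate_group(2000, sigma, seed = 50)
  s2 <- simulate_group(2000, sigma, seed = 50)
  expect_identical(series_matrix(s1), series_matrix(s2))
  C <- pearson_connectivity(s1)$values
  expect_lt(max(abs(C[upper.tri(C)])), 0.1)

  planted <- modular_covariance(5, modules = rep(1, 5), within_r = 0.1,
                                planted_edges = data.frame(i = 1, j = 2, r = 0.8))
  sp <- simulate_group(500, planted, seed = 51)
  expect_lt(abs(pearson_connectivity(sp)$values[1, 2] - 0.8), 0.08)
})

test_that("cohort pairs plant distinct edges and honour the null effect", {
  spec <- cohort_spec(n_case = 10, n_control = 10, n_regions = 30, seed = 52)
  expect_equal(nrow(dplyr::distinct(spec$planted_edges)), 10L)

  # sample correlations converge to the built (PSD-repaired) covariance
  built <- modular_covariance(spec$n_regions, spec$modules, spec$within_r,
                              spec$between_r, spec$planted_edges)
  big_a <- simulate_group(4000, built, seed = 53)
  ca <- pearson_connectivity(big_a)$values
  for (k in seq_len(10)) {
    expect_equal(ca[spec$planted_edges$i[k], spec$planted_edges$j[k]],
                 built[spec$planted_edges$i[k], spec$planted_edges$j[k]],
                 tolerance = 0.06)
  }

  pr <- simulate_cohort_pair(cohort_spec(n_case = 2000, n_control = 2000,
                                         n_regions = 30, seed = 54))
  cc <- pearson_connectivity(pr$case)$values
  cn <- pearson_connectivity(pr$control)$values
  pe <- pr$planted_edges
  case_r <- mapply(function(i, j) cc[i, j], pe$i, pe$j)
  ctrl_r <- mapply(function(i, j) cn[i, j], pe$i, pe$j)
  expect_true(all(abs(case_r - 0.1) < 0.1))
  expect_true(all(ctrl_r > 0.4))
})

test_that("global attenuation lowers the case group's clustering", {
  lower <- vapply(1:6, function(seed) {
    pr <- simulate_cohort_pair(cohort_spec(n_case = 40, n_control = 40,
                                           n_regions = 30, seed = 60 + seed),
                               global_attenuation = 0.5)
    cc <- clustering_coefficient(
      proportional_threshold(pearson_connectivity(pr$case), 0.3))$C
    cn <- clustering_coefficient(
      proportional_threshold(pearson_connectivity(pr$control), 0.3))$C
    cc < cn
  }, logical(1))
  expect_gte(mean(lower), 5 / 6)
})

test_that("phantom volumes reproduce planted means and compose with normalization", {
  atlas <- toy_atlas(n_regions = 4, n_cerebellar = 1)
  means <- c("1" = 1.2, "2" = 0.8, "3" = 1.5, "4" = 2.0)
  v <- simulate_phantom_volume(atlas, means, noise_sd = 0)
  got <- extract_roi_means(v, atlas)$mean_uptake
  expect_equal(got, unname(means))
  # cerebellar planted mean m: normalization divides by exactly m at zero noise
  nv <- normalize_by_cerebellum(v, atlas)
  expect_equal(extract_roi_means(nv, atlas)$mean_uptake, unname(means) / 2.0)

  v1 <- simulate_phantom_volume(atlas, means, noise_sd = 0.1, seed = 55)
  v2 <- simulate_phantom_volume(atlas, means, noise_sd = 0.1, seed = 55)
  expect_identical(v1$voxels, v2$voxels)
  expect_error(simulate_phantom_volume(atlas, means[1:3]), "missing region mean")
})

test_that("subject series round-trip through the TSV dialect", {
  ss <- random_series(6, 5, seed = 56, group = "EAD")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_subject_series(ss, path)
  back <- read_subject_series(path)
  expect_equal(group_label(back), "EAD")
  expect_equal(region_ids(back), region_ids(ss))
  expect_equal(series_matrix(back), series_matrix(ss), tolerance = 1e-12)
})
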