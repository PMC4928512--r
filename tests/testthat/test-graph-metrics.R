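test_that("proportional thresholding keeps the top-k edges at the target density", {
  withr::with_seed(1, {
    v <- matrix(0, 4, 4)
    v[upper.tri(v)] <- c(0.9, 0.8, 0.2, 0.7, 0.4, 0.1)
    v <- v + t(v); diag(v) <- 1
  })
  C <- metconn:::new_connectivity_matrix(v, 1:4, 10L)
  g <- proportional_threshold(C, 0.5)
  expect_equal(sum(metconn:::upper_vec(g$adjacency) != 0), 3L)
  expect_setequal(metconn:::upper_vec(g$adjacency)[metconn:::upper_vec(g$adjacency) != 0],
                  c(0.9, 0.8, 0.7))

  full <- proportional_threshold(C, 1.0)
  expect_equal(sum(metconn:::upper_vec(full$adjacency) != 0), 6L)

  bin <- proportional_threshold(C, 0.5, mode = "binary")
  expect_true(all(bin$adjacency %in% c(0, 1)))

  expect_error(proportional_threshold(C, 0.01), "density too low")
})

test_that("ties at the cut are broken by canonical edge index order", {
  v <- matrix(0, 4, 4)
  # canonical edge order (1,2),(1,3),(1,4),(2,3),(2,4),(3,4)
  v[upper.tri(v)] <- 0.5
  v <- v + t(v); diag(v) <- 1
  v[1, 2] <- v[2, 1] <- 0.9
  C <- metconn:::new_connectivity_matrix(v, 1:4, 10L)
  g <- proportional_threshold(C, 0.5)  # k = 3: (1,2) then first two ties
  kept <- which(metconn:::upper_vec(g$adjacency) != 0)
  expect_equal(kept, c(1L, 2L, 3L))  # (1,2), (1,3), (1,4)
})

test_that("analytic clustering/path/efficiency values hold", {
  for (n in c(4, 6)) {
    g <- graph_complete(n)
    d <- shortest_path_lengths(g)
    expect_equal(clustering_coefficient(g)$C, 1)
    expect_equal(characteristic_path_length(d)$L, 1)
    expect_equal(global_efficiency(d), 1)
  }
  p3 <- graph_path3()
  d3 <- shortest_path_lengths(p3)
  expect_equal(clustering_coefficient(p3)$C, 0)
  expect_equal(characteristic_path_length(d3)$L, 4 / 3)
  expect_equal(global_efficiency(d3), 5 / 6)
  expect_equal(d3[1, 3], 2)

  expect_equal(clustering_coefficient(graph_k4_minus_edge())$C, 5 / 6)
})

test_that("implementation matches brute-force oracles on random small graphs", {
  withr::with_seed(14, {
    for (rep in 1:40) {
      n <- sample(4:6, 1)
      m <- n * (n - 1) / 2
      bits <- rbinom(m, 1, 0.5)
      a <- adj_from_bits(bits, n)
      if (sum(a) == 0) next
      g <- as_thresholded_graph(a, mode = "binary")
      d <- shortest_path_lengths(g)
      expect_equal(d, oracle_distances_binary(a))
      expect_equal(clustering_coefficient(g)$C, oracle_clustering_binary(a))
      if (any(is.finite(d[row(d) != col(d)]))) {
        expect_equal(characteristic_path_length(d)$L, oracle_char_path(d))
      }
      expect_equal(global_efficiency(d), oracle_efficiency(d))
    }
  })
})

test_that("weighted distances match exhaustive simple-path search", {
  withr::with_seed(15, {
    for (rep in 1:12) {
      n <- 5
      v <- runif(n * (n - 1) / 2)
      v[runif(length(v)) < 0.4] <- 0
      a <- metconn:::sym_from_upper(v, n)
      if (sum(v > 0) < 2) next
      g <- as_thresholded_graph(a, mode = "weighted")
      expect_equal(shortest_path_lengths(g), oracle_distances_weighted(a),
                   tolerance = 1e-12)
    }
  })
})

test_that("weighted metrics with unit weights reduce to binary metrics", {
  withr::with_seed(16, bits <- rbinom(15, 1, 0.6))
  a <- adj_from_bits(bits, 6)
  gb <- as_thresholded_graph(a, mode = "binary")
  gw <- metconn:::new_thresholded_graph(a, gb$density, "weighted", 1:6)
  expect_equal(clustering_coefficient(gw)$C, clustering_coefficient(gb)$C,
               tolerance = 1e-10)
  expect_equal(shortest_path_lengths(gw), shortest_path_lengths(gb),
               tolerance = 1e-10)
})

test_that("disconnected graphs: infinite pairs, reachable-pair L, zero contribution to E", {
  # two disconnected dyads
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 1] <- 1
  a[3, 4] <- a[4, 3] <- 1
  d <- shortest_path_lengths(as_thresholded_graph(a))
  expect_true(all(!is.finite(d[1:2, 3:4])))
  pl <- characteristic_path_length(d)
  expect_equal(pl$L, 1)
  expect_equal(pl$unreachable_frac, 8 / 12)
  expect_equal(global_efficiency(d), (1 / 1) * 4 / 12)

  # isolated node: unreachable fraction 2(N-1)/(N(N-1))
  n <- 5
  b <- 1 - diag(n)
  b[n, ] <- b[, n] <- 0
  db <- shortest_path_lengths(as_thresholded_graph(b))
  expect_equal(characteristic_path_length(db)$unreachable_frac,
               2 * (n - 1) / (n * (n - 1)))

  empty <- metconn:::new_thresholded_graph(matrix(0, 3, 3), 0.1, "binary", 1:3)
  expect_equal(global_efficiency(shortest_path_lengths(empty)), 0)
  expect_error(characteristic_path_length(shortest_path_lengths(empty)),
               "no finite distances")
})

test_that("efficiency is non-decreasing in density for nested thresholds", {
  ss <- random_series(20, 15, seed = 17)
  C <- pearson_connectivity(ss)
  e <- vapply(seq(0.1, 0.9, by = 0.2), function(dd) {
    global_efficiency(shortest_path_lengths(proportional_threshold(C, dd)))
  }, numeric(1))
  expect_true(all(diff(e) >= -1e-12))
})

test_that("rewired nulls conserve edges, degrees and the weight multiset", {
  ss <- random_series(25, 12, seed = 18)
  g <- proportional_threshold(pearson_connectivity(ss), 0.3)
  nulls <- rewire_null(g, 8, seed = 19)
  a0 <- (g$adjacency != 0) * 1
  for (nl in nulls) {
    a1 <- (nl$adjacency != 0) * 1
    expect_equal(sum(a1), sum(a0))
    expect_equal(rowSums(a1), rowSums(a0))
    expect_equal(sort(metconn:::upper_vec(nl$adjacency)),
                 sort(metconn:::upper_vec(g$adjacency)))
  }
  # at least one null differs from the input
  expect_true(any(vapply(nulls, function(nl) any(nl$adjacency != g$adjacency),
                         logical(1))))
  # deterministic given seed
  n2 <- rewire_null(g, 8, seed = 19)
  expect_identical(lapply(nulls, `[[`, "adjacency"),
                   lapply(n2, `[[`, "adjacency"))
})

test_that("small-worldness of a complete graph is exactly 1", {
  g <- graph_complete(8)
  sw <- small_worldness(g, 10, seed = 20)
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)
})

test_that("sigma is stable under node relabeling", {
  g <- ring_lattice_graph(30, 6, p = 0.1, seed = 21)
  sw1 <- small_worldness(g, 60, seed = 22)
  perm <- withr::with_seed(23, sample(30))
  gp <- as_thresholded_graph(g$adjacency[perm, perm], mode = "binary")
  sw2 <- small_worldness(gp, 60, seed = 22)
  # deterministic pieces are exactly invariant
  expect_equal(sw1$C, sw2$C, tolerance = 1e-12)
  expect_equal(sw1$L, sw2$L, tolerance = 1e-12)
  # null means are Monte Carlo, so sigma agrees to sampling tolerance
  expect_equal(sw1$sigma, sw2$sigma, tolerance = 0.1)
})
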