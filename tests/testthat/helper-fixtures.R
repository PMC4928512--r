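# Shared fixture builders: small graphs and subject tables built in code.

graph_path3 <- function() as_thresholded_graph(adj_from_bits(c(1, 0, 1), 3))

graph_complete <- function(n) as_thresholded_graph(1 - diag(n))

graph_k4_minus_edge <- function() {
  a <- 1 - diag(4)
  a[3, 4] <- a[4, 3] <- 0
  as_thresholded_graph(a)
}

# Watts-Strogatz-style ring lattice: each node linked to k/2 neighbours per
# side, then each edge's far endpoint rewired with probability p.
ring_lattice_graph <- function(n, k, p = 0, seed = 1) {
  a <- matrix(0, n, n)
  for (s in seq_len(k / 2)) {
    idx <- cbind(seq_len(n), (seq_len(n) + s - 1) %% n + 1)
    a[idx] <- 1
    a[idx[, c(2, 1)]] <- 1
  }
  if (p > 0) {
    withr::with_seed(seed, {
      ij <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
      for (e in seq_len(nrow(ij))) {
        if (stats::runif(1) < p) {
          i <- ij[e, 1]
          free <- which(a[i, ] == 0 & seq_len(n) != i)
          if (length(free)) {
            j <- ij[e, 2]
            newj <- free[sample.int(length(free), 1)]
            a[i, j] <- a[j, i] <- 0
            a[i, newj] <- a[newj, i] <- 1
          }
        }
      }
    })
  }
  as_thresholded_graph(a)
}

erdos_renyi_graph <- function(n, p, seed = 1) {
  withr::with_seed(seed, {
    m <- n * (n - 1) / 2
    v <- as.numeric(stats::runif(m) < p)
    a <- matrix(0, n, n)
    ij <- which(upper.tri(a), arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), ]
    a[ij[v == 1, , drop = FALSE]] <- 1
    a[ij[v == 1, c(2, 1), drop = FALSE]] <- 1
    as_thresholded_graph(a)
  })
}

toy_series <- function(values, group = "g") {
  subject_series(values, seq_len(ncol(as.matrix(values))), group)
}

random_series <- function(n_subjects, n_regions, seed, group = "g") {
  vals <- withr::with_seed(seed, matrix(stats::rnorm(n_subjects * n_regions),
                                        n_subjects, n_regions))
  subject_series(vals, seq_len(n_regions), group)
}
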