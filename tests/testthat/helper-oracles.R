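# Independent brute-force oracles for graph metrics. These deliberately use
# different algorithms from the package: distances via matrix-power
# reachability (binary) or exhaustive simple-path search (weighted),
# triangles via diag(A^3).

oracle_distances_binary <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  reach <- a
  pow <- a
  d[a > 0 & d > 1] <- 1
  if (n > 2) {
    for (m in 2:(n - 1)) {
      pow <- pow %*% a
      newly <- pow > 0 & !is.finite(d)
      d[newly] <- m
    }
  }
  diag(d) <- 0
  d
}

# exhaustive minimal simple-path length search, lengths 1/w (small n only)
oracle_distances_weighted <- function(w) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  dfs <- function(node, target, visited, acc) {
    if (node == target) return(acc)
    out <- Inf
    for (nxt in seq_len(n)) {
      if (!visited[nxt] && is.finite(len[node, nxt])) {
        visited[nxt] <- TRUE
        out <- min(out, dfs(nxt, target, visited, acc + len[node, nxt]))
        visited[nxt] <- FALSE
      }
    }
    out
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        visited <- rep(FALSE, n)
        visited[i] <- TRUE
        best[i, j] <- dfs(i, j, visited, 0)
      }
    }
  }
  best
}

oracle_clustering_binary <- function(a) {
  k <- rowSums(a)
  tri <- diag(a %*% a %*% a) / 2
  ci <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  mean(ci)
}

oracle_char_path <- function(d) {
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

oracle_efficiency <- function(d) {
  off <- d[row(d) != col(d)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

oracle_connected <- function(a) {
  n <- nrow(a)
  b <- a + diag(n)
  pow <- b
  for (m in seq_len(n)) pow <- pow %*% b
  all(pow > 0)
}

# adjacency matrix from an edge bitmask over the canonical (i < j) pairs
adj_from_bits <- function(bits, n) {
  ij <- which(upper.tri(diag(n)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  a <- matrix(0, n, n)
  on <- which(bits == 1)
  a[ij[on, , drop = FALSE]] <- 1
  a[ij[on, c(2, 1), drop = FALSE]] <- 1
  a
}

int_to_bits <- function(x, m) as.integer(intToBits(x))[seq_len(m)]
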