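#' Thresholded graph at a target connection density
#'
#' Retains the top `k = round(density * M)` edges of a connectivity matrix
#' (`M = N(N-1)/2`, rounding half away from zero) so that graphs compared
#' across groups have identical edge counts — proportional (density)
#' thresholding. Ranking is by signed correlation by default (strongest
#' positive first); `ranking = "absolute"` ranks by `|r|`. Ties at the cut
#' are resolved by canonical (i, j) index order, making the selection
#' deterministic. Binary mode sets retained weights to 1; weighted mode
#' keeps the correlation values.
#'
#' @param C A `connectivity_matrix` (or plain symmetric matrix).
#' @param density Fraction of possible edges to retain, in (0, 1].
#' @param mode `"weighted"` (default; the mode used for the network
#'   analysis) or `"binary"`.
#' @param ranking `"signed"` (default) or `"absolute"`.
#' @return A `thresholded_graph`: `adjacency` (symmetric, zero diagonal),
#'   `density`, `mode`, `region_ids`.
#' @export
proportional_threshold <- function(C, density, mode = c("weighted", "binary"),
                                   ranking = c("signed", "absolute")) {
  mode <- match.arg(mode)
  ranking <- match.arg(ranking)
  check_number(density, "density", lower = 0, upper = 1, strict_lower = TRUE)
  if (inherits(C, "connectivity_matrix")) {
    v <- C$values
    ids <- C$region_ids
  } else {
    v <- as.matrix(C)
    ids <- seq_len(nrow(v))
  }
  n <- nrow(v)
  w <- upper_vec(v)
  m <- length(w)
  k <- as.integer(round_half_away(density * m))
  if (k < 1L) abort("density too low: no edges survive rounding")
  key <- if (ranking == "absolute") abs(w) else w
  # stable decreasing order => ties resolved by canonical index order
  sel <- order(-key)[seq_len(k)]
  keep <- logical(m)
  keep[sel] <- TRUE
  wv <- if (mode == "binary") as.numeric(keep) else w * keep
  new_thresholded_graph(sym_from_upper(wv, n), density, mode, ids)
}

#' @noRd
new_thresholded_graph <- function(adjacency, density, mode, region_ids) {
  diag(adjacency) <- 0
  structure(
    list(adjacency = adjacency, density = density, mode = mode,
         region_ids = as.integer(region_ids)),
    class = "thresholded_graph"
  )
}

#' Wrap an adjacency matrix as a `thresholded_graph`
#'
#' For graphs built directly (lattices, random graphs, imported networks)
#' rather than by thresholding a connectivity matrix.
#'
#' @param adjacency Symmetric non-negative weight matrix; the diagonal is
#'   zeroed.
#' @param mode `"binary"` or `"weighted"`; default guesses binary when all
#'   nonzero weights equal 1.
#' @return A `thresholded_graph` with density set to the realized edge
#'   fraction.
#' @export
as_thresholded_graph <- function(adjacency, mode = NULL) {
  adjacency <- as.matrix(adjacency)
  if (!isSymmetric(unname(adjacency), tol = 1e-12)) abort("adjacency must be symmetric")
  diag(adjacency) <- 0
  nz <- adjacency[adjacency != 0]
  mode <- mode %||% (if (all(nz == 1)) "binary" else "weighted")
  n <- nrow(adjacency)
  dens <- sum(upper_vec(adjacency) != 0) / (n * (n - 1) / 2)
  new_thresholded_graph(adjacency, dens, mode, seq_len(n))
}

#' @export
print.thresholded_graph <- function(x, ...) {
  cat(sprintf("<thresholded_graph> %d nodes, %d edges (density %.3f, %s)\n",
              nrow(x$adjacency), graph_edge_count(x), x$density, x$mode))
  invisible(x)
}

#' @noRd
graph_edge_count <- function(g) sum(upper_vec(g$adjacency) != 0)

#' Effective weight matrix for metric computation
#'
#' Negative weights are meaningless under the weighted formulas
#' (cube roots, inverse-weight lengths), so they are dropped (treated as
#' absent) unless the graph was thresholded on absolute values upstream.
#' @noRd
metric_weights <- function(g) {
  w <- g$adjacency
  w[w < 0] <- 0
  w
}

#' Clustering coefficient
#'
#' Local interconnectivity: in binary mode `C_i = 2 t_i / (k_i (k_i - 1))`
#' where `t_i` counts triangles at node i — the fraction of a node's
#' neighbour pairs that are themselves connected; `C_i = 0` for degree < 2.
#' In weighted mode the Onnela geometric-mean form is used:
#' `C_i = (1 / (k_i (k_i - 1))) * sum_{j,h} (w'_ij w'_ih w'_jh)^(1/3)` with
#' weights normalized by the maximum weight. The network-level coefficient
#' is the mean of `C_i` over all N nodes.
#'
#' @param g A `thresholded_graph` with at least 3 nodes.
#' @return List with `C` (global mean) and `Ci` (per-node vector).
#' @export
clustering_coefficient <- function(g) {
  stopifnot(inherits(g, "thresholded_graph"))
  n <- nrow(g$adjacency)
  if (n < 3L) abort("clustering requires at least 3 nodes")
  w <- metric_weights(g)
  a <- (w != 0) * 1
  k <- rowSums(a)
  denom <- k * (k - 1)
  if (g$mode == "binary") {
    # neighbour-submatrix edge count per node
    tri <- vapply(seq_len(n), function(i) {
      nb <- which(a[i, ] != 0)
      if (length(nb) < 2L) return(0)
      sum(a[nb, nb]) / 2
    }, numeric(1))
    ci <- ifelse(denom > 0, 2 * tri / denom, 0)
  } else {
    mx <- max(w)
    if (mx == 0) {
      ci <- rep(0, n)
    } else {
      wh <- (w / mx)^(1 / 3)
      num <- diag(wh %*% wh %*% wh)
      ci <- ifelse(denom > 0, num / denom, 0)
    }
  }
  list(C = mean(ci), Ci = ci)
}

#' All-pairs shortest path lengths
#'
#' Binary mode counts hops; weighted mode maps each retained edge to a
#' length `1 / w` (strong correlations are short) and minimizes the summed
#' length. Unreachable pairs are `Inf`. Computed by Floyd-Warshall over the
#' dense matrix (compiled; dense brain graphs make sparse algorithms
#' pointless at N = 90).
#'
#' @param g A `thresholded_graph`.
#' @return Symmetric matrix of distances with zero diagonal.
#' @export
shortest_path_lengths <- function(g) {
  stopifnot(inherits(g, "thresholded_graph"))
  w <- metric_weights(g)
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  edge <- w != 0
  d[edge] <- if (g$mode == "binary") 1 else 1 / w[edge]
  diag(d) <- 0
  .fw_distances(d)
}

#' Characteristic path length
#'
#' Mean shortest-path length over all ordered reachable pairs i != j. The
#' fraction of unreachable pairs is reported alongside; at low densities
#' graphs can fragment and L is then a within-component summary.
#'
#' @param d Distance matrix from [shortest_path_lengths()].
#' @return List with `L` and `unreachable_frac`.
#' @export
characteristic_path_length <- function(d) {
  off <- d[row(d) != col(d)]
  finite <- is.finite(off)
  if (!any(finite)) abort("no finite distances: graph fully disconnected")
  list(L = mean(off[finite]), unreachable_frac = mean(!finite))
}

#' Global efficiency
#'
#' `E = (1 / (N (N - 1))) * sum_{i != j} 1 / d_ij`, with `1 / Inf = 0` so
#' disconnected pairs simply contribute nothing. Measures integration: high
#' E means short functional distances throughout the network.
#'
#' @param d Distance matrix from [shortest_path_lengths()].
#' @return Numeric scalar.
#' @export
global_efficiency <- function(d) {
  n <- nrow(d)
  if (n < 2L) abort("efficiency requires at least 2 nodes")
  inv <- 1 / d
  inv[!is.finite(inv) | row(d) == col(d)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' All core metrics of one graph
#'
#' @param g A `thresholded_graph`.
#' @return One-row tibble: `C`, `E`, `L`, `unreachable_frac`, `n_nodes`,
#'   `n_edges`, `density`, `mode`.
#' @export
network_metrics <- function(g) {
  d <- shortest_path_lengths(g)
  cl <- clustering_coefficient(g)
  pl <- characteristic_path_length(d)
  tibble(C = cl$C, E = global_efficiency(d), L = pl$L,
         unreachable_frac = pl$unreachable_frac,
         n_nodes = nrow(g$adjacency), n_edges = graph_edge_count(g),
         density = g$density, mode = g$mode)
}

#' Degree-preserving rewired null graphs
#'
#' Generates random reference networks by repeated double-edge swaps
#' ((a-b, c-d) -> (a-d, c-b)), each swap preserving every node's degree and
#' hence the graph's density — the constraint the null model must satisfy.
#' In weighted mode the multiset of weights is preserved: after rewiring,
#' the original weights are reassigned to the rewired edge positions
#' uniformly at random. If no admissible swap exists (e.g. a complete
#' graph, where rewiring cannot change anything), the graph is returned
#' unchanged; for incomplete graphs this triggers a warning and a fallback
#' to density-only rewiring (edge positions redrawn uniformly).
#'
#' @param g A `thresholded_graph` with at least 2 edges.
#' @param n_randomizations Number of null graphs (the reference analysis
#'   uses 1000).
#' @param seed Integer seed; deterministic.
#' @param swaps_per_edge Target accepted swaps per edge (default 10).
#' @return List of `thresholded_graph`s.
#' @export
rewire_null <- function(g, n_randomizations = 1000, seed = 1L,
                        swaps_per_edge = 10) {
  stopifnot(inherits(g, "thresholded_graph"))
  if (graph_edge_count(g) < 2L) abort("rewiring needs at least 2 edges")
  withr::with_seed(seed, {
    lapply(seq_len(n_randomizations), function(i) rewire_once(g, swaps_per_edge))
  })
}

#' @noRd
rewire_once <- function(g, swaps_per_edge) {
  n <- nrow(g$adjacency)
  complete <- graph_edge_count(g) == n * (n - 1) / 2
  ij <- which(upper.tri(g$adjacency) & g$adjacency != 0, arr.ind = TRUE)
  m <- nrow(ij)
  if (complete) {
    # no swap can change a complete graph; the null is the graph itself
    e <- ij
  } else {
    target <- as.integer(ceiling(swaps_per_edge * m))
    e <- .rewire_edges(ij, n, target, 20L * target)
    if (attr(e, "accepted") == 0L) {
      warn("no admissible degree-preserving swap; falling back to density-only rewiring")
      pos <- sample.int(n * (n - 1) / 2, m)
      e <- edge_index(n)[pos, , drop = FALSE]
    }
  }
  av <- numeric(n * (n - 1) / 2)
  # canonical linear position of each rewired edge (i < j): see edge_index
  lin <- edge_linear_index(e[, 1L], e[, 2L], n)
  if (g$mode == "weighted") {
    wts <- upper_vec(g$adjacency)
    wts <- wts[wts != 0]
    av[lin] <- sample(wts, length(wts))
  } else {
    av[lin] <- 1
  }
  new_thresholded_graph(sym_from_upper(av, n), g$density, g$mode, g$region_ids)
}

#' Linear position of edge (i, j), i < j, in canonical edge order
#' @noRd
edge_linear_index <- function(i, j, n) {
  (i - 1L) * n - (i * (i - 1L)) %/% 2L + (j - i)
}

#' Small-worldness against rewired nulls
#'
#' A small-world network is more clustered than a random network with the
#' same degrees (`gamma = C_real / C_rand >> 1`) while keeping nearly the
#' same characteristic path length (`lambda = L_real / L_rand ~ 1`); their
#' ratio `sigma = gamma / lambda > 1` summarizes the property. Null means
#' are taken over `n_randomizations` rewired graphs.
#'
#' @param g A `thresholded_graph` with at least one finite distance.
#' @param n_randomizations Null graphs to average (reference value 1000).
#' @param seed Integer seed.
#' @return One-row tibble: `gamma`, `lambda`, `sigma`, `C`, `L`, `E`,
#'   `C_rand`, `L_rand`, `n_randomizations`, `density`.
#' @export
small_worldness <- function(g, n_randomizations = 1000, seed = 1L) {
  mt <- network_metrics(g)
  nulls <- rewire_null(g, n_randomizations, seed)
  c_rand <- mean(vapply(nulls, function(x) clustering_coefficient(x)$C, numeric(1)))
  l_rand <- mean(vapply(nulls, function(x) {
    characteristic_path_length(shortest_path_lengths(x))$L
  }, numeric(1)))
  if (c_rand == 0 || l_rand == 0) abort("degenerate null: zero mean C or L")
  gamma <- mt$C / c_rand
  lambda <- mt$L / l_rand
  tibble(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
         C = mt$C, L = mt$L, E = mt$E, C_rand = c_rand, L_rand = l_rand,
         n_randomizations = n_randomizations, density = g$density)
}

#' Write a graph as a weighted edge-list TSV
#' @param g A `thresholded_graph`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_graph_edges <- function(g, path) {
  ij <- edge_index(nrow(g$adjacency))
  w <- upper_vec(g$adjacency)
  keep <- w != 0
  readr::write_tsv(tibble(
    region_i = g$region_ids[ij[keep, "i"]],
    region_j = g$region_ids[ij[keep, "j"]],
    weight = w[keep]
  ), path)
  invisible(path)
}
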