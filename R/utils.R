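#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Check a scalar is a single finite number
#' @noRd
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    abort(sprintf("`%s` = %g is out of range", name, x))
  }
  invisible(x)
}

.edge_cache <- new.env(parent = emptyenv())

#' Indices of the strict upper triangle in canonical (i < j) edge order
#'
#' Edges of an N-node undirected graph are indexed as unordered pairs
#' (i, j), i < j, ordered by i then j. Returns a two-column integer matrix;
#' cached per size since it sits on hot permutation paths.
#' @noRd
edge_index <- function(n) {
  key <- as.character(n)
  hit <- .edge_cache[[key]]
  if (!is.null(hit)) return(hit$ij)
  ij <- which(upper.tri(diag(n)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
  colnames(ij) <- c("i", "j")
  .edge_cache[[key]] <- list(
    ij = ij,
    up = (ij[, 2L] - 1L) * n + ij[, 1L],   # column-major positions (i, j)
    lo = (ij[, 1L] - 1L) * n + ij[, 2L]    # and their transposes (j, i)
  )
  ij
}

#' Extract the strict upper triangle as a vector in canonical edge order
#' @noRd
upper_vec <- function(m) {
  n <- nrow(m)
  edge_index(n)
  m[.edge_cache[[as.character(n)]]$up]
}

#' Rebuild a symmetric matrix (zero diagonal) from a canonical edge vector
#' @noRd
sym_from_upper <- function(v, n) {
  edge_index(n)
  cache <- .edge_cache[[as.character(n)]]
  m <- matrix(0, n, n)
  m[cache$up] <- v
  m[cache$lo] <- v
  m
}

#' Round half away from zero
#' @noRd
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
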