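#' Shared permutation scheme for two-group tests
#'
#' Pre-draws the sequence of group relabelings used by both the edgewise
#' connectivity test and the network-parameter test, so the two analyses
#' share exactly the same null draws. Each relabeling assigns `nA` of the
#' pooled `nA + nB` subjects to group A (the rest to B) uniformly at random
#' without replacement — the classical two-sample permutation null under
#' subject exchangeability.
#'
#' When the complete assignment set is small enough
#' (`choose(nA + nB, nA) <= n_permutations` and `exhaustive = "auto"`), all
#' distinct assignments are enumerated instead and p-values downstream
#' become exact.
#'
#' @param nA,nB Group sizes (each >= 3).
#' @param n_permutations Number of relabelings to draw (default 10000, the
#'   standard choice for this analysis).
#' @param seed Integer seed; the scheme is reproducible from it.
#' @param exhaustive `"auto"` (enumerate when feasible), `"never"` (always
#'   Monte Carlo), or `"always"` (error if the assignment set is larger than
#'   `n_permutations`).
#' @return A `permutation_scheme`: list with `assign_A` (n_draws x nA matrix
#'   of pooled indices assigned to A), `nA`, `nB`, `n_permutations`, `seed`,
#'   `exhaustive` flag.
#' @export
make_scheme <- function(nA, nB, n_permutations = 10000, seed = 1L,
                        exhaustive = c("auto", "never", "always")) {
  exhaustive <- match.arg(exhaustive)
  check_number(nA, "nA", lower = 3)
  check_number(nB, "nB", lower = 3)
  check_number(n_permutations, "n_permutations", lower = 1)
  n <- nA + nB
  n_total <- choose(n, nA)
  do_exhaustive <- switch(exhaustive,
    auto = n_total <= n_permutations,
    never = FALSE,
    always = {
      if (n_total > n_permutations) {
        abort(sprintf("exhaustive enumeration needs %d draws > n_permutations", n_total))
      }
      TRUE
    }
  )
  if (do_exhaustive) {
    assign_A <- t(combn(n, nA))
  } else {
    assign_A <- withr::with_seed(seed, {
      t(vapply(seq_len(n_permutations),
               function(i) sort(sample.int(n, nA)),
               integer(nA)))
    })
  }
  structure(
    list(assign_A = assign_A, nA = as.integer(nA), nB = as.integer(nB),
         n_permutations = nrow(assign_A), seed = as.integer(seed),
         exhaustive = do_exhaustive),
    class = "permutation_scheme"
  )
}

#' @export
print.permutation_scheme <- function(x, ...) {
  cat(sprintf("<permutation_scheme> %d + %d subjects, %d relabelings (%s), seed %d\n",
              x$nA, x$nB, x$n_permutations,
              if (x$exhaustive) "exhaustive" else "Monte Carlo", x$seed))
  invisible(x)
}

#' Checksum of a scheme's relabeling sequence
#'
#' Lets callers assert that two analyses reused the same null draws.
#' @param scheme A `permutation_scheme`.
#' @return A numeric checksum.
#' @export
scheme_checksum <- function(scheme) {
  sum(scheme$assign_A * row(scheme$assign_A)) %% 2147483647
}

#' Permutation p-values from counts
#'
#' Monte Carlo draws get the add-one estimator (1 + count) / (n + 1), which
#' can never be 0 and is valid at every n. Exhaustive schemes include the
#' observed assignment among the draws, so the plain proportion is already
#' the exact p-value.
#' @noRd
perm_pvalue <- function(count, n_draws, exhaustive) {
  if (exhaustive) count / n_draws else (1 + count) / (n_draws + 1)
}

#' Edgewise permutation test on subtracted connectivity matrices
#'
#' Tests every region pair for a group difference in metabolic connectivity.
#' The observed statistic per edge is the subtracted correlation
#' `delta = r_A - r_B`. For each relabeling in the scheme, both group
#' matrices are recomputed from the relabelled pooled subjects and
#' subtracted; two-tailed p-values compare `|delta|` against this null.
#' Familywise error across all `N(N-1)/2` edges is controlled by the
#' max-statistic null: each edge's `|delta|` is compared against the
#' permutation distribution of the maximum `|delta|` over all edges, the
#' standard nonparametric strong-control FWE procedure.
#'
#' A relabeling that produces a zero-variance region column (possible only
#' for degenerate synthetic input) contributes `+Inf` for the affected
#' edges, which is conservative; a message notes how many draws were hit.
#'
#' @param seriesA,seriesB [subject_series()] for the two groups; identical
#'   region sets and order.
#' @param scheme A [make_scheme()] result matching the group sizes.
#' @return An `edge_permutation_test`: `delta` (matrix A - B),
#'   `p_uncorrected`, `p_fwe` (matrices), `region_ids`, `n_permutations`,
#'   `scheme_checksum`, group labels.
#' @export
permute_edge_test <- function(seriesA, seriesB, scheme) {
  stopifnot(inherits(scheme, "permutation_scheme"))
  prep <- pool_series(seriesA, seriesB, scheme)
  p <- length(prep$codes)
  obs <- abs(prep$obs_delta_vec)

  count_unc <- numeric(length(obs))
  count_max <- numeric(length(obs))
  n_degenerate <- 0L
  for (k in seq_len(scheme$n_permutations)) {
    pd <- perm_delta_vec(prep$pooled, scheme$assign_A[k, ])
    if (anyNA(pd)) {
      n_degenerate <- n_degenerate + 1L
      pd[is.na(pd)] <- Inf
    }
    apd <- abs(pd)
    count_unc <- count_unc + (apd >= obs)
    count_max <- count_max + (max(apd) >= obs)
  }
  if (n_degenerate > 0L) {
    warn(sprintf("%d permutation draw(s) had zero-variance columns; affected statistics set to +Inf (conservative)",
                 n_degenerate))
  }
  p_unc <- perm_pvalue(count_unc, scheme$n_permutations, scheme$exhaustive)
  p_fwe <- perm_pvalue(count_max, scheme$n_permutations, scheme$exhaustive)
  structure(
    list(
      delta = sym_from_upper(prep$obs_delta_vec, p),
      p_uncorrected = sym_from_upper(p_unc, p) + diag(1, p),
      p_fwe = sym_from_upper(p_fwe, p) + diag(1, p),
      region_ids = prep$codes,
      n_permutations = scheme$n_permutations,
      exhaustive = scheme$exhaustive,
      scheme_checksum = scheme_checksum(scheme),
      group_a = group_label(seriesA), group_b = group_label(seriesB)
    ),
    class = "edge_permutation_test"
  )
}

#' Pool two series for permutation, with the observed delta
#' @noRd
pool_series <- function(seriesA, seriesB, scheme) {
  codes <- region_ids(seriesA)
  if (!identical(codes, region_ids(seriesB))) {
    abort("region sets/order differ between the two groups")
  }
  mA <- series_matrix(seriesA)
  mB <- series_matrix(seriesB)
  if (nrow(mA) != scheme$nA || nrow(mB) != scheme$nB) {
    abort("scheme group sizes do not match the series")
  }
  cA <- pearson_connectivity(seriesA)$values
  cB <- pearson_connectivity(seriesB)$values
  list(pooled = rbind(mA, mB), codes = codes,
       obs_delta_vec = upper_vec(cA - cB))
}

#' Subtracted correlation vector for one relabeling (NA where degenerate)
#' @noRd
perm_delta_vec <- function(pooled, idxA) {
  a <- pooled[idxA, , drop = FALSE]
  b <- pooled[-idxA, , drop = FALSE]
  d <- suppressWarnings(stats::cor(a) - stats::cor(b))
  upper_vec(d)
}

#' @export
print.edge_permutation_test <- function(x, ...) {
  cat(sprintf("<edge_permutation_test> %s vs %s: %d regions, %d permutations (%s)\n",
              x$group_a, x$group_b, length(x$region_ids), x$n_permutations,
              if (x$exhaustive) "exhaustive" else "Monte Carlo"))
  invisible(x)
}

#' @describeIn permute_edge_test Edge tibble: `region_i`, `region_j`,
#'   `delta`, `p_uncorrected`, `p_fwe`.
#' @param x An `edge_permutation_test`.
#' @param ... Unused.
#' @export
tidy.edge_permutation_test <- function(x, ...) {
  ij <- edge_index(length(x$region_ids))
  tibble(
    region_i = x$region_ids[ij[, "i"]],
    region_j = x$region_ids[ij[, "j"]],
    delta = upper_vec(x$delta),
    p_uncorrected = upper_vec(x$p_uncorrected),
    p_fwe = upper_vec(x$p_fwe)
  )
}

#' @describeIn permute_edge_test One-row summary with edge counts at
#'   conventional thresholds.
#' @export
glance.edge_permutation_test <- function(x, ...) {
  td <- tidy(x)
  tibble(
    group_a = x$group_a, group_b = x$group_b,
    n_regions = length(x$region_ids), n_edges = nrow(td),
    n_permutations = x$n_permutations,
    n_sig_fwe_05 = sum(td$p_fwe < 0.05),
    n_sig_unc_0001 = sum(td$p_uncorrected < 1e-4),
    min_p_fwe = min(td$p_fwe)
  )
}

#' Edges passing a significance threshold
#'
#' Filters the edge test at `alpha` under the chosen correction and returns
#' the surviving edges sorted by `|delta|` descending (ties broken by
#' canonical (i, j) index order). Per-region counts of significant edges —
#' the "degree" used for node sizing in renderings — come along as the
#' `degree` attribute and via [edge_degree()].
#'
#' @param result An [permute_edge_test()] result.
#' @param alpha Significance level in (0, 1).
#' @param correction `"fwe"` (default) or `"uncorrected"`.
#' @return A tibble of significant edges with attributes `alpha`,
#'   `correction`, `degree`.
#' @export
significant_edges <- function(result, alpha = 0.05,
                              correction = c("fwe", "uncorrected")) {
  stopifnot(inherits(result, "edge_permutation_test"))
  correction <- match.arg(correction)
  check_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  td <- tidy(result)
  pcol <- if (correction == "fwe") td$p_fwe else td$p_uncorrected
  keep <- which(pcol < alpha)
  out <- td[keep, ]
  out$p <- pcol[keep]
  # stable order: |delta| descending, canonical index order breaks ties
  out <- out[order(-abs(out$delta)), ]
  degree <- tibble(code = result$region_ids,
                   degree = vapply(result$region_ids, function(cd) {
                     sum(out$region_i == cd | out$region_j == cd)
                   }, integer(1)))
  structure(out, alpha = alpha, correction = correction, degree = degree,
            class = class(tibble()))
}

#' Per-region significant-edge counts of a [significant_edges()] result
#' @param edges Result of [significant_edges()].
#' @return Tibble with columns `code`, `degree`.
#' @export
edge_degree <- function(edges) attr(edges, "degree")

#' Write an edge test as a flat TSV edge list
#' @param result An `edge_permutation_test`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_test <- function(result, path) {
  readr::write_tsv(tidy(result), path)
  invisible(path)
}
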