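# Structural covariance network construction: residualize thickness on
# covariates, correlate regions across subjects within each group, then
# binarize across a density grid by keeping the top-ranked correlations.
# Ranking once per association matrix guarantees nested edge sets across
# densities.

#' Density grid for network thresholding
#'
#' Computed as `d_min + step * (0:n)` with `n = round((d_max - d_min)/step)`
#' to avoid floating-point drift; the default 0.38-0.50 range with step 0.01
#' has exactly 13 points.
#'
#' @param d_min,d_max,step Density bounds and increment, all in (0, 1].
#' @return Numeric vector of densities.
#' @examples
#' density_grid()
#' @export
density_grid <- function(d_min = 0.38, d_max = 0.50, step = 0.01) {
  if (d_min <= 0 || d_max > 1 || d_min > d_max || step <= 0) {
    abort("Need 0 < d_min <= d_max <= 1 and step > 0.")
  }
  n <- round((d_max - d_min) / step)
  round(d_min + step * (0:n), 10)
}

#' Residualize thickness on covariates
#'
#' Ordinary least-squares residuals of each region on an intercept plus the
#' covariates; zero-variance covariates are dropped (with a message), so an
#' intercept-only fit simply centres each region.
#'
#' @param thickness Subjects-by-regions numeric matrix.
#' @param covariates Data frame or matrix (subjects by k, `k <` subject
#'   count) of numeric covariates.
#' @return Residual matrix with the input's dimnames; residuals are
#'   orthogonal to every covariate to numerical precision.
#' @export
residualize <- function(thickness, covariates) {
  thickness <- as.matrix(thickness)
  X <- as.matrix(as.data.frame(covariates))
  storage.mode(X) <- "double"
  keep <- apply(X, 2, function(c) sd(c) > 0)
  if (any(!keep)) {
    inform(sprintf("Dropping zero-variance covariate(s): %s",
                   paste(colnames(X)[!keep], collapse = ", ")))
    X <- X[, keep, drop = FALSE]
  }
  design <- cbind(`(Intercept)` = 1, X)
  if (ncol(design) >= nrow(thickness)) {
    abort("More covariates than subjects.")
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    abort(sprintf("Rank-deficient covariate design; collinear column(s): %s",
                  paste(dropped, collapse = ", ")))
  }
  res <- qr.resid(qrd, thickness)
  dimnames(res) <- dimnames(thickness)
  res
}

#' Inter-regional association matrix
#'
#' Pearson correlation between every pair of regions across subjects, with
#' the diagonal set to zero.
#'
#' @param residuals Subjects-by-regions matrix (normally from
#'   [residualize()]; >= 3 subjects, no zero-variance region).
#' @return Symmetric regions-by-regions matrix, entries in `[-1, 1]`,
#'   diagonal 0.
#' @export
association_matrix <- function(residuals) {
  residuals <- as.matrix(residuals)
  if (nrow(residuals) < 3) abort("Need >= 3 subjects.")
  v <- apply(residuals, 2, sd)
  if (any(v == 0)) {
    abort(sprintf("Zero-variance region(s): %s",
                  paste(colnames(residuals)[v == 0], collapse = ", ")))
  }
  M <- cor(residuals)
  diag(M) <- 0
  M
}

# off-diagonal pairs ordered by decreasing association, ties broken by
# (row, col) lexicographic order; returns list(i, j, value)
edge_ranking <- function(M) {
  n <- nrow(M)
  ut <- which(upper.tri(M))
  vals <- M[ut]
  j <- ((ut - 1) %/% n) + 1
  i <- ut - (j - 1) * n
  o <- order(-vals, i, j)
  list(i = i[o], j = j[o], value = vals[o], n = n)
}

adjacency_from_ranking <- function(ranking, k) {
  n <- ranking$n
  A <- matrix(0, n, n)
  if (k > 0) {
    idx <- seq_len(k)
    A[cbind(ranking$i[idx], ranking$j[idx])] <- 1
    A[cbind(ranking$j[idx], ranking$i[idx])] <- 1
  }
  A
}

#' Binarize an association matrix at a target density
#'
#' Keeps the `round(d * E_max)` most strongly ranked off-diagonal pairs
#' (`E_max = n(n-1)/2`; half-away-from-zero rounding) as edges. Because
#' edges are taken from a single ranking of `M`, thresholded graphs are
#' nested across densities and invariant under any strictly increasing
#' transform of the entries. Admitting a non-positive correlation (possible
#' in weakly correlated data at high densities) triggers a warning.
#'
#' @param M Association matrix.
#' @param d Target density in (0, 1].
#' @return Symmetric 0/1 adjacency matrix with zero diagonal and exactly
#'   `round(d * E_max)` edges.
#' @export
threshold_at_density <- function(M, d) {
  if (d <= 0 || d > 1) abort("`d` must be in (0, 1].")
  ranking <- edge_ranking(M)
  e_max <- length(ranking$value)
  k <- round_half_up(d * e_max)
  if (k > sum(is.finite(ranking$value))) {
    abort("Requested edge count exceeds the number of finite associations.")
  }
  if (k > 0 && ranking$value[k] <= 0) {
    warn("Density threshold admits non-positive correlations as edges.")
  }
  A <- adjacency_from_ranking(ranking, k)
  dimnames(A) <- dimnames(M)
  A
}

# connected iff one component; operates on the first k ranked edges using
# union-find, returning the smallest k connecting the graph (Inf if none)
connecting_edge_count <- function(ranking) {
  n <- ranking$n
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  comps <- n
  for (k in seq_along(ranking$i)) {
    ri <- find(ranking$i[k]); rj <- find(ranking$j[k])
    if (ri != rj) {
      parent[ri] <- rj
      comps <- comps - 1
      if (comps == 1) return(k)
    }
  }
  Inf
}

#' Minimum fully-connected density
#'
#' The smallest density on a `step`-resolution grid at which every supplied
#' association matrix, thresholded by [threshold_at_density()], forms a
#' single connected component. Group metric comparison is only meaningful
#' at densities at or above this value.
#'
#' @param Ms A single association matrix or a (possibly named) list of them.
#' @param step Grid resolution (default 0.01).
#' @return List with `overall` (max over groups) and `per_group` tibble
#'   (`group`, `dmin`).
#' @export
min_connected_density <- function(Ms, step = 0.01) {
  if (is.matrix(Ms)) Ms <- list(Ms)
  if (!length(Ms)) abort("Need at least one association matrix.")
  if (is.null(names(Ms))) names(Ms) <- paste0("group", seq_along(Ms))
  grid <- density_grid(step, 1, step)
  dmin <- vapply(Ms, function(M) {
    ranking <- edge_ranking(M)
    k_star <- connecting_edge_count(ranking)
    if (!is.finite(k_star)) {
      abort("No density <= 1 connects the graph (isolated node in M).")
    }
    e_max <- length(ranking$value)
    grid[which(round_half_up(grid * e_max) >= k_star)[1]]
  }, 0)
  list(overall = max(dmin),
       per_group = tibble::tibble(group = names(Ms), dmin = unname(dmin)))
}

new_scn_network <- function(group, M, grid) {
  ranking <- edge_ranking(M)
  e_max <- length(ranking$value)
  ks <- round_half_up(grid * e_max)
  adjacency <- lapply(ks, function(k) {
    A <- adjacency_from_ranking(ranking, k)
    dimnames(A) <- dimnames(M)
    A
  })
  names(adjacency) <- format(grid)
  k_star <- connecting_edge_count(ranking)
  dmin <- if (is.finite(k_star)) {
    full <- density_grid(0.01, 1, 0.01)
    full[which(round_half_up(full * e_max) >= k_star)[1]]
  } else NA_real_
  structure(
    list(group = group, M = M, densities = grid, adjacency = adjacency,
         edge_counts = ks, dmin = dmin),
    class = "scn_network"
  )
}

#' @export
print.scn_network <- function(x, ...) {
  cat(sprintf("<scn_network> group '%s': %d nodes, %d densities (%.2f-%.2f), Dmin = %.2f\n",
              x$group, nrow(x$M), length(x$densities),
              min(x$densities), max(x$densities), x$dmin))
  invisible(x)
}

#' Build per-group structural covariance networks
#'
#' For each group: residualize thickness on the covariates (within the
#' group, so covariate fits cannot leak group differences), correlate
#' regions, and threshold over the density grid. Warns when the grid starts
#' below the computed minimum fully-connected density.
#'
#' @param cohort An `scn_cohort`.
#' @param grid Density grid from [density_grid()].
#' @param covariates Covariate column names in `cohort$subjects`
#'   (default age and sex); use `character()` for raw centring only.
#' @return An `scn_networks` object: `$networks` (named list of per-group
#'   `scn_network`s, region order aligned), `$grid`, `$atlas`, `$dmin`
#'   (overall minimum connected density).
#' @examples
#' cohort <- simulate_cohort(cohort_spec(
#'   n_per_group = c(case = 30, control = 30),
#'   atlas = region_atlas(sprintf("R%02d", 1:20)), seed = 1
#' ), clinical = FALSE)
#' nets <- build_networks(cohort, density_grid(0.38, 0.5, 0.01))
#' nets$dmin
#' @export
build_networks <- function(cohort, grid = density_grid(),
                           covariates = c("age", "sex")) {
  s <- cohort$subjects
  nets <- lapply(levels(s$group), function(g) {
    rows <- s$group == g
    resid <- if (length(covariates)) {
      residualize(cohort$thickness[rows, , drop = FALSE],
                  s[rows, covariates, drop = FALSE])
    } else {
      scale(cohort$thickness[rows, , drop = FALSE], scale = FALSE)
    }
    new_scn_network(g, association_matrix(resid), grid)
  })
  names(nets) <- levels(s$group)
  dmin <- max(vapply(nets, `[[`, 0, "dmin"))
  if (min(grid) < dmin) {
    warn(sprintf(
      "Grid starts at %.2f but graphs are only fully connected from %.2f; metrics below Dmin use reachable pairs only.",
      min(grid), dmin
    ))
  }
  structure(
    list(networks = nets, grid = grid, atlas = cohort$atlas,
         covariates = covariates, dmin = dmin),
    class = "scn_networks"
  )
}

#' @export
print.scn_networks <- function(x, ...) {
  cat(sprintf("<scn_networks> %d group(s), %d nodes, densities %.2f-%.2f, overall Dmin = %.2f\n",
              length(x$networks), nrow(x$atlas),
              min(x$grid), max(x$grid), x$dmin))
  for (nw in x$networks) print(nw)
  invisible(x)
}
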