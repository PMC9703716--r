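# Binary undirected graph measures on 0/1 adjacency matrices. Triangle
# counting is done with adjacency-matrix algebra (fast inside permutation
# loops); shortest-path based measures, modularity optimisation, and
# degree-preserving rewiring delegate to igraph.

as_graph <- function(A) {
  igraph::graph_from_adjacency_matrix(A != 0, mode = "undirected",
                                      diag = FALSE)
}

check_adjacency <- function(A) {
  A <- as.matrix(A) != 0
  if (nrow(A) != ncol(A) || !isTRUE(all(A == t(A)))) {
    abort("Adjacency must be a symmetric square matrix.")
  }
  diag(A) <- FALSE
  storage.mode(A) <- "double"
  A
}

#' Nodal degree
#'
#' @param A 0/1 adjacency matrix.
#' @return Integer vector of edge counts per node.
#' @export
nodal_degree <- function(A) {
  A <- check_adjacency(A)
  rowSums(A)
}

#' Nodal clustering coefficient
#'
#' `c_i = 2 * triangles_i / (k_i (k_i - 1))`, the fraction of realised edges
#' among each node's neighbours; 0 for nodes of degree < 2.
#'
#' @param A 0/1 adjacency matrix.
#' @return Numeric vector in `[0, 1]`.
#' @export
nodal_clustering <- function(A) {
  A <- check_adjacency(A)
  k <- rowSums(A)
  tri2 <- diag(A %*% A %*% A)  # = 2 * triangles per node
  c_i <- ifelse(k < 2, 0, tri2 / (k * (k - 1)))
  unname(c_i)
}

#' Mean clustering coefficient
#'
#' Unweighted mean of [nodal_clustering()] over all nodes.
#'
#' @param A 0/1 adjacency matrix.
#' @return Scalar in `[0, 1]`.
#' @export
mean_clustering <- function(A) mean(nodal_clustering(A))

graph_distances <- function(A) {
  igraph::distances(as_graph(A))
}

#' Characteristic path length
#'
#' Mean shortest-path length over all unordered node pairs. On a
#' disconnected graph the mean is taken over reachable pairs only, with a
#' prominent warning.
#'
#' @param A 0/1 adjacency matrix.
#' @return Scalar >= 1 on nontrivial connected graphs.
#' @export
characteristic_path_length <- function(A) {
  D <- graph_distances(check_adjacency(A))
  d <- D[upper.tri(D)]
  if (any(is.infinite(d))) {
    warn("Graph is disconnected: characteristic path length computed over reachable pairs only.")
    d <- d[is.finite(d)]
  }
  mean(d)
}

#' Global efficiency
#'
#' Mean over node pairs of the inverse shortest-path length, with
#' unreachable pairs contributing 0 (the inverse harmonic mean of
#' distances).
#'
#' @param A 0/1 adjacency matrix.
#' @return Scalar in `[0, 1]`.
#' @export
global_efficiency <- function(A) {
  A <- check_adjacency(A)
  if (nrow(A) < 2) return(0)
  D <- graph_distances(A)
  inv <- 1 / D[upper.tri(D)]
  mean(ifelse(is.finite(inv), inv, 0))
}

#' Nodal local efficiency
#'
#' The global efficiency of the subgraph induced by each node's neighbours
#' (0 for degree < 2).
#'
#' @param A 0/1 adjacency matrix.
#' @return Numeric vector in `[0, 1]`.
#' @export
local_efficiency <- function(A) {
  A <- check_adjacency(A)
  vapply(seq_len(nrow(A)), function(i) {
    nb <- which(A[i, ] != 0)
    if (length(nb) < 2) return(0)
    global_efficiency(A[nb, nb, drop = FALSE])
  }, 0)
}

#' Transitivity (global clustering)
#'
#' `3 * triangles / connected triples`; 0 by convention on graphs without
#' connected triples.
#'
#' @param A 0/1 adjacency matrix.
#' @return Scalar in `[0, 1]`.
#' @export
graph_transitivity <- function(A) {
  A <- check_adjacency(A)
  k <- rowSums(A)
  triples2 <- sum(k * (k - 1))       # 2 * connected triples
  if (triples2 == 0) return(0)
  tri6 <- sum(diag(A %*% A %*% A))   # 6 * triangles
  tri6 / triples2
}

#' Normalized betweenness centrality
#'
#' Shortest-path betweenness with even splitting across equal-length paths,
#' normalized by `(n-1)(n-2)/2` so values lie in `[0, 1]`.
#'
#' @param A 0/1 adjacency matrix.
#' @return Numeric vector per node.
#' @export
nodal_betweenness <- function(A) {
  A <- check_adjacency(A)
  n <- nrow(A)
  b <- igraph::betweenness(as_graph(A), directed = FALSE, normalized = FALSE)
  if (n > 2) b <- b / ((n - 1) * (n - 2) / 2)
  unname(b)
}

#' Modularity of the best partition found
#'
#' Newman modularity `Q` of the best partition over `n_restarts` seeded runs
#' of multilevel (Louvain) optimisation; single-threaded and reproducible
#' for a given seed.
#'
#' @param A 0/1 adjacency matrix with at least one edge.
#' @param n_restarts Number of optimisation restarts (default 10).
#' @param seed Integer seed (default 1).
#' @return List with `Q` and integer `membership`.
#' @export
graph_modularity <- function(A, n_restarts = 10, seed = 1L) {
  A <- check_adjacency(A)
  g <- as_graph(A)
  if (igraph::ecount(g) == 0) abort("Modularity is undefined on an edgeless graph.")
  best <- NULL
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    cl <- igraph::cluster_louvain(g)
    q <- igraph::modularity(cl)
    if (is.null(best) || q > best$Q) {
      best <- list(Q = q, membership = as.integer(igraph::membership(cl)))
    }
  }
  best
}

#' Degree-preserving rewired null graphs
#'
#' Edge-swap (Maslov-Sneppen) randomization: each null attempts
#' `10 * |edges|` swaps, preserving the exact degree sequence. Seeded and
#' reproducible. Graphs without two independent edges cannot be rewired;
#' the inputs are returned unchanged with a warning.
#'
#' @param A 0/1 adjacency matrix.
#' @param n_nulls Number of null graphs (default 20).
#' @param seed Integer seed (default 1).
#' @return List of adjacency matrices.
#' @export
rewired_nulls <- function(A, n_nulls = 20, seed = 1L) {
  A <- check_adjacency(A)
  g <- as_graph(A)
  m <- igraph::ecount(g)
  if (m < 2) {
    warn("Graph admits no degree-preserving swap: nulls equal the input.")
    return(rep(list(A), n_nulls))
  }
  set.seed(seed)
  lapply(seq_len(n_nulls), function(b) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * m))
    as.matrix(igraph::as_adjacency_matrix(gr, sparse = FALSE))
  })
}

#' Small-world normalization
#'
#' `gamma = Cp / mean(Cp_null)`, `lambda = Lp / mean(Lp_null)`, and the
#' small-world index `sigma = gamma / lambda` against degree-preserving
#' rewired nulls; `sigma > 1` indicates small-world organisation.
#'
#' @param A 0/1 adjacency matrix (connected).
#' @param n_nulls Number of rewired nulls (default 20).
#' @param seed Integer seed (default 1).
#' @return One-row tibble: `Cp`, `Lp`, `Cp_null`, `Lp_null`, `gamma`,
#'   `lambda`, `sigma`, `small_world` (`sigma > 1`).
#' @export
small_world <- function(A, n_nulls = 20, seed = 1L) {
  A <- check_adjacency(A)
  cp <- mean_clustering(A)
  lp <- characteristic_path_length(A)
  nulls <- rewired_nulls(A, n_nulls, seed)
  cp_null <- mean(vapply(nulls, mean_clustering, 0))
  lp_null <- mean(vapply(nulls, function(x)
    suppressWarnings(characteristic_path_length(x)), 0))
  if (cp_null == 0) {
    warn("Mean null clustering is 0: gamma undefined.")
    gamma <- NA_real_
  } else {
    gamma <- cp / cp_null
  }
  lambda <- lp / lp_null
  sigma <- gamma / lambda
  tibble::tibble(Cp = cp, Lp = lp, Cp_null = cp_null, Lp_null = lp_null,
                 gamma = gamma, lambda = lambda, sigma = sigma,
                 small_world = !is.na(sigma) & sigma > 1)
}

# internal: fast evaluation of a set of global metrics on one adjacency
global_metric_values <- function(A, metrics) {
  vapply(metrics, function(m) {
    switch(m,
      clustering = mean_clustering(A),
      path_length = suppressWarnings(characteristic_path_length(A)),
      global_efficiency = global_efficiency(A),
      transitivity = graph_transitivity(A),
      modularity = graph_modularity(A)$Q,
      abort(sprintf("Unknown global metric '%s'.", m))
    )
  }, 0)
}

# internal: node-by-metric matrix of nodal metrics
nodal_metric_values <- function(A, metrics) {
  vapply(metrics, function(m) {
    switch(m,
      degree = as.numeric(nodal_degree(A)),
      betweenness = nodal_betweenness(A),
      clustering = nodal_clustering(A),
      local_efficiency = local_efficiency(A),
      abort(sprintf("Unknown nodal metric '%s'.", m))
    )
  }, numeric(nrow(A)))
}

#' Global metric curves of built networks
#'
#' Evaluates the requested global measures for every group at every grid
#' density, optionally adding the rewired-null normalized measures
#' (`gamma`, `lambda`, `sigma`) when `n_nulls > 0`.
#'
#' @param networks An `scn_networks` object from [build_networks()].
#' @param metrics Global metrics: any of `"clustering"`, `"path_length"`,
#'   `"global_efficiency"`, `"transitivity"`, `"modularity"`.
#' @param n_nulls Rewired nulls per (group, density) for normalized
#'   measures; 0 (default) skips them.
#' @param seed Master seed for the null streams.
#' @return Long tibble: `group`, `density`, `metric`, `value`.
#' @export
global_metric_curves <- function(networks,
                                 metrics = c("clustering", "path_length",
                                             "global_efficiency",
                                             "transitivity", "modularity"),
                                 n_nulls = 0, seed = 1L) {
  purrr::imap_dfr(networks$networks, function(nw, g) {
    purrr::map_dfr(seq_along(nw$densities), function(t) {
      A <- nw$adjacency[[t]]
      vals <- global_metric_values(A, metrics)
      out <- tibble::tibble(group = g, density = nw$densities[t],
                            metric = metrics, value = unname(vals))
      if (n_nulls > 0) {
        sw <- small_world(A, n_nulls = n_nulls,
                          seed = seed + 7919L * match(g, names(networks$networks)) + t)
        out <- dplyr::bind_rows(out, tibble::tibble(
          group = g, density = nw$densities[t],
          metric = c("gamma", "lambda", "sigma"),
          value = c(sw$gamma, sw$lambda, sw$sigma)
        ))
      }
      out
    })
  })
}

#' Nodal metric curves of built networks
#'
#' @param networks An `scn_networks` object.
#' @param metrics Nodal metrics: any of `"degree"`, `"betweenness"`,
#'   `"clustering"`, `"local_efficiency"`.
#' @return Long tibble: `group`, `density`, `metric`, `region`, `value`.
#' @export
nodal_metric_curves <- function(networks,
                                metrics = c("degree", "betweenness",
                                            "clustering",
                                            "local_efficiency")) {
  regions <- networks$atlas$region
  purrr::imap_dfr(networks$networks, function(nw, g) {
    purrr::map_dfr(seq_along(nw$densities), function(t) {
      vals <- nodal_metric_values(nw$adjacency[[t]], metrics)
      tibble::tibble(group = g, density = nw$densities[t],
                     metric = rep(metrics, each = length(regions)),
                     region = rep(regions, length(metrics)),
                     value = as.vector(vals))
    })
  })
}
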