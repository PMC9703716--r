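# Independent brute-force oracles for graph measures, kept deliberately
# naive: Floyd-Warshall distances, neighbour-pair enumeration for
# clustering, triple enumeration for transitivity, and shortest-path
# counting via adjacency-matrix walk counts for betweenness. None of these
# share code with the package implementation.

oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A != 0] <- 1
  diag(D) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

oracle_path_length <- function(A) {
  D <- oracle_distances(A)
  d <- D[upper.tri(D)]
  mean(d[is.finite(d)])
}

oracle_global_efficiency <- function(A) {
  D <- oracle_distances(A)
  inv <- 1 / D[upper.tri(D)]
  mean(ifelse(is.finite(inv), inv, 0))
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  sapply(seq_len(n), function(i) {
    nb <- which(A[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (u in seq_len(k - 1)) for (v in (u + 1):k) {
      links <- links + (A[nb[u], nb[v]] != 0)
    }
    links / choose(k, 2)
  })
}

oracle_transitivity <- function(A) {
  n <- nrow(A)
  triangles <- 0
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      triangles <- triangles + (A[i, j] & A[j, k] & A[i, k])
    }
  }
  triples <- sum(choose(rowSums(A != 0), 2))
  if (triples == 0) 0 else 3 * triangles / triples
}

# shortest-path counts sigma(s, t) = number of walks of minimal length,
# obtained from powers of the adjacency matrix; paths through v counted by
# the combinatorial identity sigma(s,v) * sigma(v,t) when distances add up
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  finite <- D[is.finite(D)]
  maxd <- max(finite)
  P <- vector("list", max(maxd, 1))
  Ak <- diag(n)
  for (d in seq_len(max(maxd, 1))) {
    Ak <- Ak %*% A
    P[[d]] <- Ak
  }
  nsp <- function(i, j) if (i == j) 1 else P[[D[i, j]]][i, j]
  b <- numeric(n)
  if (n >= 3) {
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      if (!is.finite(D[s, t])) next
      tot <- nsp(s, t)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
              D[s, v] + D[v, t] == D[s, t]) {
          b[v] <- b[v] + nsp(s, v) * nsp(v, t) / tot
        }
      }
    }
    b <- b / ((n - 1) * (n - 2) / 2)
  }
  b
}

# graph constructors -------------------------------------------------------

complete_graph <- function(n) {
  A <- matrix(1, n, n); diag(A) <- 0; A
}

path_graph <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  A
}

star_graph <- function(n) {
  A <- matrix(0, n, n)
  A[1, 2:n] <- A[2:n, 1] <- 1
  A
}

ring_graph <- function(n) {
  A <- path_graph(n)
  A[1, n] <- A[n, 1] <- 1
  A
}

random_connected_graph <- function(n, p) {
  repeat {
    A <- matrix(0, n, n)
    up <- which(upper.tri(A))
    A[up[runif(length(up)) < p]] <- 1
    A <- A + t(A)
    if (sum(A) >= 2 && all(is.finite(oracle_distances(A)))) return(A)
  }
}

# step-up Benjamini-Hochberg, written out directly
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  below <- which(p[o] <= alpha * seq_len(m) / m)
  rej <- logical(m)
  if (length(below)) rej[o[seq_len(max(below))]] <- TRUE
  rej
}

rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  }
  agree / choose(n, 2)
}
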