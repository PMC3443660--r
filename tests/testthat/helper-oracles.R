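# Independent brute-force oracles for the graph measures, built on matrix
# powers of the adjacency matrix rather than any graph library:
# the number of length-L walks from i to j is (A^L)[i, j]; the shortest-path
# distance is the smallest L with a positive entry, and the walk count at
# that L equals the geodesic count (shortest walks cannot revisit a node).

oracle_paths <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  diag(D) <- 0
  diag(sigma) <- 1
  P <- diag(n)
  if (n > 1) {
    for (L in seq_len(n - 1)) {
      P <- P %*% adj
      new <- which(P > 0 & is.infinite(D))
      D[new] <- L
      sigma[new] <- P[new]
    }
  }
  diag(D) <- 0
  diag(sigma) <- 1
  list(dist = D, sigma = sigma)
}

# Betweenness: sum over ordered pairs (s, t), s != v != t, of the fraction
# of s->t geodesics passing through v; unreachable pairs contribute 0.
# v lies on an s->t geodesic iff d(s,v) + d(v,t) = d(s,t), in which case it
# carries sigma(s,v) * sigma(v,t) of the sigma(s,t) geodesics.
oracle_betweenness <- function(adj) {
  o <- oracle_paths(adj)
  n <- nrow(adj)
  D <- o$dist
  S <- o$sigma
  bw <- numeric(n)
  for (v in seq_len(n)) {
    on_geodesic <- is.finite(D) & (outer(D[, v], D[v, ], "+") == D)
    on_geodesic[v, ] <- FALSE
    on_geodesic[, v] <- FALSE
    diag(on_geodesic) <- FALSE
    contrib <- outer(S[, v], S[v, ]) / S
    bw[v] <- sum(contrib[on_geodesic])
  }
  bw
}

oracle_reach <- function(adj, mode = c("in", "out")) {
  mode <- match.arg(mode)
  D <- oracle_paths(adj)$dist
  diag(D) <- -Inf
  D[is.infinite(D) & D > 0] <- -Inf
  val <- if (mode == "in") apply(D, 2, max) else apply(D, 1, max)
  val[!is.finite(val)] <- 0
  val
}

# Build a pathway_graph (single-gene nodes) from a 0/1 adjacency matrix.
adj_to_pathway <- function(adj, id = "adj", directed = TRUE) {
  n <- nrow(adj)
  nodes <- sprintf("v%02d", seq_len(n))
  idx <- which(adj > 0, arr.ind = TRUE)
  idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
  pathway_graph(
    id, nodes = nodes,
    edges = if (nrow(idx)) cbind(nodes[idx[, 1]], nodes[idx[, 2]]) else NULL,
    members = stats::setNames(as.list(sprintf("g%02d", seq_len(n))), nodes),
    directed = directed
  )
}

# All labelled digraphs on n nodes (no self-loops), as adjacency matrices.
all_digraphs <- function(n) {
  off <- which(row(diag(n)) != col(diag(n)))
  lapply(seq_len(2^length(off)) - 1L, function(mask) {
    adj <- matrix(0, n, n)
    bits <- as.integer(intToBits(mask))[seq_along(off)]
    adj[off] <- bits
    adj
  })
}

random_adj <- function(n, p) {
  adj <- matrix(as.numeric(stats::runif(n * n) < p), n, n)
  diag(adj) <- 0
  adj
}

reverse_adj <- function(adj) t(adj)

# Random multi-gene toy pathway: some complexes share genes, some nodes
# carry no genes at all.
random_multigene_pathway <- function(id = "rand", n_nodes = 8, n_genes = 10,
                                     p_edge = 0.25) {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  genes <- sprintf("G%02d", seq_len(n_genes))
  members <- lapply(seq_len(n_nodes), function(i) {
    k <- sample(0:3, 1)
    if (k == 0) character(0) else sample(genes, k)
  })
  names(members) <- nodes
  adj <- random_adj(n_nodes, p_edge)
  idx <- which(adj > 0, arr.ind = TRUE)
  pathway_graph(
    id, nodes = nodes,
    edges = if (nrow(idx)) cbind(nodes[idx[, 1]], nodes[idx[, 2]]) else NULL,
    members = members
  )
}
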