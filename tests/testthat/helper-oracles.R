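# Independent oracles used across the suite. These deliberately avoid the
# package's packed-word code path: set operations work on integer index
# sets, popcounts on rawToBits().

random_binary <- function(K, N, p = 0.3) {
  matrix(rbinom(K * N, 1L, p), K, N,
         dimnames = list(sprintf("f%d", seq_len(K)),
                         sprintf("s%d", seq_len(N))))
}

# |set_i OP set_j| computed on index sets
oracle_pair_count <- function(X, i, j, op) {
  a <- which(X[, i] == 1L)
  b <- which(X[, j] == 1L)
  switch(op,
         and = length(intersect(a, b)),
         xor = length(union(a, b)) - length(intersect(a, b)),
         or = length(union(a, b)))
}

oracle_compare <- function(Q, L, op) {
  out <- matrix(0L, ncol(Q), ncol(L))
  for (i in seq_len(ncol(Q))) for (j in seq_len(ncol(L)))
    out[i, j] <- oracle_pair_count(cbind(Q[, i], L[, j]), 1, 2, op)
  out
}

# bit-level popcount oracle on raw bytes
oracle_popcount <- function(words) sum(as.integer(rawToBits(words)))

# exact hypergeometric upper-tail by combinatorial sum (log scale for safety)
oracle_hyper_tail <- function(overlap, n_sig, n_set, U) {
  m <- seq(overlap, min(n_sig, n_set))
  if (length(m) == 0 || overlap <= 0) return(1)
  sum(exp(lchoose(n_sig, m) + lchoose(U - n_sig, n_set - m) - lchoose(U, n_set)))
}

# brute-force common-neighbor counts from an edge tibble
oracle_common_neighbors <- function(edges, cut) {
  nodes <- sort(unique(c(edges$node_i, edges$node_j)))
  nb <- lapply(nodes, function(v) {
    kept <- edges[edges$weight >= cut, ]
    sort(unique(c(kept$node_j[kept$node_i == v], kept$node_i[kept$node_j == v])))
  })
  names(nb) <- nodes
  out <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_along(nodes)) for (j in seq_along(nodes))
    if (i < j) out[i, j] <- length(intersect(nb[[i]], nb[[j]]))
  out
}

build_graph_from_edges <- function(edges) bitsig:::new_sig_edges(edges)

expect_counts_equal <- function(res, expected) {
  expect_equal(unname(res$counts), unname(expected), ignore_attr = TRUE)
}
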