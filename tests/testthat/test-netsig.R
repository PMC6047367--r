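make_self_result <- function(X, op = "and") sig_compare_self(pack_signatures(X), op)

test_that("merging up and down shared counts is cellwise addition", {
  set.seed(51)
  U <- random_binary(60, 8)
  D <- random_binary(60, 8)
  colnames(D) <- colnames(U)
  up <- make_self_result(U)
  down <- make_self_result(D)
  merged <- merge_up_down(up, down)
  expect_equal(merged$counts, up$counts + down$counts)
  # commutes
  expect_equal(merge_up_down(down, up)$counts, merged$counts)
  # zeros + zeros
  z <- make_self_result(matrix(0L, 10, 3))
  expect_true(all(merge_up_down(z, z)$counts == 0L))
  # contract violations
  expect_error(merge_up_down(up, make_self_result(random_binary(60, 5))),
               "identical ids")
  expect_error(merge_up_down(up, make_self_result(D, "xor")), "AND")
})

test_that("top-k graph selection matches a full sort with deterministic ties", {
  set.seed(52)
  X <- random_binary(80, 20, p = 0.5)
  merged <- make_self_result(X)
  g15 <- build_graph(merged, top_k = 15)
  # full-sort oracle with (weight desc, node_i asc, node_j asc) tie-break
  pairs <- tidy(merged)
  ord <- order(-pairs$count, pairs$query_id, pairs$library_id)
  expected <- pairs[ord, ][1:15, ]
  expect_equal(g15$node_i, expected$query_id)
  expect_equal(g15$node_j, expected$library_id)
  expect_equal(g15$weight, expected$count)

  # k = 1 gives the single heaviest pair; huge k gives all nonzero pairs
  g1 <- build_graph(merged, top_k = 1)
  expect_equal(g1$weight, max(pairs$count))
  gall <- build_graph(merged, top_k = 1e6)
  expect_equal(nrow(gall), sum(pairs$count > 0))

  # top_k output is a subset of thresholding at the k-th weight
  gthr <- build_graph(merged, threshold = min(g15$weight))
  expect_true(all(paste(g15$node_i, g15$node_j) %in%
                    paste(gthr$node_i, gthr$node_j)))

  expect_error(build_graph(merged, top_k = 0), "positive")
  expect_error(build_graph(merged, threshold = -1), "non-negative")
  expect_error(build_graph(merged), "exactly one")
  expect_error(build_graph(sig_compare(pack_signatures(X), pack_signatures(X))),
               "self-comparison")
})

test_that("sub-network extraction is the one-hop closure of the seeds", {
  edges <- tibble::tibble(
    node_i = c("a", "a", "b", "c", "d"),
    node_j = c("b", "c", "c", "d", "e"),
    weight = c(5, 4, 3, 2, 1))
  graph <- build_graph_from_edges(edges)

  # star: seeding the center keeps everything
  star <- build_graph_from_edges(tibble::tibble(
    node_i = "hub", node_j = paste0("leaf", 1:5), weight = 1:5))
  expect_equal(nrow(subnetwork(star, "hub")), 5)

  # seeding every node returns the original graph
  expect_equal(nrow(subnetwork(graph, c("a", "b", "c", "d", "e"))), 5)

  # brute-force one-hop oracle on random graphs
  set.seed(53)
  for (rep in 1:5) {
    nodes <- sprintf("n%02d", 1:15)
    e <- t(combn(nodes, 2))
    keep <- runif(nrow(e)) < 0.25
    g <- build_graph_from_edges(tibble::tibble(
      node_i = e[keep, 1], node_j = e[keep, 2],
      weight = sample(1:50, sum(keep), replace = TRUE)))
    seeds <- sample(unique(c(g$node_i, g$node_j)), 2)
    got <- subnetwork(g, seeds)
    adj <- unique(c(seeds,
                    g$node_j[g$node_i %in% seeds],
                    g$node_i[g$node_j %in% seeds]))
    want <- g[g$node_i %in% adj & g$node_j %in% adj, ]
    expect_setequal(paste(got$node_i, got$node_j), paste(want$node_i, want$node_j))
  }

  expect_error(subnetwork(graph, "zz"), "no seed present.*zz")
  expect_error(subnetwork(graph, character(0)), "nonempty")
})

test_that("common-neighbor similarity equals brute-force enumeration", {
  # triangle: each pair shares exactly the third vertex
  tri <- build_graph_from_edges(tibble::tibble(
    node_i = c("a", "a", "b"), node_j = c("b", "c", "c"), weight = 30))
  cn <- second_order_similarity(tri, edge_cut = 20)$counts
  expect_true(all(cn[upper.tri(cn)] == 1L))

  # star: leaves share the center, center-leaf pairs share nothing
  star <- build_graph_from_edges(tibble::tibble(
    node_i = "hub", node_j = paste0("leaf", 1:4), weight = 25))
  cn <- second_order_similarity(star, edge_cut = 20)$counts
  leaves <- paste0("leaf", 1:4)
  expect_true(all(cn[leaves, leaves][upper.tri(diag(4))] == 1L))
  expect_true(all(cn["hub", leaves] == 0L | cn[leaves, "hub"] == 0L))

  # random graphs against the neighbor-set oracle
  set.seed(54)
  for (rep in 1:5) {
    nodes <- sprintf("n%02d", 1:30)
    e <- t(combn(nodes, 2))
    keep <- runif(nrow(e)) < 0.15
    g <- build_graph_from_edges(tibble::tibble(
      node_i = e[keep, 1], node_j = e[keep, 2],
      weight = sample(1:40, sum(keep), replace = TRUE)))
    got <- second_order_similarity(g, edge_cut = 15)$counts
    want <- oracle_common_neighbors(g, cut = 15)
    expect_equal(got[rownames(want), colnames(want)], want)
  }

  # depends only on the binarized adjacency, not the surviving weights
  g <- build_graph_from_edges(tibble::tibble(
    node_i = c("a", "b", "c"), node_j = c("b", "c", "d"), weight = c(21, 35, 90)))
  rescaled <- g
  rescaled$weight <- rescaled$weight * 10
  expect_equal(second_order_similarity(g, 20)$counts,
               second_order_similarity(rescaled, 20)$counts)

  expect_error(second_order_similarity(g, 1000), "no edges survive")
})

test_that("overlap enrichment equals the exact hypergeometric tail", {
  # zero overlap has probability one of being matched or beaten
  expect_equal(overlap_enrichment(c("a", "b"), c("c", "d"), 10)$p_value, 1)
  # degenerate: both sets are the whole universe
  u <- sprintf("g%d", 1:20)
  expect_equal(overlap_enrichment(u, u, 20)$p_value, 1)

  # |sig|=10, |set|=15, U=100 with a forced overlap of 5
  sig <- sprintf("g%d", 1:10)
  set_ <- c(sprintf("g%d", 1:5), sprintf("h%d", 1:10))
  res <- overlap_enrichment(sig, set_, 100)
  expect_equal(res$overlap, 5L)
  expect_equal(res$p_value, oracle_hyper_tail(5, 10, 15, 100), tolerance = 1e-12)

  # 50 random configurations, absolute agreement to 1e-12
  set.seed(55)
  for (rep in 1:50) {
    U <- sample(20:200, 1)
    uni <- sprintf("x%03d", seq_len(U))
    a <- sample(uni, sample(1:15, 1))
    b <- sample(uni, sample(1:15, 1))
    res <- overlap_enrichment(a, b, U)
    want <- oracle_hyper_tail(res$overlap, length(a), length(b), U)
    expect_equal(res$p_value, want, tolerance = 1e-12)
  }

  expect_error(overlap_enrichment(sprintf("g%d", 1:30), "g1", 20), "below the union")
})

test_that("planted signature clusters are recovered by the top-k graph", {
  sim <- synth_lincs(seed = 56)
  merged <- merge_up_down(sig_compare_self(sim$up, "and"),
                          sig_compare_self(sim$down, "and"))
  truth <- sim$truth[!is.na(sim$truth$cluster), ]
  # one edge per within-cluster pair
  graph <- build_graph(merged, top_k = sum(choose(table(truth$cluster), 2)))
  comp <- igraph::components(as_igraph(graph))$membership
  scored <- truth[truth$signature_id %in% names(comp), ]
  expect_gte(rand_index(comp[scored$signature_id], scored$cluster), 0.95)
})
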