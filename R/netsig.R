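#' Merge up- and down-regulated shared counts
#'
#' Adds the AND pair counts of the up-signature comparison and the
#' down-signature comparison cellwise, giving the total number of
#' concordantly shared regulated features per pair of experiments. This
#' merged count is the edge weight used by [build_graph()].
#'
#' @param up,down `sig_result` objects from operator `"and"` with identical
#'   ids, shapes and self-ness.
#' @return A `sig_result` of the summed counts.
#' @export
merge_up_down <- function(up, down) {
  stopifnot(inherits(up, "sig_result"), inherits(down, "sig_result"))
  if (up$operator != "and" || down$operator != "and")
    abort("merge expects AND (shared-count) results.")
  if (!identical(dimnames(up$counts), dimnames(down$counts)) ||
      !identical(up$self, down$self))
    abort("up and down results must have identical ids, shapes and self-ness.")
  new_sig_result(up$counts + down$counts, "and", max(up$K, down$K), up$self)
}

#' Build a similarity graph from a self-comparison
#'
#' Turns a merged self-comparison into a weighted undirected edge table.
#' `threshold` keeps every pair with weight at or above the cut; `top_k`
#' keeps the k heaviest nonzero pairs, with deterministic tie-breaking by
#' (weight descending, first id ascending, second id ascending).
#'
#' @param merged A self `sig_result` (e.g. from [merge_up_down()]).
#' @param threshold,top_k Exactly one of the two selection modes.
#' @param node_sizes Optional named vector of per-node signature sizes,
#'   attached as a node attribute.
#' @return A `sig_edges` tibble: `node_i`, `node_j`, `weight`, each
#'   unordered pair at most once.
#' @export
build_graph <- function(merged, threshold = NULL, top_k = NULL,
                        node_sizes = NULL) {
  stopifnot(inherits(merged, "sig_result"))
  if (!merged$self) abort("graph construction needs a self-comparison result.")
  if (is.null(threshold) == is.null(top_k))
    abort("give exactly one of `threshold` or `top_k`.")
  pairs <- tidy(merged)
  names(pairs) <- c("node_i", "node_j", "weight")
  if (!is.null(threshold)) {
    if (threshold < 0) abort("`threshold` must be non-negative.")
    edges <- dplyr::filter(pairs, .data$weight >= threshold)
    edges <- dplyr::arrange(edges, dplyr::desc(.data$weight),
                            .data$node_i, .data$node_j)
  } else {
    if (top_k <= 0) abort("`top_k` must be positive.")
    edges <- dplyr::filter(pairs, .data$weight > 0)
    edges <- dplyr::arrange(edges, dplyr::desc(.data$weight),
                            .data$node_i, .data$node_j)
    edges <- head(edges, top_k)
  }
  new_sig_edges(edges, node_sizes)
}

new_sig_edges <- function(edges, node_sizes = NULL) {
  edges <- as_tibble(edges)
  attr(edges, "node_sizes") <- node_sizes
  class(edges) <- unique(c("sig_edges", class(edges)))
  edges
}

edge_nodes <- function(graph) sort(unique(c(graph$node_i, graph$node_j)))

#' One-hop sub-network around seed nodes
#'
#' Restricts a graph to the one-hop neighborhood closure of a seed set:
#' nodes that are seeds or adjacent to a seed, and every edge joining two
#' such nodes. Optionally keeps only the `top_edges` heaviest edges of the
#' restriction (same ordering as [build_graph()]).
#'
#' @param graph A `sig_edges` table.
#' @param seeds Nonempty character vector of node ids.
#' @param top_edges Optional edge cap.
#' @return A `sig_edges` tibble.
#' @export
subnetwork <- function(graph, seeds, top_edges = NULL) {
  if (length(seeds) == 0) abort("`seeds` must be nonempty.")
  nodes <- edge_nodes(graph)
  missing <- setdiff(seeds, nodes)
  if (length(missing) == length(seeds))
    abort(sprintf("no seed present in graph: %s", paste(missing, collapse = ", ")))
  seeds <- intersect(seeds, nodes)
  touched <- graph$node_i %in% seeds | graph$node_j %in% seeds
  closure <- union(seeds, c(graph$node_i[touched], graph$node_j[touched]))
  sub <- dplyr::filter(graph, .data$node_i %in% closure & .data$node_j %in% closure)
  sub <- dplyr::arrange(sub, dplyr::desc(.data$weight), .data$node_i, .data$node_j)
  if (!is.null(top_edges)) sub <- head(sub, top_edges)
  new_sig_edges(sub, attr(graph, "node_sizes"))
}

#' Common-neighbor similarity of graph nodes
#'
#' Second-order similarity: binarizes the graph's adjacency at
#' `weight >= edge_cut`, packs each node's neighbor vector as a signature,
#' and runs an AND self-comparison. Cell (i, j) then answers: how many
#' nodes are incident on both node i and node j? The result depends only
#' on which edges survive the cut, not on their weights.
#'
#' @param graph A `sig_edges` table.
#' @param edge_cut Minimum weight for an edge to count as present
#'   (default 20, a practical cut for shared-gene adjacency matrices).
#' @return A self `sig_result` of common-neighbor counts over the graph's
#'   nodes.
#' @export
second_order_similarity <- function(graph, edge_cut = 20) {
  if (edge_cut < 0) abort("`edge_cut` must be non-negative.")
  nodes <- edge_nodes(graph)
  kept <- dplyr::filter(graph, .data$weight >= edge_cut)
  if (nrow(kept) == 0) abort("no edges survive the cut; adjacency is empty.")
  n <- length(nodes)
  adj <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  adj[cbind(match(kept$node_i, nodes), match(kept$node_j, nodes))] <- 1L
  adj[cbind(match(kept$node_j, nodes), match(kept$node_i, nodes))] <- 1L
  sig_compare_self(pack_signatures(adj), "and")
}

#' Set-overlap enrichment p-value
#'
#' One-sided (greater) hypergeometric tail probability of observing at
#' least the actual overlap between a signature and a gene set drawn from a
#' universe of `universe_size` features — the set-overlap half of a
#' Fisher's exact test as used for gene-set enrichment. The overlap itself
#' is computed through the packed AND count.
#'
#' @param signature,gene_set Character vectors of feature ids.
#' @param universe_size Total number of features in the universe; must be
#'   at least the size of the union of the two sets.
#' @return A tibble with `overlap`, `signature_size`, `gene_set_size`,
#'   `universe_size` and `p_value`.
#' @export
overlap_enrichment <- function(signature, gene_set, universe_size) {
  signature <- unique(as.character(signature))
  gene_set <- unique(as.character(gene_set))
  u <- union(signature, gene_set)
  if (universe_size < length(u))
    abort(sprintf("universe_size (%d) below the union of the two sets (%d).",
                  universe_size, length(u)))
  if (length(u) == 0) {
    ov <- 0L
  } else {
    memb <- cbind(sig = as.integer(u %in% signature),
                  set = as.integer(u %in% gene_set))
    rownames(memb) <- u
    ov <- sig_compare_self(pack_signatures(memb), "and")$counts[1, 2]
  }
  p <- phyper(ov - 1, length(signature), universe_size - length(signature),
              length(gene_set), lower.tail = FALSE)
  tibble(overlap = as.integer(ov),
         signature_size = length(signature),
         gene_set_size = length(gene_set),
         universe_size = as.integer(universe_size),
         p_value = p)
}

#' @method glance sig_edges
#' @export
glance.sig_edges <- function(x, ...) {
  tibble(n_nodes = length(edge_nodes(x)), n_edges = nrow(x),
         min_weight = if (nrow(x)) min(x$weight) else NA_real_,
         max_weight = if (nrow(x)) max(x$weight) else NA_real_)
}

#' Convert an edge table to an igraph graph
#'
#' @param graph A `sig_edges` table.
#' @return An undirected weighted [igraph::graph] with any node sizes as a
#'   `size` vertex attribute.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "sig_edges"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = graph$node_i, to = graph$node_j, weight = graph$weight),
    directed = FALSE)
  sizes <- attr(graph, "node_sizes")
  if (!is.null(sizes)) {
    igraph::V(g)$size <- unname(sizes[igraph::V(g)$name])
  }
  g
}

#' @method autoplot sig_edges
#' @export
autoplot.sig_edges <- function(object, ...) {
  g <- as_igraph(object)
  set.seed(1L)  # layout only; numeric results never depend on this
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble(name = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
  seg <- tibble(
    x = nodes$x[match(object$node_i, nodes$name)],
    y = nodes$y[match(object$node_i, nodes$name)],
    xend = nodes$x[match(object$node_j, nodes$name)],
    yend = nodes$y[match(object$node_j, nodes$name)],
    weight = object$weight)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linewidth = .data$weight),
                          colour = "grey60", alpha = 0.7) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        colour = "steelblue", size = 2) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5)) +
    ggplot2::theme_void()
}
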