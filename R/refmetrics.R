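#' Full-precision reference metrics
#'
#' The exact similarity metrics that bit-count filtering stands in front of.
#' `cosine_similarity(a, b)` is `sum(a*b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))`;
#' `euclidean_distance(a, b)` is `sqrt(sum((a - b)^2))`. Accumulation is
#' sequential over features, so values are run-to-run reproducible.
#'
#' On 0/1 vectors these reduce to bit counts: cosine equals
#' `AND / sqrt(pop_a * pop_b)` and Euclidean distance equals `sqrt(XOR)`.
#'
#' @param a,b Numeric vectors of equal length.
#' @return A single numeric value; cosine in `[-1, 1]`, Euclidean `>= 0`.
#' @export
cosine_similarity <- function(a, b) {
  check_pair(a, b)
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) abort("cosine similarity undefined for a zero-norm vector.")
  sum(a * b) / (na * nb)
}

#' @rdname cosine_similarity
#' @export
euclidean_distance <- function(a, b) {
  check_pair(a, b)
  sqrt(sum((a - b)^2))
}

check_pair <- function(a, b) {
  if (length(a) != length(b))
    abort(sprintf("vector length mismatch: %d vs %d.", length(a), length(b)))
  invisible(NULL)
}

#' Filter-then-refine similarity search
#'
#' Uses cheap bit counts on binarized data to prune pairs before the exact
#' metric touches the full-precision values. Both dense matrices are
#' binarized into low/high signatures with the given cuts; for every
#' query-library pair the combined shared count (low-shared + high-shared,
#' under AND) is computed, and the reference metric is evaluated only for
#' pairs whose combined count reaches `min_shared`. Refined values are
#' identical to computing the metric directly on those pairs.
#'
#' @param query,library Continuous matrices (features x samples) over the
#'   same feature universe, as for [threshold_binarize()].
#' @param low_cut,high_cut Binarization cuts.
#' @param min_shared Minimum combined low+high shared count a pair needs to
#'   be refined. 0 disables the filter.
#' @param metric `"cosine"` or `"euclidean"`.
#' @return A `sig_refined` tibble: `query_id`, `library_id`, `shared_count`,
#'   `metric`, `value`, sorted by ids; carries `min_shared` as an attribute.
#' @export
filter_then_refine <- function(query, library, low_cut = -0.6, high_cut = 0.6,
                               min_shared = 20,
                               metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  query <- as_dense_matrix(query)
  library <- as_dense_matrix(library)
  if (!identical(rownames(query), rownames(library)))
    abort("query and library must share one feature universe (identical row ids).")
  if (min_shared > nrow(query))
    abort(sprintf("min_shared (%s) exceeds the signature length K = %d.",
                  format(min_shared), nrow(query)))
  qb <- threshold_binarize(query, low_cut, high_cut)
  lb <- threshold_binarize(library, low_cut, high_cut)
  shared <- sig_compare(qb$low, lb$low, "and")$counts +
    sig_compare(qb$high, lb$high, "and")$counts
  keep <- which(shared >= min_shared, arr.ind = TRUE)
  fn <- if (metric == "cosine") cosine_similarity else euclidean_distance
  vals <- vapply(seq_len(nrow(keep)), function(r) {
    fn(query[, keep[r, 1]], library[, keep[r, 2]])
  }, numeric(1))
  out <- tibble(query_id = colnames(query)[keep[, 1]],
                library_id = colnames(library)[keep[, 2]],
                shared_count = shared[keep],
                metric = rep(metric, nrow(keep)),
                value = vals) |>
    dplyr::arrange(.data$query_id, .data$library_id)
  attr(out, "min_shared") <- min_shared
  class(out) <- c("sig_refined", class(out))
  out
}

#' @method autoplot sig_refined
#' @export
autoplot.sig_refined <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$shared_count, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6, colour = "steelblue") +
    ggplot2::labs(x = "combined shared count (low + high)",
                  y = unique(object$metric)) +
    ggplot2::theme_minimal()
}
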