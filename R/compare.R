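#' Pairwise signature comparison
#'
#' Computes the full table of bitwise pair counts between two packed
#' signature matrices. For signatures (feature sets) `i` and `j`, the count
#' under `"and"` is the size of the set intersection, under `"xor"` the size
#' of the symmetric difference, and under `"or"` the size of the union. The
#' result is an `N`-query by `M`-library integer matrix of counts.
#'
#' @param query,library `sig_matrix` objects over the same feature universe
#'   (`K` must match).
#' @param operator One of `"and"`, `"xor"`, `"or"`.
#' @return A `sig_result`: integer count matrix with query ids as rownames
#'   and library ids as colnames, plus the operator and `K` used. Use
#'   [tidy()] to get one row per pair.
#' @seealso [sig_compare_self()] for all pairs within one matrix,
#'   [sig_compare_chunked()] for memory-bounded evaluation.
#' @examples
#' x <- pack_signatures(matrix(c(1, 1, 0, 0, 1, 1), nrow = 3))
#' sig_compare(x, x, "and")$counts
#' @export
sig_compare <- function(query, library, operator = c("and", "xor", "or")) {
  operator <- match_operator(operator)
  validate_sig_matrix(query)
  validate_sig_matrix(library)
  if (query$K != library$K)
    abort(sprintf("signature length mismatch: query K = %d, library K = %d.",
                  query$K, library$K))
  counts <- cpp_compare(query$words, query$N, library$words, library$N,
                        query$W, op_code(operator))
  dimnames(counts) <- list(query$signature_ids, library$signature_ids)
  new_sig_result(counts, operator, query$K, self = FALSE)
}

#' Self comparison of one signature matrix
#'
#' All-vs-all comparison of the columns of a single packed matrix. Each
#' unordered pair is computed once: the result is strictly upper triangular
#' with a zero diagonal, so cell `(i, j)` with `i < j` holds the pair count
#' and every cell with `i >= j` is zero.
#'
#' @inheritParams sig_compare
#' @param x A `sig_matrix` with at least two signatures.
#' @param memory_budget Optional byte budget; when the full `N x N` count
#'   matrix would exceed it, the computation runs blockwise (blocks
#'   straddling the diagonal zero their lower parts) and is cellwise
#'   identical to the in-memory result.
#' @return A `sig_result` with `self = TRUE`.
#' @export
sig_compare_self <- function(x, operator = c("and", "xor", "or"),
                             memory_budget = NULL) {
  operator <- match_operator(operator)
  validate_sig_matrix(x)
  if (x$N < 2L) abort("self-comparison needs at least two signatures.")
  if (is.null(memory_budget) ||
      as.numeric(x$N) * x$N * 4 <= memory_budget) {
    counts <- cpp_compare_self(x$words, x$N, x$W, op_code(operator))
  } else {
    plan <- plan_chunks(x$N, x$N, 4L, memory_budget)
    counts <- matrix(0L, x$N, x$N)
    for (b in seq_len(nrow(plan))) {
      ri <- plan$row_start[b]:plan$row_end[b]
      ci <- plan$col_start[b]:plan$col_end[b]
      blk <- cpp_compare(x[ri]$words, length(ri), x[ci]$words, length(ci),
                         x$W, op_code(operator))
      # keep only strictly-upper cells of the global matrix
      blk[outer(ri, ci, ">=")] <- 0L
      counts[ri, ci] <- blk
    }
  }
  dimnames(counts) <- list(x$signature_ids, x$signature_ids)
  new_sig_result(counts, operator, x$K, self = TRUE)
}

new_sig_result <- function(counts, operator, K, self) {
  structure(list(counts = counts, operator = operator, K = K, self = self),
            class = "sig_result")
}

match_operator <- function(operator) {
  match.arg(tolower(operator), c("and", "xor", "or"))
}

op_code <- function(operator) {
  c(and = 1L, xor = 2L, or = 3L)[[operator]]
}

#' Plan memory-bounded output chunks
#'
#' Tiles an `n_query x n_library` count matrix into rectangular blocks whose
#' individual byte size fits `memory_budget`. Rows are split first; only
#' when a single full-width row exceeds the budget are columns split too.
#' Every output cell belongs to exactly one block.
#'
#' @param n_query,n_library Output dimensions.
#' @param bytes_per_cell Bytes per count cell (counts are 32-bit, so 4).
#' @param memory_budget Maximum bytes a single block may occupy.
#' @return A tibble with columns `row_start`, `row_end`, `col_start`,
#'   `col_end` (1-based, inclusive) and `bytes`.
#' @export
plan_chunks <- function(n_query, n_library, bytes_per_cell = 4L,
                        memory_budget = 2^30) {
  if (n_query < 1 || n_library < 1 || bytes_per_cell < 1 || memory_budget < 1)
    abort("all chunk-plan arguments must be positive.")
  if (memory_budget < bytes_per_cell)
    abort(sprintf("memory budget (%s bytes) cannot hold a single %d-byte cell.",
                  format(memory_budget), bytes_per_cell))
  rows_per <- floor(memory_budget / (bytes_per_cell * as.numeric(n_library)))
  if (rows_per >= 1) {
    row_starts <- seq(1L, n_query, by = rows_per)
    blocks <- tibble(
      row_start = as.integer(row_starts),
      row_end = as.integer(pmin(row_starts + rows_per - 1, n_query)),
      col_start = 1L, col_end = as.integer(n_library))
  } else {
    cols_per <- floor(memory_budget / bytes_per_cell)
    col_starts <- seq(1L, n_library, by = cols_per)
    blocks <- tidyr::expand_grid(
      row_start = seq_len(n_query),
      col_start = as.integer(col_starts))
    blocks$row_end <- blocks$row_start
    blocks$col_end <- as.integer(pmin(blocks$col_start + cols_per - 1, n_library))
    blocks <- blocks[, c("row_start", "row_end", "col_start", "col_end")]
  }
  blocks$bytes <- (blocks$row_end - blocks$row_start + 1) *
    (blocks$col_end - blocks$col_start + 1) * as.numeric(bytes_per_cell)
  blocks
}

#' Chunked pairwise comparison
#'
#' Evaluates [sig_compare()] block by block following a chunk plan, calling
#' `sink(block, counts)` after each block. The concatenation of the emitted
#' blocks is cellwise identical to the unchunked comparison.
#'
#' @inheritParams sig_compare
#' @param plan A chunk plan from [plan_chunks()]; defaults to a plan for
#'   `memory_budget`.
#' @param memory_budget Byte budget used when `plan` is `NULL`.
#' @param sink Optional function of `(block, counts)` where `block` is the
#'   plan row (a one-row tibble) and `counts` the block's integer matrix;
#'   use [tsv_chunk_sink()] to stream blocks to disk. Errors raised by the
#'   sink are propagated with the failing block's coordinates.
#' @return The assembled full `sig_result`, invisibly when a sink is given.
#' @export
sig_compare_chunked <- function(query, library,
                                operator = c("and", "xor", "or"),
                                plan = NULL, memory_budget = 2^30,
                                sink = NULL) {
  operator <- match_operator(operator)
  validate_sig_matrix(query)
  validate_sig_matrix(library)
  if (query$K != library$K)
    abort(sprintf("signature length mismatch: query K = %d, library K = %d.",
                  query$K, library$K))
  if (is.null(plan)) plan <- plan_chunks(query$N, library$N, 4L, memory_budget)
  check_plan_tiles(plan, query$N, library$N)
  counts <- matrix(0L, query$N, library$N,
                   dimnames = list(query$signature_ids, library$signature_ids))
  for (b in seq_len(nrow(plan))) {
    ri <- plan$row_start[b]:plan$row_end[b]
    ci <- plan$col_start[b]:plan$col_end[b]
    blk <- cpp_compare(query[ri]$words, length(ri), library[ci]$words,
                       length(ci), query$W, op_code(operator))
    dimnames(blk) <- list(query$signature_ids[ri], library$signature_ids[ci])
    counts[ri, ci] <- blk
    if (!is.null(sink)) {
      tryCatch(sink(plan[b, ], blk), error = function(e) {
        abort(sprintf("sink failed on block rows %d-%d, cols %d-%d: %s",
                      plan$row_start[b], plan$row_end[b],
                      plan$col_start[b], plan$col_end[b],
                      conditionMessage(e)))
      })
    }
  }
  res <- new_sig_result(counts, operator, query$K, self = FALSE)
  if (is.null(sink)) res else invisible(res)
}

check_plan_tiles <- function(plan, n_query, n_library) {
  covered <- matrix(0L, n_query, n_library)
  for (b in seq_len(nrow(plan))) {
    covered[plan$row_start[b]:plan$row_end[b],
            plan$col_start[b]:plan$col_end[b]] <-
      covered[plan$row_start[b]:plan$row_end[b],
              plan$col_start[b]:plan$col_end[b]] + 1L
  }
  if (any(covered != 1L))
    abort("chunk plan does not tile the output exactly once.")
  invisible(plan)
}

#' Number of unordered pairs
#'
#' The number of distinct pairwise comparisons among `n` signatures,
#' `n * (n - 1) / 2`, in exact double arithmetic (exact for all `n` of
#' practical signature-library size).
#'
#' @param n Number of signatures (non-negative).
#' @examples
#' pair_count(1e6)      # ~0.5 trillion comparisons for a million signatures
#' pair_count(117373)   # ~6.89 billion
#' @export
pair_count <- function(n) {
  n <- as.numeric(n)
  if (any(n < 0)) abort("`n` must be non-negative.")
  n * (n - 1) / 2
}

#' @export
print.sig_result <- function(x, ...) {
  cat(sprintf("<sig_result> %d x %d %s counts (K = %d)%s\n",
              nrow(x$counts), ncol(x$counts), toupper(x$operator), x$K,
              if (x$self) ", self (strictly upper triangular)" else ""))
  invisible(x)
}

#' Tidy a comparison result
#'
#' One row per signature pair. For self-comparisons only the strictly upper
#' triangle (each unordered pair once) is returned.
#'
#' @param x A `sig_result`.
#' @param ... Unused.
#' @return A tibble with columns `query_id`, `library_id`, `count`.
#' @method tidy sig_result
#' @export
tidy.sig_result <- function(x, ...) {
  if (x$self) {
    idx <- which(upper.tri(x$counts), arr.ind = TRUE)
  } else {
    idx <- as.matrix(expand.grid(row = seq_len(nrow(x$counts)),
                                 col = seq_len(ncol(x$counts))))
  }
  tibble(query_id = rownames(x$counts)[idx[, 1]],
         library_id = colnames(x$counts)[idx[, 2]],
         count = x$counts[idx]) |>
    dplyr::arrange(.data$query_id, .data$library_id)
}

#' @rdname tidy.sig_result
#' @method glance sig_result
#' @export
glance.sig_result <- function(x, ...) {
  vals <- if (x$self) x$counts[upper.tri(x$counts)] else as.vector(x$counts)
  tibble(n_query = nrow(x$counts), n_library = ncol(x$counts),
         n_pairs = length(vals), K = x$K, operator = x$operator,
         self = x$self, max_count = max(vals), mean_count = mean(vals))
}

#' @rdname tidy.sig_result
#' @param object A `sig_result`.
#' @param bins Histogram bin count.
#' @method autoplot sig_result
#' @export
autoplot.sig_result <- function(object, bins = 30, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = sprintf("%s pair count", toupper(object$operator)),
                  y = "pairs") +
    ggplot2::theme_minimal()
}
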