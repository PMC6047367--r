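#' Threshold binarization of a continuous matrix
#'
#' Splits a continuous feature-by-sample matrix into a paired low/high
#' signature representation: the low bit of a cell is set iff its value is
#' strictly below `low_cut`, the high bit iff strictly above `high_cut`.
#' With the default cuts (-0.6, 0.6) the two matrices mark the extremes of
#' the value distribution, e.g. down- and up-regulated genes relative to a
#' reference. A value can never set both bits.
#'
#' @param x Continuous matrix (features in rows, samples in columns) or a
#'   data frame whose first column holds feature ids.
#' @param low_cut,high_cut Strict cutpoints; `low_cut < high_cut` required.
#' @param na_action `"zero"` leaves both bits unset for a missing value (a
#'   missing measurement is not part of either signature); `"error"`
#'   rejects non-finite input.
#' @return A list with `sig_matrix` components `low` and `high` sharing the
#'   input's feature and sample ids.
#' @examples
#' m <- matrix(c(-1, 0, 1, -0.6, 0.6, 2), nrow = 3)
#' b <- threshold_binarize(m)
#' signature_sizes(b$low); signature_sizes(b$high)
#' @export
threshold_binarize <- function(x, low_cut = -0.6, high_cut = 0.6,
                               na_action = c("zero", "error")) {
  na_action <- match.arg(na_action)
  x <- as_dense_matrix(x)
  if (!(low_cut < high_cut)) abort("`low_cut` must be strictly below `high_cut`.")
  bad <- !is.finite(x)
  if (any(bad) && na_action == "error")
    abort("non-finite values present and na_action = \"error\".")
  lo <- x < low_cut
  hi <- x > high_cut
  lo[bad] <- FALSE  # a missing measurement belongs to neither signature
  hi[bad] <- FALSE
  lo <- matrix(as.integer(lo), nrow(x), ncol(x), dimnames = dimnames(x))
  hi <- matrix(as.integer(hi), nrow(x), ncol(x), dimnames = dimnames(x))
  list(low = pack_signatures(lo), high = pack_signatures(hi))
}

as_dense_matrix <- function(x) {
  if (is.data.frame(x)) {
    first <- x[[1]]
    if (is.character(first) || is.factor(first)) {
      ids <- as.character(first)
      x <- as.matrix(x[, -1, drop = FALSE])
      rownames(x) <- ids
    } else {
      x <- as.matrix(x)
    }
  }
  if (!is.matrix(x) || !is.numeric(x)) abort("`x` must be a numeric matrix or data frame.")
  if (nrow(x) < 1L || ncol(x) < 1L) abort("empty matrix.")
  if (is.null(rownames(x))) rownames(x) <- sprintf("f%d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("s%d", seq_len(ncol(x)))
  x
}

#' Build paired signatures from per-sample up/down feature calls
#'
#' Converts per-sample lists of up- and down-called features (e.g.
#' differential-expression calls) into paired membership signature matrices
#' over a fixed feature universe: the bit for a feature is set exactly when
#' the feature is listed for that sample, in universe order.
#'
#' @param up_sets,down_sets Named lists (one element per sample) of feature
#'   id vectors; the two lists must have identical names in the same order
#'   and be pairwise disjoint within each sample.
#' @param universe Character vector of all feature ids, defining row order.
#' @return A list with `sig_matrix` components `down` and `up`.
#' @export
updown_signatures <- function(up_sets, down_sets, universe) {
  if (!identical(names(up_sets), names(down_sets)))
    abort("`up_sets` and `down_sets` must cover the same samples in the same order.")
  samples <- names(up_sets)
  if (is.null(samples)) samples <- sprintf("s%d", seq_along(up_sets))
  build <- function(sets) {
    cols <- vapply(sets, function(feats) {
      feats <- as.character(feats)
      missing <- setdiff(feats, universe)
      if (length(missing) > 0)
        abort(sprintf("feature(s) outside universe: %s",
                      paste(missing, collapse = ", ")))
      as.integer(universe %in% feats)
    }, integer(length(universe)))
    cols <- matrix(cols, nrow = length(universe),
                   dimnames = list(universe, samples))
    pack_signatures(cols)
  }
  for (s in seq_along(up_sets)) {
    both <- intersect(up_sets[[s]], down_sets[[s]])
    if (length(both) > 0)
      abort(sprintf("sample %s lists feature(s) as both up and down: %s",
                    samples[s], paste(both, collapse = ", ")))
  }
  list(down = build(down_sets), up = build(up_sets))
}
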