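#' Bit-packed binary signature matrices
#'
#' A `sig_matrix` stores an K-feature-by-N-signature 0/1 matrix column-wise
#' in 64-bit words (`W = ceiling(K/64)` words per signature), so that pairwise
#' set operations reduce to bitwise AND/XOR/OR plus a hardware population
#' count. Bit position within a word is the feature index modulo 64,
#' least-significant bit first; padding bits beyond position K are always
#' zero, which keeps AND/XOR/OR counts exact without masking.
#'
#' @param x For [pack_signatures()], a 0/1 matrix (features in rows,
#'   signatures in columns) or a data frame whose first column holds feature
#'   identifiers and whose remaining columns are 0/1 signature columns.
#' @param feature_ids,signature_ids Optional identifier vectors overriding
#'   the dimnames of `x`.
#'
#' @return [pack_signatures()] returns a `sig_matrix`; [unpack_signatures()]
#'   returns the integer 0/1 matrix it encodes, with feature ids as rownames
#'   and signature ids as colnames.
#'
#' @examples
#' m <- matrix(c(1, 0, 1, 0, 0, 1), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' sig <- pack_signatures(m)
#' signature_sizes(sig)
#' all(unpack_signatures(sig) == m)
#' @export
pack_signatures <- function(x, feature_ids = NULL, signature_ids = NULL) {
  if (is.data.frame(x)) {
    first <- x[[1]]
    if (is.character(first) || is.factor(first)) {
      if (is.null(feature_ids)) feature_ids <- as.character(first)
      x <- as.matrix(x[, -1, drop = FALSE])
    } else {
      x <- as.matrix(x)
    }
  }
  if (!is.matrix(x)) abort("`x` must be a matrix or data frame of 0/1 values.")
  if (nrow(x) < 1L || ncol(x) < 1L) abort("empty matrix: need K >= 1 and N >= 1.")
  storage.mode(x) <- "integer"
  if (is.null(feature_ids)) feature_ids <- rownames(x)
  if (is.null(feature_ids)) feature_ids <- sprintf("f%d", seq_len(nrow(x)))
  if (is.null(signature_ids)) signature_ids <- colnames(x)
  if (is.null(signature_ids)) signature_ids <- sprintf("s%d", seq_len(ncol(x)))
  if (length(feature_ids) != nrow(x) || length(signature_ids) != ncol(x))
    abort("identifier lengths do not match matrix dimensions.")
  new_sig_matrix(cpp_pack(x), feature_ids, signature_ids)
}

new_sig_matrix <- function(words, feature_ids, signature_ids) {
  K <- length(feature_ids)
  N <- length(signature_ids)
  structure(
    list(words = words,
         feature_ids = as.character(feature_ids),
         signature_ids = as.character(signature_ids),
         K = K, N = N, W = (K + 63L) %/% 64L),
    class = "sig_matrix")
}

validate_sig_matrix <- function(sig) {
  stopifnot(inherits(sig, "sig_matrix"))
  if (length(sig$words) != 8L * sig$W * sig$N)
    abort("corrupted signature matrix: word buffer size mismatch.")
  if (!cpp_padding_clean(sig$words, sig$K, sig$N))
    abort("corrupted signature matrix: nonzero padding bits.")
  invisible(sig)
}

#' @rdname pack_signatures
#' @param sig A `sig_matrix`.
#' @export
unpack_signatures <- function(sig) {
  validate_sig_matrix(sig)
  out <- cpp_unpack(sig$words, sig$K, sig$N)
  dimnames(out) <- list(sig$feature_ids, sig$signature_ids)
  out
}

#' Population counts
#'
#' [popcount_words()] counts set bits in a raw buffer of little-endian 64-bit
#' words; [signature_sizes()] gives the per-signature set-bit count (the
#' signature size: number of features in each signature).
#'
#' @param words A raw vector whose length is a multiple of 8.
#' @return [popcount_words()]: a single non-negative number.
#'   [signature_sizes()]: a named integer vector, one entry per signature.
#' @export
popcount_words <- function(words) {
  stopifnot(is.raw(words))
  cpp_popcount(words)
}

#' @rdname popcount_words
#' @param sig A `sig_matrix`.
#' @export
signature_sizes <- function(sig) {
  validate_sig_matrix(sig)
  stats::setNames(cpp_col_popcounts(sig$words, sig$K, sig$N), sig$signature_ids)
}

#' @export
print.sig_matrix <- function(x, ...) {
  cat(sprintf("<sig_matrix> %d features x %d signatures (%d words/signature)\n",
              x$K, x$N, x$W))
  sz <- signature_sizes(x)
  cat(sprintf("  signature sizes: min %d, median %s, max %d\n",
              min(sz), format(stats::median(sz)), max(sz)))
  invisible(x)
}

#' @export
dim.sig_matrix <- function(x) c(x$K, x$N)

# Column subsetting by index; used by the chunked comparison driver.
#' @export
`[.sig_matrix` <- function(x, j) {
  j <- seq_len(x$N)[j]
  if (anyNA(j)) abort("signature index out of range.")
  bytes_per_col <- 8L * x$W
  keep <- unlist(lapply(j, function(jj) {
    (jj - 1L) * bytes_per_col + seq_len(bytes_per_col)
  }))
  new_sig_matrix(x$words[keep], x$feature_ids, x$signature_ids[j])
}
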