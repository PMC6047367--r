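#' Timing comparison of bit-count filtering vs full-precision metrics
#'
#' Generates a Gaussian benchmark matrix, binarizes it at the given cuts,
#' and times (a) the packed AND self-comparison of the low and high
#' signature matrices and (b) the all-pairs cosine baseline on the
#' full-precision values (computed via a crossproduct, the fastest dense
#' route available here). Timings are informational — they depend on the
#' machine — but the ordering illustrates why filtering before refining
#' pays.
#'
#' @param n_features,n_samples Benchmark dimensions (defaults 20,000 x 500;
#'   the full-scale run uses 15,000 samples).
#' @param sigma,low_cut,high_cut Generation and binarization parameters.
#' @param seed Seed for the synthetic matrix.
#' @return A tibble with one row per timed method: `method`, `n_pairs`,
#'   `seconds`.
#' @export
sig_benchmark <- function(n_features = 20000, n_samples = 500, sigma = 0.5,
                          low_cut = -0.6, high_cut = 0.6, seed = 1L) {
  x <- synth_gaussian_matrix(n_features, n_samples, sigma, seed = seed)
  b <- threshold_binarize(x, low_cut, high_cut)
  n_pairs <- pair_count(n_samples)
  t_bit <- system.time({
    sig_compare_self(b$low, "and")
    sig_compare_self(b$high, "and")
  })[["elapsed"]]
  t_cos <- system.time(cosine_all_pairs(x))[["elapsed"]]
  tibble(method = c("bit_and_self (low+high)", "cosine_all_pairs"),
         n_pairs = c(2 * n_pairs, n_pairs),
         seconds = c(t_bit, t_cos))
}

# All-pairs cosine via normalized crossproduct (baseline only; the
# per-pair reference implementation is cosine_similarity()).
cosine_all_pairs <- function(x) {
  norms <- sqrt(colSums(x^2))
  if (any(norms == 0)) abort("cosine undefined for a zero-norm column.")
  crossprod(x) / tcrossprod(norms)
}
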