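#' Shared gene content between genomes
#'
#' Gene presence/absence is already binary, so genome similarity is a direct
#' AND self-comparison of an ortholog-by-genome presence matrix: cell
#' (i, j) is the number of orthologs annotated in both genomes.
#'
#' @param presence A `sig_matrix` of ortholog presence/absence (orthologs in
#'   rows, genomes in columns), or a 0/1 matrix to pack.
#' @return A self `sig_result` of shared-ortholog counts.
#' @export
shared_ortholog_counts <- function(presence) {
  if (!inherits(presence, "sig_matrix")) presence <- pack_signatures(presence)
  sig_compare_self(presence, "and")
}

check_labels <- function(labels, genomes, level) {
  stopifnot(is.data.frame(labels), "genome" %in% names(labels))
  if (!level %in% names(labels))
    abort(sprintf("no column `%s` in the taxonomy table.", level))
  missing <- setdiff(genomes, labels$genome)
  if (length(missing) > 0)
    abort(sprintf("genome(s) without a taxonomy label: %s",
                  paste(missing, collapse = ", ")))
  stats::setNames(as.character(labels[[level]]), labels$genome)[genomes]
}

# symmetrized full count matrix from a strictly-upper self result
full_counts <- function(counts) {
  stopifnot(inherits(counts, "sig_result"))
  if (!counts$self) abort("expected a self-comparison result.")
  counts$counts + t(counts$counts)
}

#' Mean shared genes within a genome's taxonomic group
#'
#' For each genome, the average shared-ortholog count with the other
#' genomes of its group at the chosen taxonomic level. A genome whose group
#' has a single member has no within-group pairs; its mean is undefined
#' (`NA`) and flagged.
#'
#' @param counts A self `sig_result` from [shared_ortholog_counts()].
#' @param labels Taxonomy table with a `genome` column plus one column per
#'   level (e.g. `domain`, `group`, `genus`), covering every genome.
#' @param level Column of `labels` to group by.
#' @return A tibble with `genome`, `group`, `n_members`, `mean_shared`,
#'   `defined`.
#' @export
within_group_means <- function(counts, labels, level = "group") {
  full <- full_counts(counts)
  genomes <- rownames(full)
  grp <- check_labels(labels, genomes, level)
  purrr::map_dfr(seq_along(genomes), function(i) {
    others <- which(grp == grp[i])
    others <- setdiff(others, i)
    tibble(genome = genomes[i], group = unname(grp[i]),
           n_members = length(others) + 1L,
           mean_shared = if (length(others)) mean(full[i, others]) else NA_real_,
           defined = length(others) > 0)
  })
}

#' Group-by-group mean shared-gene matrix
#'
#' Cell (A, B) is the mean shared-ortholog count over all cross pairs with
#' one genome in group A and one in group B; the diagonal is the mean over
#' within-group pairs, excluding genome-with-itself pairs, and is undefined
#' (`NA`, flagged) for singleton groups. The matrix is symmetric.
#'
#' @inheritParams within_group_means
#' @param level Taxonomic level; genus-level matrices are the usual view.
#' @return A `sig_group_matrix`: list with the symmetric `means` matrix,
#'   per-group `n_members`, and `level`. [tidy()] gives the long form.
#' @export
group_pair_matrix <- function(counts, labels, level = "genus") {
  full <- full_counts(counts)
  genomes <- rownames(full)
  grp <- check_labels(labels, genomes, level)
  groups <- sort(unique(grp))
  g <- length(groups)
  means <- matrix(NA_real_, g, g, dimnames = list(groups, groups))
  members <- lapply(groups, function(a) which(grp == a))
  for (ai in seq_len(g)) {
    for (bi in ai:g) {
      a <- members[[ai]]; b <- members[[bi]]
      if (ai == bi) {
        if (length(a) >= 2) {
          sub <- full[a, a, drop = FALSE]
          means[ai, ai] <- mean(sub[upper.tri(sub)])
        }
      } else {
        means[ai, bi] <- means[bi, ai] <- mean(full[a, b, drop = FALSE])
      }
    }
  }
  structure(list(means = means,
                 n_members = stats::setNames(lengths(members), groups),
                 level = level),
            class = "sig_group_matrix")
}

#' @export
print.sig_group_matrix <- function(x, ...) {
  cat(sprintf("<sig_group_matrix> %d %s groups; singleton diagonals NA\n",
              nrow(x$means), x$level))
  print(round(x$means, 1))
  invisible(x)
}

#' @method tidy sig_group_matrix
#' @export
tidy.sig_group_matrix <- function(x, ...) {
  idx <- which(row(x$means) <= col(x$means), arr.ind = TRUE)
  tibble(group_a = rownames(x$means)[idx[, 1]],
         group_b = colnames(x$means)[idx[, 2]],
         mean_shared = x$means[idx],
         defined = !is.na(x$means[idx])) |>
    dplyr::arrange(.data$group_a, .data$group_b)
}

#' @rdname group_pair_matrix
#' @param object A `sig_group_matrix`.
#' @param cluster Reorder rows/columns by average-linkage hierarchical
#'   clustering of the mean-shared matrix (presentation only).
#' @param ... Unused.
#' @method autoplot sig_group_matrix
#' @export
autoplot.sig_group_matrix <- function(object, cluster = TRUE, ...) {
  m <- object$means
  ord <- seq_len(nrow(m))
  if (cluster && nrow(m) > 2) {
    d <- stats::as.dist(max(m, na.rm = TRUE) - replace(m, is.na(m), 0))
    ord <- stats::hclust(d, method = "average")$order
  }
  m <- m[ord, ord, drop = FALSE]
  long <- tibble(group_a = factor(rep(rownames(m), times = ncol(m)),
                                  levels = rownames(m)),
                 group_b = factor(rep(colnames(m), each = nrow(m)),
                                  levels = colnames(m)),
                 mean_shared = as.vector(m))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group_b, y = .data$group_a,
                                     fill = .data$mean_shared)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean shared") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Select genomes by annotated gene count
#'
#' Keeps genomes whose presence-column popcount lies in `[lo, hi]`
#' inclusive — e.g. the 200-600 gene range that picks out minimalist,
#' genome-reduced organisms.
#'
#' @param presence A `sig_matrix` (or 0/1 matrix) of ortholog presence.
#' @param lo,hi Inclusive gene-count bounds.
#' @return Character vector of genome ids.
#' @export
select_minimal_genomes <- function(presence, lo = 200, hi = 600) {
  if (lo > hi) abort("`lo` must not exceed `hi`.")
  if (!inherits(presence, "sig_matrix")) presence <- pack_signatures(presence)
  sz <- signature_sizes(presence)
  names(sz)[sz >= lo & sz <= hi]
}

#' Domain composition of a taxonomy table
#'
#' Counts genomes per domain and in total; the standard sanity check that a
#' presence matrix and its metadata describe the same organisms.
#'
#' @param labels Taxonomy table with `genome` and `domain` columns.
#' @return A tibble of per-domain counts with a final `total` row.
#' @export
taxonomy_composition <- function(labels) {
  stopifnot(is.data.frame(labels), all(c("genome", "domain") %in% names(labels)))
  if (anyDuplicated(labels$genome))
    abort("duplicate genome ids in the taxonomy table.")
  per <- labels |>
    dplyr::count(.data$domain, name = "n_genomes") |>
    dplyr::arrange(.data$domain)
  dplyr::bind_rows(per, tibble(domain = "total", n_genomes = nrow(labels)))
}
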