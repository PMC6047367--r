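#' Synthetic Gaussian expression benchmark matrix
#'
#' Draws a features-by-samples matrix of independent Gaussian values with
#' mean 0 and standard deviation `sigma` (default 0.5), emulating the kind
#' of centred log-ratio expression table whose tails mark down/up regulated
#' genes. With the default binarization cuts of ±0.6, each tail captures
#' `pnorm(-1.2)` ≈ 11.5% of values. Default size is 20,000 features by 500
#' samples — the full-scale benchmark uses 15,000 samples, reachable via
#' `n_samples`.
#'
#' @param n_features,n_samples Matrix dimensions.
#' @param sigma Gaussian standard deviation.
#' @param seed Optional integer seed; generation is a pure function of the
#'   arguments plus seed, and the caller's RNG state is untouched.
#' @return A numeric matrix with feature/sample dimnames.
#' @export
synth_gaussian_matrix <- function(n_features = 20000, n_samples = 500,
                                  sigma = 0.5, seed = NULL) {
  stopifnot(n_features >= 1, n_samples >= 1, sigma > 0)
  draw <- function() {
    matrix(stats::rnorm(n_features * n_samples, mean = 0, sd = sigma),
           nrow = n_features,
           dimnames = list(sprintf("gene_%05d", seq_len(n_features)),
                           sprintf("sample_%05d", seq_len(n_samples))))
  }
  with_opt_seed(seed, draw)
}

with_opt_seed <- function(seed, fn) {
  if (is.null(seed)) fn() else withr::with_seed(seed, fn())
}

#' Synthetic up/down signature collection with planted clusters
#'
#' Emulates a collection of differential-expression signatures: each
#' signature is a pair of disjoint up/down feature sets of fixed size.
#' Members of a planted cluster share a fixed core fraction of their up and
#' down sets (the same core for all members); the rest of each signature,
#' and all background signatures, are drawn independently. Cluster
#' membership is returned so recovery can be scored.
#'
#' Defaults: 5 clusters of 10 members with core fraction 0.6, 100 features
#' per direction over a 2,000-feature universe, 100 signatures in total
#' (the remainder is background).
#'
#' @param n_features Universe size.
#' @param n_signatures Total signatures (clustered + background).
#' @param n_clusters,cluster_size Planted cluster layout;
#'   `n_clusters * cluster_size <= n_signatures` required.
#' @param signature_size Up and down set size per signature.
#' @param overlap Core fraction in `[0, 1]` shared within a cluster.
#' @param seed Optional integer seed.
#' @return A list: `down` and `up` (`sig_matrix`), and `truth`, a tibble
#'   with `signature_id` and `cluster` (`NA` for background).
#' @export
synth_lincs <- function(n_features = 2000, n_signatures = 100,
                        n_clusters = 5, cluster_size = 10,
                        signature_size = 100, overlap = 0.6, seed = NULL) {
  stopifnot(overlap >= 0, overlap <= 1, n_clusters >= 1, cluster_size >= 1)
  core <- round(overlap * signature_size)
  if (core > signature_size)
    abort("overlap fraction infeasible for the signature size.")
  if (2 * signature_size > n_features)
    abort("universe too small for disjoint up/down sets of this size.")
  if (n_clusters * cluster_size > n_signatures)
    abort("planted clusters exceed the number of signatures.")
  features <- sprintf("gene_%04d", seq_len(n_features))
  with_opt_seed(seed, function() {
    up_sets <- list(); down_sets <- list(); cluster_of <- integer(0)
    sid <- 0L
    for (cl in seq_len(n_clusters)) {
      up_core <- sample(features, core)
      down_core <- sample(setdiff(features, up_core), core)
      pool <- setdiff(features, c(up_core, down_core))
      for (m in seq_len(cluster_size)) {
        sid <- sid + 1L
        extra_up <- sample(pool, signature_size - core)
        extra_down <- sample(setdiff(pool, extra_up), signature_size - core)
        up_sets[[sid]] <- c(up_core, extra_up)
        down_sets[[sid]] <- c(down_core, extra_down)
        cluster_of[sid] <- cl
      }
    }
    while (sid < n_signatures) {
      sid <- sid + 1L
      up <- sample(features, signature_size)
      down <- sample(setdiff(features, up), signature_size)
      up_sets[[sid]] <- up
      down_sets[[sid]] <- down
      cluster_of[sid] <- NA_integer_
    }
    ids <- sprintf("sig_%03d", seq_len(n_signatures))
    names(up_sets) <- ids
    names(down_sets) <- ids
    sigs <- updown_signatures(up_sets, down_sets, features)
    list(down = sigs$down, up = sigs$up,
         truth = tibble(signature_id = ids, cluster = cluster_of))
  })
}

#' Synthetic ortholog presence/absence matrix with taxonomic structure
#'
#' Emulates a knowledgebase-style gene-content table: genomes belong to
#' taxonomic groups nested in domains; each group has a core gene set
#' shared by all its members (cores are disjoint across groups), and each
#' genome adds accessory genes drawn from a common pool to reach a
#' domain-typical genome size. Eukaryote genomes are largest, archaea
#' smallest, mirroring real annotation counts. Within-group sharing
#' therefore exceeds between-group sharing by construction.
#'
#' @param n_orthologs Universe size.
#' @param genomes_per_domain Named counts for `eukaryote`, `bacterium`,
#'   `archaeon`.
#' @param groups_per_domain Named group counts per domain.
#' @param size_ranges Named list of `c(lo, hi)` genome-size ranges.
#' @param core_fraction Fraction of a domain's minimum genome size used as
#'   the group core size.
#' @param seed Optional integer seed.
#' @return A list: `presence` (`sig_matrix`) and `labels` (tibble with
#'   `genome`, `domain`, `group`, `genus`).
#' @export
synth_kegg <- function(n_orthologs = 5000,
                       genomes_per_domain = c(eukaryote = 6, bacterium = 20,
                                              archaeon = 6),
                       groups_per_domain = c(eukaryote = 2, bacterium = 5,
                                             archaeon = 2),
                       size_ranges = list(eukaryote = c(1200, 1800),
                                          bacterium = c(400, 900),
                                          archaeon = c(300, 700)),
                       core_fraction = 0.7, seed = NULL) {
  domains <- names(genomes_per_domain)
  stopifnot(identical(domains, names(groups_per_domain)),
            all(domains %in% names(size_ranges)),
            core_fraction > 0, core_fraction <= 1)
  orthologs <- sprintf("K%05d", seq_len(n_orthologs))
  with_opt_seed(seed, function() {
    core_sizes <- unlist(lapply(domains, function(d) {
      rep(round(core_fraction * size_ranges[[d]][1]), groups_per_domain[[d]])
    }))
    if (sum(core_sizes) >= n_orthologs)
      abort("ortholog universe too small for the requested disjoint cores.")
    # disjoint cores at the front of the universe, shared accessory pool after
    bounds <- cumsum(c(0, core_sizes))
    pool <- orthologs[(bounds[length(bounds)] + 1):n_orthologs]
    cols <- list(); labels <- list(); gi <- 0L; grp_i <- 0L
    for (d in domains) {
      n_g <- genomes_per_domain[[d]]
      n_grp <- groups_per_domain[[d]]
      grp_assign <- rep(seq_len(n_grp), length.out = n_g)
      rng <- size_ranges[[d]]
      for (g in seq_len(n_grp)) {
        grp_i <- grp_i + 1L
        core <- orthologs[(bounds[grp_i] + 1):bounds[grp_i + 1]]
        members <- which(grp_assign == g)
        for (m in seq_along(members)) {
          gi <- gi + 1L
          size <- sample(rng[1]:rng[2], 1)
          acc <- sample(pool, max(0, size - length(core)))
          cols[[gi]] <- union(core, acc)
          labels[[gi]] <- tibble(
            genome = sprintf("gn_%03d", gi), domain = d,
            group = sprintf("%s_grp%d", substr(d, 1, 3), g),
            genus = sprintf("%s_grp%d_gen%d", substr(d, 1, 3), g,
                            1L + (m - 1L) %% 2L))
        }
      }
    }
    labels <- dplyr::bind_rows(labels)
    mat <- vapply(cols, function(s) as.integer(orthologs %in% s),
                  integer(n_orthologs))
    dimnames(mat) <- list(orthologs, labels$genome)
    list(presence = pack_signatures(mat), labels = labels)
  })
}

#' Rand index between two partitions
#'
#' Fraction of element pairs on which two partitions agree (both together
#' or both apart); 1 means identical clusterings.
#'
#' @param a,b Cluster label vectors of equal length (any atomic type).
#' @return A number in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  n <- length(a)
  sum_cells <- sum(choose(tab, 2))
  sum_rows <- sum(choose(rowSums(tab), 2))
  sum_cols <- sum(choose(colSums(tab), 2))
  (choose(n, 2) + 2 * sum_cells - sum_rows - sum_cols) / choose(n, 2)
}
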