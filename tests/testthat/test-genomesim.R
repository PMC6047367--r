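fixture_counts <- function(seed = 61, n_orth = 300, n_gen = 20) {
  set.seed(seed)
  X <- random_binary(n_orth, n_gen, p = 0.4)
  colnames(X) <- sprintf("gn%02d", seq_len(n_gen))
  list(X = X, counts = shared_ortholog_counts(pack_signatures(X)))
}

random_labels <- function(genomes, n_groups = 4) {
  tibble::tibble(genome = genomes,
                 domain = "bacterium",
                 group = sample(sprintf("grp%d", seq_len(n_groups)),
                                length(genomes), replace = TRUE),
                 genus = sample(sprintf("gen%d", 1:6),
                                length(genomes), replace = TRUE))
}

test_that("shared ortholog counts are set intersections of gene content", {
  # identical genomes share their whole gene complement
  X <- cbind(a = c(1L, 1L, 0L, 1L), b = c(1L, 1L, 0L, 1L))
  rownames(X) <- sprintf("K%d", 1:4)
  expect_equal(unname(shared_ortholog_counts(X)$counts[1, 2]), 3L)

  # disjoint gene sets share nothing
  Y <- cbind(a = c(1L, 1L, 0L, 0L), b = c(0L, 0L, 1L, 1L))
  expect_equal(unname(shared_ortholog_counts(Y)$counts[1, 2]), 0L)

  f <- fixture_counts()
  want <- oracle_compare(f$X, f$X, "and")
  got <- f$counts$counts
  expect_equal(unname(got[upper.tri(got)]), want[upper.tri(want)])
})

test_that("within-group means match brute-force averaging and flag singletons", {
  # two identical genomes with 500 genes each
  Z <- matrix(0L, 600, 3, dimnames = list(NULL, c("a", "b", "solo")))
  Z[1:500, 1] <- Z[1:500, 2] <- 1L
  Z[1:100, 3] <- 1L
  labels <- tibble::tibble(genome = c("a", "b", "solo"),
                           domain = "bacterium",
                           group = c("pair", "pair", "lone"),
                           genus = "g")
  res <- within_group_means(shared_ortholog_counts(Z), labels, "group")
  expect_equal(res$mean_shared[res$genome %in% c("a", "b")], c(500, 500))
  expect_false(res$defined[res$genome == "solo"])
  expect_true(is.na(res$mean_shared[res$genome == "solo"]))

  # brute-force per-genome averaging on a random fixture
  set.seed(62)
  f <- fixture_counts()
  labels <- random_labels(colnames(f$X))
  res <- within_group_means(f$counts, labels, "group")
  full <- f$counts$counts + t(f$counts$counts)
  for (r in seq_len(nrow(res))) {
    others <- labels$genome[labels$group == res$group[r] &
                              labels$genome != res$genome[r]]
    if (length(others) == 0) {
      expect_true(is.na(res$mean_shared[r]))
    } else {
      expect_equal(res$mean_shared[r], mean(full[res$genome[r], others]))
    }
  }

  # order invariance
  perm <- sample(ncol(f$X))
  res2 <- within_group_means(shared_ortholog_counts(f$X[, perm]), labels, "group")
  expect_equal(dplyr::arrange(res, genome), dplyr::arrange(res2, genome))

  expect_error(within_group_means(f$counts, labels[-1, ], "group"),
               "without a taxonomy label")
})

test_that("group-pair matrix averages cross pairs and excludes self-pairs", {
  # two singleton groups: off-diagonal is their single pairwise count
  X <- cbind(a = c(1L, 1L, 1L, 0L), b = c(1L, 0L, 1L, 1L))
  labels <- tibble::tibble(genome = c("a", "b"), domain = "d",
                           group = c("A", "B"), genus = c("A", "B"))
  gm <- group_pair_matrix(shared_ortholog_counts(X), labels, "group")
  expect_equal(gm$means["A", "B"], 2)
  expect_true(is.na(gm$means["A", "A"]))  # singleton diagonal flagged

  # all genomes identical: constant matrix
  Z <- matrix(rep(c(1L, 0L), times = c(5, 5)), 10, 4)
  colnames(Z) <- sprintf("g%d", 1:4)
  labels <- tibble::tibble(genome = colnames(Z), domain = "d",
                           group = rep(c("A", "B"), 2), genus = "g")
  gm <- group_pair_matrix(shared_ortholog_counts(Z), labels, "group")
  expect_true(all(gm$means == 5))

  # random case vs brute-force double loop
  set.seed(63)
  f <- fixture_counts()
  labels <- random_labels(colnames(f$X))
  gm <- group_pair_matrix(f$counts, labels, "group")
  full <- f$counts$counts + t(f$counts$counts)
  for (a in rownames(gm$means)) for (b in colnames(gm$means)) {
    ga <- labels$genome[labels$group == a]
    gb <- labels$genome[labels$group == b]
    if (a == b) {
      if (length(ga) < 2) {
        expect_true(is.na(gm$means[a, a]))
      } else {
        sub <- full[ga, ga]
        expect_equal(gm$means[a, a], mean(sub[upper.tri(sub)]))
      }
    } else {
      expect_equal(gm$means[a, b], mean(full[ga, gb]))
      expect_equal(gm$means[a, b], gm$means[b, a])
    }
  }

  # diagonal equals the member-weighted within-group means
  wg <- within_group_means(f$counts, labels, "group")
  for (a in rownames(gm$means)) {
    members <- wg[wg$group == a & wg$defined, ]
    if (nrow(members) >= 2)
      expect_equal(gm$means[a, a],
                   sum(members$mean_shared * (members$n_members - 1)) /
                     (members$n_members[1] * (members$n_members[1] - 1)))
  }
})

test_that("gene-count selection uses inclusive bounds", {
  X <- matrix(0L, 700, 4, dimnames = list(NULL, c("tiny", "lo", "hi", "big")))
  X[1:100, 1] <- 1L
  X[1:200, 2] <- 1L
  X[1:600, 3] <- 1L
  X[1:700, 4] <- 1L
  expect_equal(select_minimal_genomes(X, 200, 600), c("lo", "hi"))
  expect_error(select_minimal_genomes(X, 200, 150), "must not exceed")
  # all below the range
  expect_equal(select_minimal_genomes(X[, 1, drop = FALSE], 200, 600),
               character(0))
  # random filter vs per-column sums
  set.seed(64)
  Y <- random_binary(300, 15, p = 0.5)
  expect_equal(select_minimal_genomes(Y, 140, 160),
               names(which(colSums(Y) >= 140 & colSums(Y) <= 160)))
})

test_that("taxonomy composition counts genomes per domain with a total row", {
  labels <- tibble::tibble(genome = sprintf("g%d", 1:9),
                           domain = rep(c("archaeon", "bacterium", "eukaryote"),
                                        c(2, 4, 3)))
  comp <- taxonomy_composition(labels)
  expect_equal(comp$n_genomes[comp$domain == "bacterium"], 4L)
  expect_equal(comp$n_genomes[comp$domain == "total"], 9L)
  expect_error(taxonomy_composition(labels[c(1, 1), ]), "duplicate")
})

test_that("synthetic gene-content fixture separates groups as planted", {
  sim <- synth_kegg(seed = 65)
  counts <- shared_ortholog_counts(sim$presence)
  gm <- group_pair_matrix(counts, sim$labels, "group")
  m <- gm$means
  for (a in rownames(m)) {
    others <- setdiff(colnames(m), a)
    expect_true(all(m[a, a] > m[a, others]),
                label = sprintf("within-group mean for %s exceeds between", a))
  }
})
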