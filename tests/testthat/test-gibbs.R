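test_that("the default configuration echoes the standard parameterization", {
  cfg <- gibbs_config()
  expect_identical(cfg$cluster_range, 1:6)
  expect_identical(cfg$motif_length, 9L)
  expect_identical(cfg$max_deletions, 2L)
  expect_identical(cfg$max_insertions, 0L)
  expect_identical(cfg$n_seeds, 5L)
  expect_identical(cfg$lambda, 0.8)
  expect_identical(cfg$sigma, 5)
  expect_true(cfg$use_trash)
  expect_identical(cfg$trash_threshold, 2)
  expect_identical(cfg$iters_per_seq_per_temp, 10L)
  expect_error(gibbs_config(max_insertions = 1), "insertions")
})

test_that("core alignments keep the terminal anchor residues", {
  expect_equal(nrow(alignments_for_length(9, 9, 2)), 1L)
  a10 <- alignments_for_length(10, 9, 2)
  expect_equal(nrow(a10), 8L)                # one interior deletion
  a11 <- alignments_for_length(11, 9, 2)
  expect_equal(nrow(a11), choose(9, 2))      # two interior deletions
  expect_true(all(a10[, 1] == 1) && all(a11[, 1] == 1))  # N-terminus kept
  expect_true(all(a10[, 9] == 10))                       # C-terminus kept
  expect_true(all(a11[, 9] == 11))
  expect_error(alignments_for_length(12, 9, 2), "not alignable")
})

test_that("clustering is deterministic and partitions every peptide", {
  peps <- sample_motif_peptides(motif_LV(), 60, 0.1, seed = 2)$peptide
  cfg <- gibbs_config(cluster_range = 1:3, n_seeds = 2, rng_seed = 42)
  a <- cluster_peptides(peps, cfg)
  b <- cluster_peptides(peps, cfg)
  expect_identical(a$kld_by_K, b$kld_by_K)
  expect_identical(lapply(a$solutions, `[[`, "assignment"),
                   lapply(b$solutions, `[[`, "assignment"))

  for (sol in a$solutions) {
    expect_true(all(sol$assignment %in% 0:sol$K))
    expect_equal(sum(sol$cluster_sizes) + sol$trash_count,
                 length(a$peptides))
    expect_true(is.finite(sol$kld))
    expect_true(all(sol$per_cluster_kld >= 0))
  }
  # selection maximizes the objective over the range
  expect_equal(a$kld_by_K[[as.character(a$selected_K)]], max(a$kld_by_K))
})

test_that("the greedy polish terminates at a fixed point without degrading fit", {
  peps <- unique(c(sample_motif_peptides(motif_LV(), 80, 0.05, seed = 3)$peptide,
                   sample_motif_peptides(motif_KR(), 80, 0.05, seed = 4)$peptide))
  cl <- cluster_peptides(peps, gibbs_config(cluster_range = 2:3, n_seeds = 2,
                                            rng_seed = 5))
  for (sol in cl$solutions) {
    tr <- sol$polish_trace
    expect_gte(length(tr), 2L)
    # converged: the last sweep moved nothing, leaving the objective fixed
    expect_equal(tr[length(tr)], tr[length(tr) - 1], tolerance = 1e-12)
    # and on these runs each greedy sweep improved (or kept) the total fit
    expect_true(all(diff(tr) >= -1e-9))
  }
})

test_that("a single strong motif selects one cluster", {
  peps <- unique(sample_motif_peptides(motif_LV(), 60, 0, seed = 7)$peptide)
  peps <- peps[seq_len(50)]
  cl <- cluster_peptides(peps, gibbs_config(cluster_range = 1:3, rng_seed = 7))
  expect_identical(cl$selected_K, 1L)
})

test_that("two disjoint planted motifs are recovered with their anchors", {
  d <- rbind(sample_motif_peptides(motif_LV(), 100, 0.05, seed = 11),
             sample_motif_peptides(motif_KR(), 100, 0.05, seed = 12))
  d <- d[!duplicated(d$peptide), ]
  cl <- cluster_peptides(d$peptide, gibbs_config(rng_seed = 11))
  expect_identical(cl$selected_K, 2L)

  sol <- cl$solutions[["2"]]
  truth <- ifelse(seq_len(nrow(d)) <= 100, 1L, 2L)
  truth[d$label == "background"] <- 3L
  keep <- sol$assignment > 0L
  ari <- mclust::adjustedRandIndex(sol$assignment[keep], truth[keep])
  expect_gte(ari, 0.9)

  # per-group consensus matches the planted anchor residues
  cons <- vapply(1:2, function(c)
    paste(AAs[apply(sol$freq[[c]], 1, which.max)], collapse = ""), "")
  p2 <- substr(cons, 2, 2)
  p9 <- substr(cons, 9, 9)
  expect_setequal(p2, c("L", "K"))
  expect_setequal(p9, c("V", "R"))
})

test_that("retained peptides reproduce the partition with alignments", {
  d <- c(sample_motif_peptides(motif_LV(), 60, 0.1, seed = 21)$peptide,
         # 10- and 11-mers join through interior deletions
         paste0(sample_motif_peptides(motif_LV(), 20, 0, seed = 22)$peptide,
                "A"),
         paste0(sample_motif_peptides(motif_LV(), 20, 0, seed = 23)$peptide,
                "AC"))
  d <- unique(d)
  cl <- cluster_peptides(d, gibbs_config(cluster_range = 1:2, n_seeds = 2,
                                         rng_seed = 8))
  ret <- retained_peptides(cl)
  n_grouped <- sum(vapply(ret$clusters, nrow, integer(1)))
  expect_equal(n_grouped + ret$trash_count, length(d))
  expect_setequal(c(unlist(lapply(ret$clusters, `[[`, "peptide")),
                    ret$trash), d)

  for (grp in ret$clusters) {
    for (i in seq_len(nrow(grp))) {
      keep <- grp$alignment[[i]]
      L <- nchar(grp$peptide[i])
      expect_length(keep, 9L)
      expect_equal(keep[1], 1L)        # anchors preserved at the core ends
      expect_equal(keep[9], L)
    }
  }

  k1 <- retained_peptides(cl, K = 1)
  expect_length(k1$clusters, 1L)
  expect_equal(nrow(k1$clusters[[1]]) + k1$trash_count, length(d))
})

test_that("degenerate and invalid inputs are handled", {
  expect_error(cluster_peptides(c("ACDEFGHIK", "ACDEFGHIW"),
                                gibbs_config(cluster_range = 1)),
               "at least 9")
  expect_error(cluster_peptides(random_peptides(20, length = 12, seed = 1),
                                gibbs_config(cluster_range = 1)),
               "lengths")
  # K larger than the structure supports still runs (empty clusters allowed)
  peps <- c(rep("ALDKEWQRV", 1), random_peptides(14, seed = 3))
  cl <- cluster_peptides(peps, gibbs_config(cluster_range = 2, n_seeds = 1,
                                            rng_seed = 2))
  expect_s3_class(cl, "gibbs_clustering")
})
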