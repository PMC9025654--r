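test_that("frequency profiles count exactly", {
  p <- amino_acid_frequencies(c("AAA", "AAA"))
  expect_equal(unname(p$pmf[, "A"]), rep(1, 3))
  expect_equal(rowSums(p$pmf), rep(1, 3), tolerance = 1e-12)

  p2 <- amino_acid_frequencies(c("AC", "CA"))
  expect_equal(unname(p2$pmf[, "A"]), c(0.5, 0.5))
  expect_equal(unname(p2$pmf[, "C"]), c(0.5, 0.5))

  peps <- sample_motif_peptides(motif_LV(), 500, 0.1, seed = 5)$peptide
  p3 <- amino_acid_frequencies(peps)
  # naive counting oracle
  for (i in c(1, 2, 9)) {
    counts <- table(factor(substr(peps, i, i), levels = AAs))
    expect_equal(unname(p3$pmf[i, ]), as.numeric(counts) / length(peps))
  }
  expect_error(amino_acid_frequencies(c("AAA", "AAAA")), "mixed lengths")
})

test_that("PCC_aaf matches the textbook covariance formula", {
  x <- amino_acid_frequencies(random_peptides(1000, seed = 21))
  y <- amino_acid_frequencies(random_peptides(1000, seed = 22))
  r <- pcc_aaf(x, y)
  for (i in seq_len(9)) {
    expect_equal(r$pcc[i], oracle_pcc(x$pmf[i, ], y$pmf[i, ]),
                 tolerance = 1e-12)
  }
  expect_equal(r$mean, mean(r$pcc), tolerance = 1e-12)
  expect_true(all(r$pcc >= -1 & r$pcc <= 1))
})

test_that("PCC_aaf is symmetric with self-correlation one", {
  x <- amino_acid_frequencies(sample_motif_peptides(motif_LV(), 200,
                                                    seed = 2)$peptide)
  y <- amino_acid_frequencies(sample_motif_peptides(motif_KR(), 200,
                                                    seed = 3)$peptide)
  expect_identical(pcc_aaf(x, y)$pcc, pcc_aaf(y, x)$pcc)
  self <- pcc_aaf(x, x)
  expect_equal(self$pcc, rep(1, 9), tolerance = 1e-12)
  expect_equal(self$mean, 1)
})

test_that("zero-variance positions are excluded from the mean with a warning", {
  x <- amino_acid_frequencies(c("AC", "AD"))   # position 1 constant, pos 2 varies
  y <- amino_acid_frequencies(c("AC", "AC"))
  # make a uniform row by hand: every residue equally likely
  u <- x
  u$pmf[1, ] <- 1 / 20
  expect_warning(r <- pcc_aaf(u, y), "zero variance")
  expect_true(is.na(r$pcc[1]))
  expect_equal(r$mean, r$pcc[2])
  expect_error(pcc_aaf(x, y, positions = c(0, 1)), "positions")
})

test_that("shared anchors dominate the positional correlation", {
  a <- sample_motif_peptides(motif_LV(), 800, 0, seed = 6)$peptide
  b <- sample_motif_peptides(motif_LV(), 800, 0, seed = 7)$peptide
  r <- pcc_aaf(a, b)
  anchor <- r$pcc[c(2, 9)]
  others <- r$pcc[-c(2, 9)]
  expect_true(all(anchor > max(others)))
  expect_gt(pcc_aaf(a, b, positions = c(2, 9))$mean, 0.95)
})

test_that("PCC converges to one as disjoint samples grow", {
  # a skewed background gives every position structure for the profiles to
  # agree on; with a uniform background non-anchor rows converge to zero
  # variance instead of correlation one
  spec <- motif_spec(anchors = list("2" = c("L", 0.7), "9" = c("V", 0.7)),
                     background = reference_background())
  means <- vapply(c(50, 500, 5000), function(n) {
    ms <- vapply(1:3, function(s) {
      a <- sample_motif_peptides(spec, n, 0, seed = 100 + s)$peptide
      b <- sample_motif_peptides(spec, n, 0, seed = 200 + s)$peptide
      pcc_aaf(a, b)$mean
    }, numeric(1))
    mean(ms)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  expect_gt(means[3], 0.95)
})
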