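test_that("background frequencies handle degenerate and exact compositions", {
  b <- background_frequencies("AAAA")
  expect_equal(unname(b["A"]), 1 - 19e-6, tolerance = 1e-9)
  expect_equal(sum(b), 1)
  expect_true(all(b > 0))

  b2 <- background_frequencies(c("ACD", "ACD"))
  expect_equal(unname(b2[c("A", "C", "D")]), rep(1 / 3, 3),
               tolerance = 1e-4)

  expect_error(background_frequencies(character()), "no sequences")
})

test_that("background frequencies of a uniform proteome are uniform", {
  prot <- random_proteins(200, c(490, 510), seed = 3)  # ~1e5 residues
  b <- background_frequencies(prot)
  n <- sum(nchar(prot$sequence))
  se <- sqrt(0.05 * 0.95 / n)
  expect_true(all(abs(b - 0.05) < 3 * se + 1e-5))
})

test_that("PSSM training matches the naive counting oracle", {
  bg <- background_frequencies(random_proteins(50, c(100, 200), seed = 2))
  for (seed in c(5, 6)) {
    peps <- sample_motif_peptides(motif_LV(), 100, seed = seed)$peptide
    for (form in c("log_odds", "as_printed")) {
      fit <- train_pssm(peps, bg, omega = 0.1, scoring_form = form)
      P <- oracle_pssm(peps, bg, 0.1, form)
      expect_equal(unname(fit$matrix), P, tolerance = 1e-12)
    }
  }
  expect_error(train_pssm(c("AAAA", "AAAAA")), "mixed lengths")
})

test_that("training limits behave as the smoothing formula dictates", {
  bg <- uniform_background()
  # one-hot limit: observed residues score log2(~1/B) > 0, all finite
  fit1 <- train_pssm("ACDEFGHIK", bg, omega = 1e-6)
  expect_true(all(is.finite(fit1$matrix)))
  expect_gt(fit1$matrix[1, "A"], 4)   # ~ log2(20)
  expect_lt(fit1$matrix[1, "C"], 0)

  # empirical frequencies equal to the background give a zero matrix
  perms <- vapply(0:19, function(k)
    paste(AAs[(seq(0, 8) + k) %% 20 + 1], collapse = ""), "")
  for (om in c(0.05, 0.5)) {
    fit0 <- train_pssm(perms, bg, omega = om)
    expect_equal(max(abs(fit0$matrix)), 0, tolerance = 1e-12)
  }

  # as_printed sums log-frequencies: every entry negative
  fitp <- train_pssm(perms, bg, omega = 0.1, scoring_form = "as_printed")
  expect_true(all(fitp$matrix < 0))
})

test_that("omega shrinks every log-odds entry toward zero", {
  peps <- sample_motif_peptides(motif_LV(), 60, seed = 4)$peptide
  oms <- c(0.01, 0.1, 0.5, 1, 5)
  mats <- lapply(oms, function(o) train_pssm(peps, omega = o)$matrix)
  for (i in seq_along(oms)[-1]) {
    expect_true(all(abs(mats[[i]]) <= abs(mats[[i - 1]]) + 1e-12))
  }
})

test_that("motif scores are per-position sums", {
  fit <- train_pssm("AC", uniform_background(), omega = 0.1)
  fit$matrix[] <- 0
  expect_equal(score_peptide(fit, c("AC", "WY")), c(0, 0))
  fit$matrix[1, "A"] <- 1.5
  fit$matrix[2, "C"] <- -0.5
  expect_equal(score_peptide(fit, "AC"), 1.0)

  expect_error(score_peptide(fit, "ACD"), "length")
  expect_error(score_peptide(fit, "AX"), "non-standard")

  # vectorized scorer equals the per-position loop oracle
  peps9 <- random_peptides(1000, seed = 17)
  fit9 <- train_pssm(sample_motif_peptides(motif_LV(), 80, seed = 3)$peptide,
                     omega = 0.1)
  vec <- score_peptide(fit9, peps9)
  loop <- vapply(peps9, oracle_score, numeric(1), P = fit9$matrix,
                 USE.NAMES = FALSE)
  expect_equal(vec, loop, tolerance = 1e-9)
})

test_that("log-odds scores are background-neutral and separate training data", {
  # a PSSM trained on background-distributed peptides scores fresh
  # background peptides near zero on average
  fit_bg <- train_pssm(random_peptides(5000, seed = 22), omega = 0.1)
  m0 <- mean(score_peptide(fit_bg, random_peptides(10000, seed = 23)))
  expect_gt(m0, -0.2)
  expect_lt(m0, 0.2)

  # a motif PSSM ranks its own training peptides above background
  train <- sample_motif_peptides(motif_LV(), 150, seed = 5)$peptide
  fit <- train_pssm(train, omega = 0.1)
  expect_gt(mean(score_peptide(fit, train)),
            mean(score_peptide(fit, random_peptides(10000, seed = 23))))
})

test_that("the filter threshold is a strict inequality with nested levels", {
  fit <- train_pssm("ACDEFGHIK", uniform_background(), omega = 0.1)
  fit$matrix[] <- 0
  fit$matrix[1, "A"] <- 0.3      # "A...": exactly 0.3
  fit$matrix[1, "C"] <- 0.3001   # just above
  fit$matrix[1, "D"] <- -1       # below
  kmers <- c("AAAAAAAAA", "CAAAAAAAA", "DAAAAAAAA")
  pass <- filter_kmers(kmers, fit, threshold = 0.3)
  expect_identical(pass$peptide, "CAAAAAAAA")

  expect_equal(nrow(filter_kmers(kmers, fit, threshold = -Inf)), 3L)

  fit2 <- train_pssm(sample_motif_peptides(motif_LV(), 80, seed = 9)$peptide,
                     omega = 0.1)
  space <- random_peptides(2000, seed = 31)
  prev <- NULL
  for (thr in c(-1, 0, 0.3, 1, 3)) {
    cur <- filter_kmers(space, fit2, threshold = thr)$peptide
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("filtering warns on unmodeled lengths and errors with none", {
  fit <- train_pssm(sample_motif_peptides(motif_LV(), 30, seed = 2)$peptide)
  expect_warning(r <- filter_kmers(c("ACDEFGHIK", "ACDEFGHIKL"), fit, -10),
                 "length")
  expect_identical(r$peptide, "ACDEFGHIK")
  expect_error(suppressWarnings(filter_kmers("ACDEFGHIKL", fit)),
               "no PSSM")
})

test_that("planted motif k-mers pass while background stays rare", {
  d <- sample_motif_peptides(motif_LV(), 200, 0, seed = 9)
  prot <- plant_proteome(d$peptide, 150, seed = 9)
  bg <- background_frequencies(prot)
  fit <- motif_model(d$peptide, background = bg,
                     gibbs = gibbs_config(cluster_range = 1:2, n_seeds = 2,
                                          rng_seed = 9))
  km <- enumerate_kmers(prot, digest_config(9, 9))
  pr <- predict(fit, km)
  planted <- pr$peptide %in% d$peptide
  expect_gt(mean(pr$pass[planted]), 0.7)        # most planted peptides pass
  expect_lt(mean(pr$pass[!planted]), 0.10)      # background passes are rare
})

test_that("PSSM serialization round-trips bit-exactly", {
  bg <- background_frequencies(random_proteins(30, c(50, 150), seed = 12))
  fit <- train_pssm(sample_motif_peptides(motif_KR(), 45, seed = 7)$peptide,
                    bg, omega = 0.1, cluster_id = 2L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pssm(fit, f)
  back <- read_pssm(f)
  expect_identical(unname(back$matrix), unname(fit$matrix))
  expect_identical(unname(back$background), unname(fit$background))
  expect_identical(back$omega, fit$omega)
  expect_identical(back$n_train, fit$n_train)
  expect_identical(back$scoring_form, fit$scoring_form)
  probe <- random_peptides(50, seed = 40)
  expect_identical(score_peptide(back, probe), score_peptide(fit, probe))
})
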