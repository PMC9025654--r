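# small, fast build setup used across these tests
small_build <- function(seed = 13, threshold = 0.3, contaminants = NULL,
                        include_contaminant_kmers = FALSE,
                        extra_hits = character()) {
  d <- sample_motif_peptides(motif_LV(), 60, 0, seed = seed)
  prot <- plant_proteome(d$peptide, 40, filler_length_range = c(60, 150),
                         seed = seed)
  hits <- unique(c(d$peptide, extra_hits))
  cfg <- build_config(gibbs = gibbs_config(cluster_range = 1:2, n_seeds = 2,
                                           rng_seed = seed),
                      threshold = threshold,
                      include_contaminant_kmers = include_contaminant_kmers,
                      rng_seed = seed)
  db <- suppressWarnings(build_targeted_database(hits, prot, contaminants,
                                                 cfg))
  list(db = db, hits = hits, prot = prot)
}

test_that("every first-round peptide enters the database (global FDR rule)", {
  x <- small_build()
  expect_true(all(x$hits %in% x$db$peptides$peptide))
  fr <- x$db$peptides[x$db$peptides$peptide %in% x$hits, ]
  expect_true(all(grepl("first_round", fr$provenance)))
})

test_that("a first-round peptide absent from the proteome is still included", {
  neo <- "WWWWHHHHH"  # a neoepitope-like sequence no background protein has
  x <- small_build(extra_hits = neo)
  row <- x$db$peptides[x$db$peptides$peptide == neo, ]
  expect_equal(nrow(row), 1L)
  expect_match(row$provenance, "first_round")
  km <- enumerate_kmers(x$prot)
  expect_false(neo %in% km$peptides$peptide)
})

test_that("motif-provenance peptides come from the enumerated space", {
  x <- small_build()
  km <- enumerate_kmers(x$prot)
  motif_only <- x$db$peptides[x$db$peptides$provenance == "motif", ]
  expect_true(all(motif_only$peptide %in% km$peptides$peptide))
  expect_true(all(x$db$peptides$length %in% 9:11))
})

test_that("the same seed reproduces a byte-identical database", {
  x1 <- small_build(seed = 17)
  x2 <- small_build(seed = 17)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_peptide_fasta(x1$db, f1)
  write_peptide_fasta(x2$db, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("databases nest across thresholds up to the injected hits", {
  lo <- small_build(threshold = 0)$db
  hi <- small_build(threshold = 1)$db
  fr <- small_build()$hits
  expect_true(all(hi$peptides$peptide %in%
                    c(lo$peptides$peptide, fr)))
  expect_lte(nrow(hi$peptides), nrow(lo$peptides))
})

test_that("the report satisfies the accounting identities", {
  x <- small_build()
  s <- x$db$summary
  expect_equal(sum(s$per_length), nrow(x$db$peptides))
  km <- enumerate_kmers(x$prot)
  expect_identical(s$full_space_unique, km$unique_counts)
  expect_equal(s$reduction_ratio,
               nrow(x$db$peptides) / sum(km$unique_counts))
  expect_gt(s$reduction_ratio, 0)
  expect_lte(s$reduction_ratio, 1)

  rep <- build_report(x$db)
  expect_named(rep, c("key", "value"))
  expect_equal(as.numeric(rep$value[rep$key == "n_peptides"]),
               nrow(x$db$peptides))
  expect_output(print(x$db), "Targeted peptide database")
})

test_that("contaminant k-mers are added unfiltered and counted exactly", {
  cont <- random_proteins(3, c(40, 60), seed = 91, prefix = "CON")
  cont$is_contaminant <- TRUE
  x <- small_build(contaminants = cont, include_contaminant_kmers = TRUE)
  ck <- enumerate_kmers(cont)
  in_db <- x$db$peptides[grepl("contaminant", x$db$peptides$provenance), ]
  expect_setequal(in_db$peptide, ck$peptides$peptide)
  expect_equal(nrow(in_db), nrow(ck$peptides))

  # off by default
  x0 <- small_build(contaminants = cont)
  expect_false(any(grepl("contaminant", x0$db$peptides$provenance)))
})

test_that("degenerate first-round sets are rejected or warned about", {
  prot <- random_proteins(10, c(60, 100), seed = 3)
  expect_error(suppressWarnings(
    build_targeted_database(c("SHORT", "TOOLONGPEPTIDEXX"), prot)),
    "no first-round peptides")
  d <- sample_motif_peptides(motif_LV(), 40, 0, seed = 5)$peptide
  w <- capture_warnings(
    build_targeted_database(unique(d), plant_proteome(unique(d), 5, seed = 5),
                            config = build_config(
                              gibbs = gibbs_config(cluster_range = 1,
                                                   n_seeds = 1,
                                                   rng_seed = 5))))
  expect_true(any(grepl("poorly determined", w)))
})
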