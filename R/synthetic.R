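# Ground-truth generators (motif peptide sets, planted proteomes) and a
# minimal target-decoy search simulation of the sensitivity mechanism:
# a smaller database means less random competition per spectrum, hence more
# identifications at a fixed FDR.

#' Specify a positional peptide motif
#'
#' Anchor positions (typically P2 and the C-terminus for HLA class I
#' ligands) concentrate probability mass on one residue; the remaining mass,
#' and all non-anchor positions, follow the background distribution
#' (remainder spread over the other residues proportionally to it).
#'
#' @param length Peptide length (default 9).
#' @param anchors Named list: names are 1-based positions, values are
#'   `c(residue, mass)` with mass defaulting to 0.7, e.g.
#'   `list("2" = c("L", 0.7), "9" = c("V", 0.7))`.
#' @param background Named 20-vector; `NULL` for uniform.
#' @return An object of class `motif_spec` with the L x 20 positional pmf.
#' @export
motif_spec <- function(length = 9L,
                       anchors = list("2" = c("L", 0.7), "9" = c("V", 0.7)),
                       background = NULL) {
  length <- as.integer(length)
  if (is.null(background)) background <- uniform_background()
  stopifnot(all(abs(sum(background) - 1) < 1e-9))
  pmf <- matrix(background, length, 20, byrow = TRUE,
                dimnames = list(NULL, AA20))
  for (ps in names(anchors)) {
    i <- as.integer(ps)
    stopifnot(i >= 1L, i <= length)
    a <- anchors[[ps]]
    res <- as.character(a[1])
    mass <- if (length(a) >= 2) as.numeric(a[2]) else 0.7
    stopifnot(res %in% AA20, mass > 0, mass <= 1)
    j <- match(res, AA20)
    row <- background * (1 - mass) / (1 - background[j])
    row[j] <- mass
    pmf[i, ] <- row / sum(row)
  }
  structure(list(pmf = pmf, length = length, anchors = anchors,
                 background = background),
            class = "motif_spec")
}

#' Sample peptides from a motif, mixed with background peptides
#'
#' Draws `round(n * (1 - noise_fraction))` peptides position-wise from the
#' motif pmf and the remainder i.i.d. from the background, with true labels.
#'
#' @param spec A [motif_spec()].
#' @param n Total number of peptides.
#' @param noise_fraction Fraction of background peptides (default 0).
#' @param seed Integer seed; sampling is deterministic per seed.
#' @return Data frame `peptide`, `label` (`"motif"` or `"background"`).
#' @export
sample_motif_peptides <- function(spec, n, noise_fraction = 0, seed = 1L) {
  stopifnot(inherits(spec, "motif_spec"), n >= 1)
  n_motif <- round(n * (1 - noise_fraction))
  n_bg <- n - n_motif
  with_seed(seed, {
    draw <- function(nn, pmf_rows) {
      if (nn == 0) return(character())
      mat <- vapply(seq_len(spec$length), function(i)
        sample(AA20, nn, replace = TRUE, prob = pmf_rows[i, ]),
        character(nn))
      if (nn == 1) mat <- matrix(mat, nrow = 1)
      apply(mat, 1, paste, collapse = "")
    }
    bg_rows <- matrix(spec$background, spec$length, 20, byrow = TRUE)
    data.frame(peptide = c(draw(n_motif, spec$pmf), draw(n_bg, bg_rows)),
               label = rep(c("motif", "background"), c(n_motif, n_bg)),
               stringsAsFactors = FALSE)
  })
}

#' Random background proteins
#'
#' @param n Number of proteins.
#' @param length_range Inclusive range of protein lengths.
#' @param background Residue distribution; `NULL` for uniform.
#' @param seed Integer seed.
#' @param prefix Id prefix.
#' @return Data frame of protein records as from [read_protein_fasta()].
#' @export
random_proteins <- function(n, length_range = c(20L, 500L),
                            background = NULL, seed = 1L,
                            prefix = "RND") {
  if (is.null(background)) background <- uniform_background()
  with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(AA20, L, replace = TRUE, prob = background),
            collapse = ""), "")
    data.frame(id = sprintf("%s%05d", prefix, seq_len(n)),
               description = "synthetic background protein",
               sequence = seqs, is_contaminant = FALSE,
               stringsAsFactors = FALSE)
  })
}

#' Plant peptides verbatim into a synthetic proteome
#'
#' Embeds each planted peptide at a random offset inside a background-sampled
#' host protein and appends filler proteins, guaranteeing that every planted
#' peptide is recoverable by [enumerate_kmers()] at its length.
#'
#' @param planted_peptides Character vector of peptides to embed.
#' @param n_filler_proteins Number of background-only proteins.
#' @param filler_length_range Protein length range (default 100-400,
#'   a realistic span for a toy proteome).
#' @param background Residue distribution; `NULL` for uniform.
#' @param seed Integer seed.
#' @return Data frame of protein records; hosts are ids `HOSTnnnnn`, fillers
#'   `FILLnnnnn`.
#' @export
plant_proteome <- function(planted_peptides, n_filler_proteins,
                           filler_length_range = c(100L, 400L),
                           background = NULL, seed = 1L) {
  planted_peptides <- as.character(planted_peptides)
  stopifnot(length(planted_peptides) >= 1L)
  if (is.null(background)) background <- uniform_background()
  with_seed(seed, {
    hosts <- vapply(planted_peptides, function(p) {
      k <- nchar(p)
      L <- max(k, sample(filler_length_range[1]:filler_length_range[2], 1))
      s <- paste(sample(AA20, L, replace = TRUE, prob = background),
                 collapse = "")
      off <- sample.int(L - k + 1L, 1)
      paste0(substr(s, 1, off - 1L), p, substr(s, off + k, L))
    }, "", USE.NAMES = FALSE)
    fillers <- if (n_filler_proteins > 0) {
      lens <- sample(filler_length_range[1]:filler_length_range[2],
                     n_filler_proteins, replace = TRUE)
      vapply(lens, function(L)
        paste(sample(AA20, L, replace = TRUE, prob = background),
              collapse = ""), "")
    } else character()
    out <- data.frame(
      id = c(sprintf("HOST%05d", seq_along(hosts)),
             if (length(fillers)) sprintf("FILL%05d", seq_along(fillers))),
      description = rep(c("synthetic host protein",
                          "synthetic filler protein"),
                        c(length(hosts), length(fillers))),
      sequence = c(hosts, fillers),
      is_contaminant = FALSE, stringsAsFactors = FALSE)
    embedded <- mapply(grepl, planted_peptides, out$sequence[seq_along(hosts)],
                       MoreArgs = list(fixed = TRUE))
    stopifnot(all(embedded))  # recoverability guarantee
    out
  })
}

#' Configuration of the toy target-decoy search simulation
#'
#' Spectra are score draws, not fragment spectra: a spectrum matched to its
#' true peptide scores `Normal(mu_true, sigma)`; a spectrum whose true
#' peptide is absent from the database gets the maximum of `k` random-match
#' draws `Normal(mu_random, sigma)`, where `k = ceiling(competition_rate *
#' |database|)` grows with database size -- the simplest competition model
#' that produces the sensitivity mechanism.  Decoys are a same-size
#' reversed-peptide set scored with random-match draws.
#'
#' @param n_true_spectra Number of spectra, one true peptide each
#'   (default 2000).
#' @param mu_true,mu_random,sigma Score-model parameters (defaults 2, 0, 1:
#'   true matches sit two standard deviations above random matches).
#' @param fdr_level Accepted FDR (default 0.01); must lie in (0, 0.5).
#' @param competition_rate Random-match draws per database peptide
#'   (default 1e-3).
#' @param rng_seed Integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_true_spectra = 2000L, mu_true = 2, mu_random = 0,
                       sigma = 1, fdr_level = 0.01,
                       competition_rate = 1e-3, rng_seed = 1L) {
  stopifnot(mu_true > mu_random, fdr_level > 0, fdr_level <= 1)
  structure(list(n_true_spectra = as.integer(n_true_spectra),
                 mu_true = mu_true, mu_random = mu_random, sigma = sigma,
                 fdr_level = fdr_level, competition_rate = competition_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

# Identifications at the configured FDR for one database, given membership
# of each spectrum's true peptide.  Maximum of k normal draws is sampled
# exactly through the inverse CDF of the maximum.  The RNG is seeded
# identically per call so that equal databases give equal counts.
count_identifications <- function(present, db_size, sim) {
  n <- sim$n_true_spectra
  k <- max(1L, as.integer(ceiling(sim$competition_rate * db_size)))
  with_seed(sim$rng_seed, {
    true_scores <- stats::rnorm(n, sim$mu_true, sim$sigma)
    comp_u <- stats::runif(n)
    decoy_u <- stats::runif(n)
    max_of_k <- function(u) sim$mu_random +
      sim$sigma * stats::qnorm(u^(1 / k))
    target <- ifelse(present, true_scores, max_of_k(comp_u))
    decoy <- max_of_k(decoy_u)
    ts <- sort(target, decreasing = TRUE)
    d_ge <- length(decoy) - findInterval(ts, sort(decoy)) # decoys >= cutoff
    ok <- which(d_ge / seq_len(n) <= sim$fdr_level)
    if (length(ok) == 0L) 0L else max(ok)
  })
}

#' Simulate the sensitivity gain of a targeted second-round search
#'
#' Scores the same set of true-peptide spectra against a full and a targeted
#' database under the toy competition model of [sim_config()] and counts
#' identifications at the configured FDR for each, using the same random
#' stream for both databases.
#'
#' @param true_peptides Peptides generating the spectra (recycled over
#'   spectra); must all be in `full_db`.
#' @param full_db,targeted_db Character vectors of database peptides.
#' @param sim A [sim_config()].
#' @return List with `counts` (named: `full`, `targeted`), `db_sizes`, `k`
#'   (competition draws per database) and `config`.
#' @export
simulate_two_round_gain <- function(true_peptides, full_db, targeted_db,
                                    sim = sim_config()) {
  stopifnot(inherits(sim, "sim_config"))
  true_peptides <- as.character(true_peptides)
  if (!all(true_peptides %in% full_db))
    stop("true peptides must be contained in the full database",
         call. = FALSE)
  missing_t <- sum(!(true_peptides %in% targeted_db))
  if (missing_t > 0)
    message(missing_t, " true peptide(s) absent from the targeted database")
  idx <- rep(seq_along(true_peptides),
             length.out = sim$n_true_spectra)
  spectra <- true_peptides[idx]
  counts <- c(
    full = count_identifications(spectra %in% full_db, length(full_db), sim),
    targeted = count_identifications(spectra %in% targeted_db,
                                     length(targeted_db), sim))
  list(counts = counts,
       db_sizes = c(full = length(full_db), targeted = length(targeted_db)),
       k = c(full = max(1L, as.integer(ceiling(sim$competition_rate *
                                                 length(full_db)))),
             targeted = max(1L, as.integer(ceiling(sim$competition_rate *
                                                     length(targeted_db))))),
       config = sim)
}
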