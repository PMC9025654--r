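# Orchestration: cluster first-round hits, train PSSMs, score the unspecific
# k-mer space and compose the targeted database (always a superset of the
# first-round peptides, so the second-round search keeps a global FDR).

#' Build configuration for a targeted database
#'
#' @param digest A [digest_config()].
#' @param gibbs A [gibbs_config()].
#' @param omega PSSM pseudocount weight (default 0.1).
#' @param threshold Motif-score cutoff for proteome k-mers (default 0.3,
#'   strict inequality).
#' @param min_train Minimum (cluster, length) training set for a
#'   length-specific PSSM (default 20).
#' @param min_total_hits Warn when fewer first-round hits than this survive
#'   length filtering (default 500); with few hits the trained motifs can be
#'   unreliable.
#' @param include_contaminant_kmers Add contaminant-protein k-mers
#'   (unfiltered, tagged `contaminant`) so post-search contaminant
#'   elimination stays possible (default `FALSE`).
#' @param rng_seed Integer seed; the build is deterministic given it.
#' @return An object of class `build_config`.
#' @export
build_config <- function(digest = digest_config(), gibbs = gibbs_config(),
                         omega = 0.1, threshold = 0.3, min_train = 20L,
                         min_total_hits = 500L,
                         include_contaminant_kmers = FALSE,
                         rng_seed = 1L) {
  stopifnot(inherits(digest, "digest_config"), inherits(gibbs, "gibbs_config"),
            is.finite(threshold), min_train >= 1L)
  structure(list(digest = digest, gibbs = gibbs, omega = omega,
                 threshold = threshold, min_train = as.integer(min_train),
                 min_total_hits = as.integer(min_total_hits),
                 include_contaminant_kmers = isTRUE(include_contaminant_kmers),
                 rng_seed = as.integer(rng_seed)),
            class = "build_config")
}

#' Build a motif-targeted peptide database
#'
#' Runs the full pipeline: restrict first-round hits to the configured
#' lengths, fit a [motif_model()], enumerate the unspecific k-mer space of
#' the proteome, keep k-mers with motif score strictly above the threshold,
#' and union them with every first-round peptide (which is injected
#' regardless of its motif score or presence in the proteome -- that is what
#' keeps the second-round FDR global).  Contaminant k-mers can be added
#' unfiltered with their own provenance tag.
#'
#' @param first_round Data frame from [read_peptide_hits()] or character
#'   vector of first-round peptide sequences.
#' @param proteome Data frame from [read_protein_fasta()] or character
#'   vector of protein sequences.
#' @param contaminants Optional contaminant protein records.
#' @param config A [build_config()].
#' @return An object of class `targeted_db`: list with `peptides` (data
#'   frame `peptide`, `length`, `provenance`, `best_score`, `best_model`),
#'   `summary` (counts, full-space sizes, reduction ratio) and `model`.
#' @export
build_targeted_database <- function(first_round, proteome,
                                    contaminants = NULL,
                                    config = build_config()) {
  stopifnot(inherits(config, "build_config"))
  if (is.data.frame(first_round)) first_round <- first_round$sequence
  first_round <- unique(as.character(first_round))
  dg <- config$digest
  in_len <- nchar(first_round) >= dg$min_length &
            nchar(first_round) <= dg$max_length
  if (any(!in_len))
    message(sum(!in_len), " first-round peptide(s) outside lengths ",
            dg$min_length, "-", dg$max_length, " excluded")
  hits <- first_round[in_len]
  if (length(hits) == 0L)
    stop("no first-round peptides within configured lengths", call. = FALSE)
  if (length(hits) < config$min_total_hits)
    warning("only ", length(hits), " first-round peptides (< ",
            config$min_total_hits, "); motifs may be poorly determined",
            call. = FALSE)

  bg <- background_frequencies(proteome)
  gb <- config$gibbs
  gb$rng_seed <- derive_seed(config$rng_seed, 1L)
  model <- motif_model(hits, background = bg, gibbs = gb,
                       omega = config$omega, min_train = config$min_train)

  kmers <- enumerate_kmers(proteome, dg)
  pred <- predict(model, kmers, threshold = config$threshold)
  motif_df <- pred[pred$pass, c("peptide", "length", "score", "model")]
  names(motif_df)[3:4] <- c("best_score", "best_model")

  fr_pred <- predict(model, hits, threshold = config$threshold)
  fr_df <- fr_pred[, c("peptide", "length", "score", "model")]
  names(fr_df)[3:4] <- c("best_score", "best_model")

  prov <- c(rep("motif", nrow(motif_df)), rep("first_round", nrow(fr_df)))
  db <- rbind(motif_df, fr_df)
  db$provenance <- prov

  if (!is.null(contaminants) && config$include_contaminant_kmers) {
    ck <- enumerate_kmers(contaminants, dg)
    cdf <- data.frame(peptide = ck$peptides$peptide,
                      length = ck$peptides$length,
                      best_score = NA_real_, best_model = NA_character_,
                      provenance = "contaminant", stringsAsFactors = FALSE)
    db <- rbind(db, cdf)
  }

  # merge duplicates: union of provenance tags in canonical order, best score
  prov_merge <- vapply(split(db$provenance, db$peptide), function(p) {
    tags <- intersect(c("first_round", "motif", "contaminant"), unique(p))
    paste(tags, collapse = ";")
  }, "")
  ord <- order(is.na(db$best_score), -ifelse(is.na(db$best_score), 0,
                                             db$best_score))
  db <- db[ord, , drop = FALSE]
  db <- db[!duplicated(db$peptide), , drop = FALSE]
  db$provenance <- unname(prov_merge[db$peptide])
  db <- db[order(db$peptide, method = "radix"),
           c("peptide", "length", "provenance", "best_score", "best_model")]
  rownames(db) <- NULL

  contam_kmers <- if (!is.null(contaminants))
    enumerate_kmers(contaminants, dg)$unique_counts else NULL
  full_unique <- sum(kmers$unique_counts)
  summary <- list(
    n_peptides = nrow(db),
    per_length = table(factor(db$length,
                              levels = dg$min_length:dg$max_length)),
    provenance_counts = {
      tags <- unlist(strsplit(db$provenance, ";"))
      table(factor(tags, levels = c("motif", "first_round", "contaminant")))
    },
    n_first_round = length(hits),
    full_space_unique = kmers$unique_counts,
    full_space_windows = kmers$window_counts,
    contaminant_space_unique = contam_kmers,
    reduction_ratio = nrow(db) / full_unique,
    selected_K = model$clustering$selected_K,
    cluster_sizes = model$clustering$solutions[[
      as.character(model$clustering$selected_K)]]$cluster_sizes,
    trash_count = model$clustering$solutions[[
      as.character(model$clustering$selected_K)]]$trash_count,
    threshold = config$threshold)

  structure(list(peptides = db, summary = summary, model = model,
                 config = config),
            class = "targeted_db")
}

#' @export
print.targeted_db <- function(x, ...) {
  s <- x$summary
  cat("Targeted peptide database:", s$n_peptides, "peptides\n")
  cat(sprintf("  %.3f%% of the %d-peptide unspecific space\n",
              100 * s$reduction_ratio, sum(s$full_space_unique)))
  cat("  provenance:",
      paste(sprintf("%s=%d", names(s$provenance_counts),
                    as.integer(s$provenance_counts)), collapse = " "), "\n")
  cat("  motif clusters:", s$selected_K,
      "(sizes", paste(s$cluster_sizes, collapse = ", "),
      "; trash", s$trash_count, ")\n")
  invisible(x)
}

#' @export
summary.targeted_db <- function(object, ...) build_report(object)

#' Flat machine-readable report of a targeted database build
#'
#' @param db A [build_targeted_database()] result.
#' @return A data frame of `key` / `value` pairs (per-length counts,
#'   full-space sizes, reduction ratio, cluster statistics), printable and
#'   writable as TSV.
#' @export
build_report <- function(db) {
  stopifnot(inherits(db, "targeted_db"))
  s <- db$summary
  kv <- c(n_peptides = s$n_peptides,
          stats::setNames(as.integer(s$per_length),
                          paste0("n_length_", names(s$per_length))),
          stats::setNames(as.integer(s$provenance_counts),
                          paste0("n_", names(s$provenance_counts))),
          n_first_round_input = s$n_first_round,
          stats::setNames(as.integer(s$full_space_unique),
                          paste0("full_space_unique_",
                                 names(s$full_space_unique))),
          full_space_unique_total = sum(s$full_space_unique),
          reduction_ratio = s$reduction_ratio,
          selected_K = s$selected_K,
          stats::setNames(as.integer(s$cluster_sizes),
                          paste0("cluster_size_",
                                 seq_along(s$cluster_sizes))),
          trash_count = s$trash_count,
          threshold = s$threshold)
  data.frame(key = names(kv), value = unname(kv), stringsAsFactors = FALSE)
}
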