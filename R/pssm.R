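# Position-specific scoring matrices: background composition, training with
# pseudocounts, peptide scoring, k-mer filtering and a tab-separated matrix
# serialization.

#' Residue background frequencies of a protein database
#'
#' Counts residues over all sequences (ambiguity codes excluded), normalizes
#' to sum 1, floors every entry at 1e-6 and renormalizes so that log-odds
#' against the background are always finite.
#'
#' @param proteins Data frame from [read_protein_fasta()] or character vector
#'   of sequences.
#' @return Named numeric 20-vector in [aa_alphabet()] order, summing to 1.
#' @export
background_frequencies <- function(proteins) {
  seqs <- if (is.data.frame(proteins)) proteins$sequence else proteins
  if (length(seqs) == 0L || all(!nzchar(seqs)))
    stop("no sequences", call. = FALSE)
  chars <- strsplit(paste(toupper(seqs), collapse = ""), "")[[1]]
  counts <- table(factor(chars, levels = AA20))
  if (sum(counts) == 0L) stop("no standard residues in sequences",
                              call. = FALSE)
  b <- as.numeric(counts) / sum(counts)
  b[b < 1e-6] <- 1e-6
  b <- b / sum(b)
  names(b) <- AA20
  b
}

#' Train a position-specific scoring matrix
#'
#' Counts residues per position over an equal-length peptide set, smooths the
#' empirical frequencies `F` with background pseudocounts,
#' `f = (F + omega * B) / (1 + omega)`, and converts to scores.  Under the
#' default `scoring_form = "log_odds"` the matrix entries are
#' `P = log2(f / B)`, so a peptide drawn from the background scores about 0
#' and motif-matching peptides score positive.  The alternative
#' `"as_printed"` form, `P = log2(F + omega * B)`, sums log-frequencies and is
#' retained for comparison (all its entries are negative).
#'
#' @param peptides Character vector of equal-length training peptides
#'   (standard residues only).
#' @param background Named 20-vector from [background_frequencies()];
#'   `NULL` for a uniform background.
#' @param omega Pseudocount weight (default 0.1).
#' @param scoring_form `"log_odds"` (default) or `"as_printed"`.
#' @param cluster_id Optional integer tag recording the source motif cluster.
#' @return An object of class `pssm`: list with `matrix` (L x 20 scores,
#'   columns in [aa_alphabet()] order), `freq` (smoothed frequencies),
#'   `background`, `omega`, `n_train`, `length`, `scoring_form`, `cluster_id`.
#' @export
train_pssm <- function(peptides, background = NULL, omega = 0.1,
                       scoring_form = c("log_odds", "as_printed"),
                       cluster_id = NA_integer_) {
  scoring_form <- match.arg(scoring_form)
  if (length(peptides) < 1L) stop("no training peptides", call. = FALSE)
  lens <- unique(nchar(peptides))
  if (length(lens) != 1L)
    stop("training peptides have mixed lengths: ",
         paste(sort(lens), collapse = ", "), call. = FALSE)
  L <- lens
  if (is.null(background)) background <- uniform_background()
  stopifnot(length(background) == 20L, all(background > 0))
  if (omega <= 0) stop("omega must be positive", call. = FALSE)

  enc <- aa_encode(peptides)
  counts <- matrix(0L, L, 20, dimnames = list(NULL, AA20))
  for (i in seq_len(L)) counts[i, ] <- tabulate(enc[, i], nbins = 20)
  n <- length(peptides)
  F_ai <- counts / n
  B <- matrix(background, L, 20, byrow = TRUE)
  f_smooth <- (F_ai + omega * B) / (1 + omega)
  P <- switch(scoring_form,
              log_odds = log2(f_smooth / B),
              as_printed = log2(F_ai + omega * B))
  structure(list(matrix = P, freq = f_smooth, counts = counts,
                 background = background, omega = omega, n_train = n,
                 length = L, scoring_form = scoring_form,
                 cluster_id = cluster_id),
            class = "pssm")
}

#' Motif score of peptides under a PSSM
#'
#' The motif score is the sum over positions of the matrix entry of the
#' observed residue -- no length normalization.  Vectorized over peptides.
#'
#' @param pssm A [train_pssm()] object.
#' @param peptide Character vector of peptides, each of length `pssm$length`,
#'   standard residues only.
#' @return Numeric vector of motif scores.
#' @export
score_peptide <- function(pssm, peptide) {
  stopifnot(inherits(pssm, "pssm"))
  if (length(peptide) == 0L) return(numeric())
  if (any(nchar(peptide) != pssm$length))
    stop("peptide length must equal PSSM length ", pssm$length,
         call. = FALSE)
  enc <- aa_encode(peptide)  # errors on ambiguity codes
  L <- pssm$length
  idx <- cbind(rep(seq_len(L), each = length(peptide)), as.vector(enc))
  scores <- matrix(pssm$matrix[idx], nrow = length(peptide))
  rowSums(scores)
}

# Best score of peptides longer than the PSSM core, maximizing over legal
# deletion placements (terminal residues always kept).  Used when a length
# has no length-specific model and must be scored through the 9-mer core.
score_peptide_aligned <- function(pssm, peptide, max_deletions = 2L) {
  L <- unique(nchar(peptide))
  stopifnot(length(L) == 1L)
  if (L == pssm$length) return(score_peptide(pssm, peptide))
  keep_sets <- alignments_for_length(L, pssm$length, max_deletions)
  best <- rep(-Inf, length(peptide))
  for (r in seq_len(nrow(keep_sets))) {
    cores <- vapply(peptide, function(p)
      paste(strsplit(p, "")[[1]][keep_sets[r, ]], collapse = ""), "",
      USE.NAMES = FALSE)
    best <- pmax(best, score_peptide(pssm, cores))
  }
  best
}

#' Filter a k-mer set at a motif-score threshold
#'
#' A peptide passes iff the maximum of its scores over all same-length PSSMs
#' is strictly greater than `threshold`.  Lengths for which no PSSM exists
#' are dropped with a warning.
#'
#' @param kmers A [enumerate_kmers()] result or character vector of peptides.
#' @param pssms A single [train_pssm()] object or a list of them.
#' @param threshold Motif-score cutoff (default 0.3); strict inequality.
#' @return Data frame `peptide`, `length`, `best_score`, `best_model` for the
#'   passing peptides.
#' @export
filter_kmers <- function(kmers, pssms, threshold = 0.3) {
  peps <- if (inherits(kmers, "kmer_set")) kmers$peptides$peptide
          else as.character(kmers)
  if (inherits(pssms, "pssm")) pssms <- list(pssms)
  stopifnot(all(vapply(pssms, inherits, logical(1), "pssm")))
  scored <- score_against_models(peps, pssms)
  if (all(is.na(scored$best_score)))
    stop("no PSSM matches any k-mer length", call. = FALSE)
  pass <- !is.na(scored$best_score) & scored$best_score > threshold
  out <- scored[pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Score peptides of mixed length against a model list; NA where no model of
# the peptide's length exists.  Returns peptide/length/best_score/best_model.
score_against_models <- function(peptides, pssms) {
  model_lens <- vapply(pssms, `[[`, integer(1) + 0, "length")
  model_ids <- vapply(seq_along(pssms), function(i) {
    p <- pssms[[i]]
    if (!is.na(p$cluster_id)) sprintf("c%d_L%d", p$cluster_id, p$length)
    else sprintf("m%d_L%d", i, p$length)
  }, "")
  lens <- nchar(peptides)
  best_score <- rep(NA_real_, length(peptides))
  best_model <- rep(NA_character_, length(peptides))
  dropped <- setdiff(unique(lens), model_lens)
  if (length(dropped))
    warning("no PSSM for length(s) ", paste(sort(dropped), collapse = ", "),
            "; those peptides are unscored", call. = FALSE)
  for (L in intersect(unique(lens), model_lens)) {
    sel <- lens == L
    for (mi in which(model_lens == L)) {
      s <- score_peptide(pssms[[mi]], peptides[sel])
      upd <- is.na(best_score[sel]) | s > best_score[sel]
      bs <- best_score[sel]; bm <- best_model[sel]
      bs[upd] <- s[upd]; bm[upd] <- model_ids[mi]
      best_score[sel] <- bs; best_model[sel] <- bm
    }
  }
  data.frame(peptide = peptides, length = lens, best_score = best_score,
             best_model = best_model, stringsAsFactors = FALSE)
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM (%s): length %d, trained on %d peptides, omega %.3g\n",
              x$scoring_form, x$length, x$n_train, x$omega))
  if (!is.na(x$cluster_id)) cat("  cluster:", x$cluster_id, "\n")
  cons <- AA20[apply(x$matrix, 1, which.max)]
  cat("  consensus:", paste(cons, collapse = ""), "\n")
  invisible(x)
}

#' @export
coef.pssm <- function(object, ...) object$matrix

#' @export
plot.pssm <- function(x, ...) {
  ic <- rowSums(x$freq * log2(x$freq /
                                matrix(x$background, x$length, 20,
                                       byrow = TRUE)))
  graphics::barplot(ic, names.arg = paste0("P", seq_len(x$length)),
                    ylab = "information content (bits)",
                    main = sprintf("PSSM cluster %s (n = %d)",
                                   x$cluster_id, x$n_train), ...)
  invisible(x)
}

#' Serialize a PSSM to a tab-separated matrix file
#'
#' Rows are positions, columns the residues in [aa_alphabet()] order; `#`
#' header lines carry cluster id, length, omega, n_train, scoring form and
#' the background vector.  Values use 17 significant digits so that
#' [read_pssm()] round-trips bit-exactly.
#'
#' @param pssm A [train_pssm()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pssm <- function(pssm, path) {
  stopifnot(inherits(pssm, "pssm"))
  num <- function(v) paste(sprintf("%.17g", v), collapse = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    sprintf("# cluster_id\t%s", pssm$cluster_id),
    sprintf("# length\t%d", pssm$length),
    sprintf("# omega\t%s", sprintf("%.17g", pssm$omega)),
    sprintf("# n_train\t%d", pssm$n_train),
    sprintf("# scoring_form\t%s", pssm$scoring_form),
    sprintf("# background\t%s", num(pssm$background)),
    paste(c("pos", AA20), collapse = "\t"),
    vapply(seq_len(pssm$length), function(i)
      paste(c(i, sprintf("%.17g", pssm$matrix[i, ])), collapse = "\t"), "")
  ), con, sep = "\n")
  invisible(path)
}

#' Read a PSSM written by [write_pssm()]
#'
#' @param path Path to a serialized PSSM.
#' @return A `pssm` object (without training counts).
#' @export
read_pssm <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    parts <- strsplit(sub("^# ", "", ml), "\t")[[1]]
    meta[[parts[1]]] <- parts[-1]
  }
  body <- lines[!grepl("^#", lines)]
  header <- strsplit(body[1], "\t")[[1]]
  stopifnot(identical(header[-1], AA20))
  rows <- strsplit(body[-1], "\t")
  L <- as.integer(meta$length)
  mat <- matrix(NA_real_, L, 20, dimnames = list(NULL, AA20))
  for (r in rows) mat[as.integer(r[1]), ] <- as.numeric(r[-1])
  bg <- stats::setNames(as.numeric(meta$background), AA20)
  B <- matrix(bg, L, 20, byrow = TRUE)
  form <- meta$scoring_form
  freq <- if (identical(form, "log_odds")) 2^mat * B else NULL
  structure(list(matrix = mat, freq = freq, counts = NULL,
                 background = bg,
                 omega = as.numeric(meta$omega),
                 n_train = as.integer(meta$n_train),
                 length = L, scoring_form = form,
                 cluster_id = suppressWarnings(as.integer(meta$cluster_id))),
            class = "pssm")
}
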