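# The central fitted object: motif clustering plus per-(cluster, length)
# PSSMs, with predict/coef/plot/simulate methods.

#' Fit a motif model to first-round peptide identifications
#'
#' The core fitting function of the package.  Peptides identified in a
#' first-round unspecific search are (i) deconvoluted into motif clusters by
#' [cluster_peptides()] and (ii) used to train PSSMs: one core model per
#' cluster from the aligned length-9 cores of all retained cluster members,
#' and one length-specific model per (cluster, length) with at least
#' `min_train` peptides of that exact length.  Trash-cluster peptides are
#' excluded from training.
#'
#' [predict.motif_model()] scores arbitrary peptides: lengths with a
#' length-specific model use it; other lengths within the deletion budget
#' fall back to the cluster core models, maximizing over legal deletion
#' placements (flagged `core_aligned` in the output).
#'
#' @param peptides Character vector of first-round peptide sequences, or a
#'   data frame from [read_peptide_hits()].
#' @param background Named 20-vector from [background_frequencies()];
#'   `NULL` for uniform.
#' @param gibbs A [gibbs_config()].
#' @param omega Pseudocount weight for PSSM training (default 0.1).
#' @param min_train Minimum per-(cluster, length) training set size for a
#'   length-specific PSSM (default 20).
#' @param scoring_form Passed to [train_pssm()].
#' @return An object of class `motif_model`: list with `clustering`,
#'   `core_pssms`, `length_pssms`, `background`, `omega`, `min_train`,
#'   `n_train`, `lengths_modeled`.
#' @export
#' @examples
#' spec <- motif_spec(anchors = list("2" = c("L", 0.8), "9" = c("V", 0.8)))
#' peps <- sample_motif_peptides(spec, 60, seed = 1)$peptide
#' fit <- motif_model(peps, gibbs = gibbs_config(cluster_range = 1:2,
#'                                               n_seeds = 2))
#' fit
#' head(predict(fit, peps))
motif_model <- function(peptides, background = NULL,
                        gibbs = gibbs_config(), omega = 0.1,
                        min_train = 20L,
                        scoring_form = c("log_odds", "as_printed")) {
  scoring_form <- match.arg(scoring_form)
  if (is.data.frame(peptides)) peptides <- peptides$sequence
  peptides <- unique(as.character(peptides))
  if (is.null(background)) background <- uniform_background()

  clustering <- cluster_peptides(peptides, gibbs, background)
  ret <- retained_peptides(clustering)
  K <- clustering$selected_K

  core_pssms <- vector("list", K)
  length_pssms <- list()
  for (c in seq_len(K)) {
    grp <- ret$clusters[[c]]
    if (nrow(grp) == 0L) next
    cores <- vapply(seq_len(nrow(grp)), function(i)
      paste(strsplit(grp$peptide[i], "")[[1]][grp$alignment[[i]]],
            collapse = ""), "")
    core_pssms[[c]] <- train_pssm(cores, background, omega, scoring_form,
                                  cluster_id = c)
    for (L in sort(unique(nchar(grp$peptide)))) {
      sub <- grp$peptide[nchar(grp$peptide) == L]
      if (length(sub) >= min_train) {
        key <- sprintf("c%d_L%d", c, L)
        length_pssms[[key]] <- train_pssm(sub, background, omega,
                                          scoring_form, cluster_id = c)
      }
    }
  }
  core_pssms <- Filter(Negate(is.null), core_pssms)
  if (length(core_pssms) == 0L)
    stop("no cluster retained enough peptides to train a model",
         call. = FALSE)
  train_lengths <- sort(unique(nchar(unlist(lapply(ret$clusters,
                                                   `[[`, "peptide")))))

  structure(list(clustering = clustering,
                 core_pssms = core_pssms,
                 length_pssms = length_pssms,
                 background = background,
                 omega = omega,
                 min_train = as.integer(min_train),
                 scoring_form = scoring_form,
                 n_train = length(peptides),
                 train_lengths = train_lengths,
                 lengths_modeled = sort(unique(c(
                   gibbs$motif_length,
                   as.integer(sub(".*_L", "", names(length_pssms))))))),
            class = "motif_model")
}

#' Score peptides under a fitted motif model
#'
#' Each peptide receives the maximum motif score over the model's PSSMs of
#' its length.  Lengths that occur among the training hits but have no
#' length-specific PSSM (fewer than `min_train` peptides) are scored through
#' the cluster core models, maximizing over all legal deletion placements.
#' Lengths absent from the training hits carry no motif evidence and are
#' unscored (`NA`) with a warning, as are lengths outside the deletion
#' budget.
#'
#' @param object A [motif_model()].
#' @param newdata Character vector of peptides, or a `kmer_set`.
#' @param threshold Motif-score cutoff used for the `pass` column
#'   (default 0.3, strict inequality).
#' @param ... Unused.
#' @return Data frame `peptide`, `length`, `score`, `model`, `method`
#'   (`"length_pssm"` or `"core_aligned"`), `pass`.
#' @export
predict.motif_model <- function(object, newdata, threshold = 0.3, ...) {
  peps <- if (inherits(newdata, "kmer_set")) newdata$peptides$peptide
          else as.character(newdata)
  cfg <- object$clustering$config
  m <- cfg$motif_length
  lens <- nchar(peps)
  score <- rep(NA_real_, length(peps))
  model <- rep(NA_character_, length(peps))
  method <- rep(NA_character_, length(peps))

  len_model_lens <- vapply(object$length_pssms, `[[`, numeric(1), "length")
  for (L in sort(unique(lens))) {
    sel <- which(lens == L)
    keys <- names(object$length_pssms)[len_model_lens == L]
    if (length(keys)) {
      for (key in keys) {
        s <- score_peptide(object$length_pssms[[key]], peps[sel])
        upd <- is.na(score[sel]) | s > score[sel]
        score[sel][upd] <- s[upd]
        model[sel][upd] <- key
      }
      method[sel] <- "length_pssm"
    } else if (L %in% object$train_lengths &&
               L >= m && L <= m + cfg$max_deletions) {
      # length seen among training hits but with too few peptides for its
      # own PSSM: score through the cluster cores over legal deletions
      for (ci in seq_along(object$core_pssms)) {
        p <- object$core_pssms[[ci]]
        s <- score_peptide_aligned(p, peps[sel], cfg$max_deletions)
        upd <- is.na(score[sel]) | s > score[sel]
        score[sel][upd] <- s[upd]
        model[sel][upd] <- sprintf("c%d_core", p$cluster_id)
      }
      method[sel] <- "core_aligned"
    } else {
      warning("no model for peptide length ", L, "; left unscored",
              call. = FALSE)
    }
  }
  data.frame(peptide = peps, length = lens, score = score, model = model,
             method = method, pass = !is.na(score) & score > threshold,
             stringsAsFactors = FALSE)
}

#' @export
print.motif_model <- function(x, ...) {
  cat("Motif model:", x$n_train, "training peptides,",
      x$clustering$selected_K, "cluster(s)\n")
  sol <- x$clustering$solutions[[as.character(x$clustering$selected_K)]]
  cat("  cluster sizes:", paste(sol$cluster_sizes, collapse = ", "),
      " trash:", sol$trash_count, "\n")
  for (p in x$core_pssms) {
    cons <- paste(AA20[apply(p$matrix, 1, which.max)], collapse = "")
    cat(sprintf("  cluster %d core consensus: %s (n = %d)\n",
                p$cluster_id, cons, p$n_train))
  }
  if (length(x$length_pssms))
    cat("  length-specific PSSMs:",
        paste(names(x$length_pssms), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.motif_model <- function(object, ...) {
  out <- list(clustering = summary(object$clustering),
              n_train = object$n_train,
              omega = object$omega,
              scoring_form = object$scoring_form,
              length_models = names(object$length_pssms))
  class(out) <- "summary.motif_model"
  out
}

#' @export
print.summary.motif_model <- function(x, ...) {
  cat("Motif model fitted on", x$n_train, "peptides (omega =", x$omega,
      ", form =", x$scoring_form, ")\n")
  print(x$clustering)
  if (length(x$length_models))
    cat("length-specific PSSMs:", paste(x$length_models, collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
coef.motif_model <- function(object, ...) {
  c(lapply(stats::setNames(object$core_pssms,
                           sprintf("c%d_core",
                                   vapply(object$core_pssms, `[[`,
                                          integer(1), "cluster_id"))),
           `[[`, "matrix"),
    lapply(object$length_pssms, `[[`, "matrix"))
}

#' @export
plot.motif_model <- function(x, ...) {
  k <- length(x$core_pssms)
  old <- graphics::par(mfrow = c(1, k))
  on.exit(graphics::par(old))
  for (p in x$core_pssms) plot(p, ...)
  invisible(x)
}

#' Simulate peptides from a fitted motif model
#'
#' Draws core-length peptides from the smoothed per-cluster frequency
#' matrices, with cluster membership proportional to retained cluster sizes.
#'
#' @param object A [motif_model()].
#' @param nsim Number of replicate peptide sets (default 1).
#' @param seed Integer seed.
#' @param n Peptides per replicate (default: the training set size).
#' @param ... Unused.
#' @return A list of `nsim` character vectors.
#' @export
simulate.motif_model <- function(object, nsim = 1, seed = 1L,
                                 n = object$n_train, ...) {
  sizes <- vapply(object$core_pssms, `[[`, integer(1), "n_train")
  with_seed(seed, {
    lapply(seq_len(nsim), function(r) {
      cl <- sample.int(length(sizes), n, replace = TRUE, prob = sizes)
      vapply(cl, function(c) {
        f <- object$core_pssms[[c]]$freq
        paste(AA20[vapply(seq_len(nrow(f)), function(i)
          sample.int(20, 1, prob = f[i, ]), integer(1))], collapse = "")
      }, "")
    })
  })
}
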