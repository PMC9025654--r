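# Motif deconvolution of first-round peptides: a simulated-annealing Gibbs
# sampler over 1..K motif clusters with a length-9 core alignment and a trash
# cluster, selecting the cluster number by maximum KLD.

#' Gibbs clustering configuration
#'
#' Defaults reproduce the standard HLA class I parameterization: clusters
#' 1-6, motif length 9, up to 2 deletions and no insertions per peptide, 5
#' seeded initial conditions, inter-cluster similarity penalty 0.8, weight on
#' small clusters 5, trash cluster enabled at threshold 2, and 10 iterations
#' per sequence per temperature step.
#'
#' @param cluster_range Integer vector of cluster numbers to try (default
#'   `1:6`).
#' @param motif_length Core motif length (default 9).
#' @param max_deletions Maximum residues deleted from a peptide to reach the
#'   core (default 2): peptides of length `motif_length` to
#'   `motif_length + max_deletions` are alignable.
#' @param max_insertions Must be 0; insertions are not supported.
#' @param n_seeds Independent seeded initializations per cluster number
#'   (default 5).
#' @param lambda Penalty factor for inter-cluster motif similarity
#'   (default 0.8).
#' @param sigma Weight on small clusters (default 5): clusters smaller than
#'   `sigma * motif_length` peptides contribute proportionally less to the
#'   KLD objective.
#' @param use_trash Enable the outlier trash cluster (default `TRUE`).
#' @param trash_threshold Score below which a peptide is discarded to trash
#'   after the final sweep (default 2).  Interpreted on the scale given by
#'   `trash_score_scale`.
#' @param trash_score_scale `"total"` (default): `trash_threshold` is in bits
#'   summed over the core, the scale on which motif peptides typically score
#'   5-15 bits and background peptides near or below 0; or `"per_position"`:
#'   threshold on the per-position average.
#' @param iters_per_seq_per_temp Sweeps per temperature step (default 10).
#' @param temperature_schedule Descending positive temperatures; default a
#'   geometric ladder from 1.5 to 0.05 over 20 steps.
#' @param omega Pseudocount weight of the sampler's leave-one-out frequency
#'   model (default 0.5).  Stronger than the [train_pssm()] default because
#'   the sampler scores single peptides against small, shifting clusters:
#'   with weak smoothing an anchor mismatch is punished so hard that
#'   ordinary motif peptides fall below the trash threshold, and small
#'   overfit clusters inflate the selected K.
#' @param rng_seed Integer seed controlling every random choice.
#' @return An object of class `gibbs_config`.
#' @export
gibbs_config <- function(cluster_range = 1:6, motif_length = 9L,
                         max_deletions = 2L, max_insertions = 0L,
                         n_seeds = 5L, lambda = 0.8, sigma = 5,
                         use_trash = TRUE, trash_threshold = 2,
                         trash_score_scale = c("total", "per_position"),
                         iters_per_seq_per_temp = 10L,
                         temperature_schedule = NULL, omega = 0.5,
                         rng_seed = 1L) {
  trash_score_scale <- match.arg(trash_score_scale)
  cluster_range <- sort(unique(as.integer(cluster_range)))
  if (any(cluster_range < 1L)) stop("cluster_range must be >= 1",
                                    call. = FALSE)
  if (as.integer(max_insertions) != 0L)
    stop("insertions are not supported (max_insertions must be 0)",
         call. = FALSE)
  if (is.null(temperature_schedule))
    temperature_schedule <- 1.5 * (0.05 / 1.5)^(seq(0, 1, length.out = 20))
  if (any(diff(temperature_schedule) > 0) || any(temperature_schedule <= 0))
    stop("temperature_schedule must be descending and positive",
         call. = FALSE)
  structure(list(cluster_range = cluster_range,
                 motif_length = as.integer(motif_length),
                 max_deletions = as.integer(max_deletions),
                 max_insertions = 0L,
                 n_seeds = as.integer(n_seeds),
                 lambda = lambda, sigma = sigma,
                 use_trash = isTRUE(use_trash),
                 trash_threshold = trash_threshold,
                 trash_score_scale = trash_score_scale,
                 iters_per_seq_per_temp = as.integer(iters_per_seq_per_temp),
                 temperature_schedule = temperature_schedule,
                 omega = omega,
                 rng_seed = as.integer(rng_seed)),
            class = "gibbs_config")
}

# All legal core alignments for a peptide of length L against a core of
# motif_length: choose the deleted positions among the interior (terminal
# residues are anchors and always kept).  Rows = candidate alignments, values
# = 1-based kept positions, deterministic combn order.
alignments_for_length <- function(L, motif_length, max_deletions) {
  d <- L - motif_length
  if (d < 0 || d > max_deletions)
    stop("peptide length ", L, " not alignable to core of ", motif_length,
         " with ", max_deletions, " deletions", call. = FALSE)
  if (d == 0) return(matrix(seq_len(L), nrow = 1))
  interior <- seq(2L, L - 1L)
  dels <- utils::combn(interior, d)
  t(apply(dels, 2, function(del) setdiff(seq_len(L), del)))
}

#' Cluster peptides into motif groups by simulated-annealing Gibbs sampling
#'
#' Partitions peptides (lengths `motif_length` to
#' `motif_length + max_deletions`) into K motif clusters over a length-9 core
#' alignment, for every K in `cluster_range`, keeping the best of `n_seeds`
#' annealing runs per K and selecting the K with the highest KLD objective.
#' After the final greedy sweep, peptides whose best log2-odds fit falls
#' below the trash threshold are discarded to a trash cluster and excluded
#' from the cluster frequency matrices.
#'
#' The KLD objective of a solution is
#' `sum_c (n_c / N) * w_c * KLD_c - lambda * sum_pairs max(0, cor)`, where
#' `KLD_c` is the Kullback-Leibler information content of cluster `c`'s
#' smoothed core frequencies against the background, `w_c = min(1, n_c /
#' (sigma * motif_length))` attenuates small clusters, and `cor` is the
#' Pearson correlation between vectorized cluster frequency matrices
#' (clipped at zero, so only positive similarity is penalized).
#'
#' @param peptides Character vector of distinct peptides (standard residues).
#' @param config A [gibbs_config()].
#' @param background Named 20-vector of residue background frequencies;
#'   `NULL` for uniform.
#' @return An object of class `gibbs_clustering`: list with `solutions` (one
#'   `cluster_solution` per K), `selected_K`, `peptides`, `config`.  Each
#'   solution carries `assignment` (cluster index, `0` = trash),
#'   `alignments` (kept core positions per peptide), `kld`,
#'   `per_cluster_kld`, `cluster_sizes`, `freq` (per-cluster core frequency
#'   matrices) and `polish_trace`.
#' @seealso [retained_peptides()], [motif_model()]
#' @export
cluster_peptides <- function(peptides, config = gibbs_config(),
                             background = NULL) {
  stopifnot(inherits(config, "gibbs_config"))
  peptides <- unique(as.character(peptides))
  if (!all(is_standard_peptide(peptides)))
    stop("peptides must use the 20-residue alphabet", call. = FALSE)
  m <- config$motif_length
  if (length(peptides) < m)
    stop("need at least ", m, " distinct peptides", call. = FALSE)
  lens <- nchar(peptides)
  if (any(lens < m | lens > m + config$max_deletions))
    stop("peptide lengths must lie in [", m, ", ", m + config$max_deletions,
         "]", call. = FALSE)
  if (is.null(background)) background <- uniform_background()

  enc <- aa_encode(peptides)
  enc0 <- enc - 1L
  enc0[is.na(enc0)] <- -1L
  ulen <- sort(unique(lens))
  align_list <- lapply(ulen, function(L)
    alignments_for_length(L, m, config$max_deletions) - 1L)
  pep_align_idx <- match(lens, ulen) - 1L

  run_one <- function(K, seed) {
    raw <- .gibbs_run(enc0, lens, align_list, pep_align_idx, K, m,
                      unname(background), config$omega,
                      config$temperature_schedule,
                      config$iters_per_seq_per_temp, seed)
    finalize_solution(raw, K, peptides, enc, lens, ulen, align_list,
                      background, config)
  }

  solutions <- vector("list", length(config$cluster_range))
  names(solutions) <- as.character(config$cluster_range)
  for (ki in seq_along(config$cluster_range)) {
    K <- config$cluster_range[ki]
    best <- NULL
    for (s in seq_len(config$n_seeds)) {
      sol <- run_one(K, derive_seed(config$rng_seed, K, s))
      if (is.null(best) || sol$kld > best$kld) best <- sol
    }
    solutions[[ki]] <- best
  }
  klds <- vapply(solutions, `[[`, numeric(1), "kld")
  structure(list(solutions = solutions,
                 selected_K = config$cluster_range[which.max(klds)],
                 kld_by_K = klds,
                 peptides = peptides,
                 background = background,
                 config = config),
            class = "gibbs_clustering")
}

# Assemble a cluster_solution from the raw sampler state: apply the trash
# rule, rebuild frequency matrices and compute the KLD model-selection
# objective.
finalize_solution <- function(raw, K, peptides, enc, lens, ulen, align_list,
                              background, config) {
  m <- config$motif_length
  N <- length(peptides)
  assign <- raw$assignment + 1L          # 1..K
  ach <- raw$align_choice + 1L
  keep_pos <- lapply(seq_len(N), function(i)
    align_list[[match(lens[i], ulen)]][ach[i], ] + 1L)

  core_idx <- function(i) enc[i, keep_pos[[i]]]
  count_cluster <- function(members) {
    cm <- matrix(0L, m, 20, dimnames = list(NULL, AA20))
    for (i in members) {
      ci <- core_idx(i)
      cm[cbind(seq_len(m), ci)] <- cm[cbind(seq_len(m), ci)] + 1L
    }
    cm
  }
  smooth <- function(cm, n) {
    B <- matrix(background, m, 20, byrow = TRUE)
    if (n == 0) return(B)
    (cm / n + config$omega * B) / (1 + config$omega)
  }

  # trash rule: best leave-one-out log2-odds fit over clusters/alignments
  if (config$use_trash) {
    counts <- lapply(seq_len(K), function(c) count_cluster(which(assign == c)))
    sizes <- tabulate(assign, nbins = K)
    B <- matrix(background, m, 20, byrow = TRUE)
    best_fit <- vapply(seq_len(N), function(i) {
      c0 <- assign[i]
      amat <- align_list[[match(lens[i], ulen)]] + 1L
      best <- -Inf
      for (c in seq_len(K)) {
        cm <- counts[[c]]
        n <- sizes[c]
        if (c == c0) {  # leave self out
          ci <- core_idx(i)
          cm <- cm
          cm[cbind(seq_len(m), ci)] <- cm[cbind(seq_len(m), ci)] - 1L
          n <- n - 1L
        }
        f <- smooth(cm, n)
        lo <- log2(f / B)
        for (r in seq_len(nrow(amat))) {
          ci_r <- enc[i, amat[r, ]]
          best <- max(best, sum(lo[cbind(seq_len(m), ci_r)]))
        }
      }
      best
    }, numeric(1))
    thr <- config$trash_threshold
    if (config$trash_score_scale == "per_position") thr <- thr * m
    trash <- best_fit < thr
    assign[trash] <- 0L
  }

  sizes <- tabulate(assign[assign > 0L], nbins = K)
  counts <- lapply(seq_len(K), function(c) count_cluster(which(assign == c)))
  freqs <- lapply(seq_len(K), function(c) smooth(counts[[c]], sizes[c]))
  B <- matrix(background, m, 20, byrow = TRUE)
  # Plug-in KLD overestimates information content by ~(20 - 1) / (2 n ln 2)
  # bits per position (Miller-Madow bias); uncorrected, small clusters look
  # spuriously sharp and inflate the selected K.
  per_kld <- vapply(seq_len(K), function(c) {
    if (sizes[c] == 0) return(0)
    raw <- sum(freqs[[c]] * log2(freqs[[c]] / B))
    bias <- m * 19 / (2 * sizes[c] * log(2))
    max(0, raw - bias)
  }, numeric(1))
  w <- pmin(1, sizes / (config$sigma * m))
  penalty <- 0
  if (K > 1) {
    for (c1 in seq_len(K - 1)) for (c2 in seq((c1 + 1), K)) {
      if (sizes[c1] == 0 || sizes[c2] == 0) next
      penalty <- penalty + max(0, stats::cor(as.vector(freqs[[c1]]),
                                             as.vector(freqs[[c2]])))
    }
  }
  kld <- sum((sizes / N) * w * per_kld) - config$lambda * penalty

  alignments <- keep_pos
  alignments[assign == 0L] <- list(NULL)
  structure(list(K = K, assignment = assign, alignments = alignments,
                 kld = kld, per_cluster_kld = per_kld,
                 cluster_sizes = sizes, trash_count = sum(assign == 0L),
                 freq = freqs, polish_trace = raw$polish_trace),
            class = "cluster_solution")
}

#' Retained peptides of the selected clustering solution
#'
#' Returns the non-trash peptides of the highest-KLD solution, grouped by
#' cluster with their core alignments; trash peptides are reported
#' separately.
#'
#' @param result A [cluster_peptides()] result.
#' @param K Cluster number to extract (default the selected one).
#' @return List with `clusters` (per cluster, a data frame `peptide` plus a
#'   list column `alignment` of kept core positions), `trash` (character
#'   vector) and `trash_count`.
#' @export
retained_peptides <- function(result, K = result$selected_K) {
  stopifnot(inherits(result, "gibbs_clustering"))
  sol <- result$solutions[[as.character(K)]]
  clusters <- lapply(seq_len(sol$K), function(c) {
    idx <- which(sol$assignment == c)
    df <- data.frame(peptide = result$peptides[idx],
                     stringsAsFactors = FALSE)
    df$alignment <- sol$alignments[idx]
    df
  })
  trash <- result$peptides[sol$assignment == 0L]
  list(clusters = clusters, trash = trash, trash_count = length(trash))
}

#' @export
print.gibbs_clustering <- function(x, ...) {
  cat("Gibbs motif clustering of", length(x$peptides), "peptides\n")
  cat("  K tried:", paste(x$config$cluster_range, collapse = ", "),
      " selected:", x$selected_K, "\n")
  sol <- x$solutions[[as.character(x$selected_K)]]
  cat("  cluster sizes:", paste(sol$cluster_sizes, collapse = ", "),
      " trash:", sol$trash_count, "\n")
  cat(sprintf("  KLD objective: %.4f\n", sol$kld))
  invisible(x)
}

#' @export
summary.gibbs_clustering <- function(object, ...) {
  tab <- data.frame(K = as.integer(names(object$solutions)),
                    kld = unname(object$kld_by_K),
                    trash = vapply(object$solutions, `[[`, integer(1),
                                   "trash_count"))
  consensus <- vapply(seq_len(object$selected_K), function(c) {
    f <- object$solutions[[as.character(object$selected_K)]]$freq[[c]]
    paste(AA20[apply(f, 1, which.max)], collapse = "")
  }, "")
  out <- list(by_K = tab, selected_K = object$selected_K,
              consensus = consensus)
  class(out) <- "summary.gibbs_clustering"
  out
}

#' @export
print.summary.gibbs_clustering <- function(x, ...) {
  print(x$by_K, row.names = FALSE)
  cat("selected K:", x$selected_K, "\n")
  cat("consensus:", paste(x$consensus, collapse = " "), "\n")
  invisible(x)
}
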