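# Unspecific in-silico digestion: every k-mer window of the configured length
# range, modelling proteasomal (non-enzymatic) cleavage.

#' Digestion configuration
#'
#' @param min_length,max_length Inclusive peptide length range.  Defaults 9-11,
#'   the HLA class I ligand lengths the downstream search considers.  Bounds:
#'   `7 <= min <= max <= 15`.
#' @param skip_ambiguous Skip windows containing ambiguity codes
#'   (`B J O U X Z`); default `TRUE` -- such windows cannot be scored by a
#'   20-residue PSSM.
#' @return An object of class `digest_config`.
#' @export
digest_config <- function(min_length = 9L, max_length = 11L,
                          skip_ambiguous = TRUE) {
  min_length <- as.integer(min_length)
  max_length <- as.integer(max_length)
  if (min_length < 7L || max_length > 15L || min_length > max_length)
    stop("lengths must satisfy 7 <= min <= max <= 15", call. = FALSE)
  structure(list(min_length = min_length, max_length = max_length,
                 skip_ambiguous = isTRUE(skip_ambiguous)),
            class = "digest_config")
}

#' Enumerate the unspecific k-mer search space of a protein database
#'
#' Slides windows of every configured length over every protein, skipping
#' windows that contain ambiguity codes, and returns the deduplicated peptide
#' set together with the pre-deduplication window count per length.  By
#' default each unique peptide keeps one representative source protein id
#' (the first encountered, in input order); set `full_source = TRUE` to keep
#' the complete id list per peptide.
#'
#' @param proteins Data frame from [read_protein_fasta()], or a (optionally
#'   named) character vector of protein sequences.
#' @param config A [digest_config()].
#' @param full_source Keep all source protein ids per peptide (slower).
#' @return An object of class `kmer_set`: list with `peptides` (data frame
#'   `peptide`, `length`, `source`), `window_counts` (named integer vector,
#'   valid pre-dedup windows per length) and `unique_counts` (unique peptides
#'   per length).
#' @export
enumerate_kmers <- function(proteins, config = digest_config(),
                            full_source = FALSE) {
  if (is.character(proteins)) {
    ids <- names(proteins)
    if (is.null(ids)) ids <- sprintf("seq%04d", seq_along(proteins))
    proteins <- data.frame(id = ids, sequence = toupper(unname(proteins)),
                           stringsAsFactors = FALSE)
  }
  if (nrow(proteins) == 0L) stop("no proteins", call. = FALSE)
  stopifnot(inherits(config, "digest_config"))
  ks <- config$min_length:config$max_length
  ambig_pat <- sprintf("[%s]", paste(AA_AMBIG, collapse = ""))

  win_counts <- stats::setNames(integer(length(ks)), as.character(ks))
  peps <- vector("list", nrow(proteins) * length(ks))
  srcs <- vector("list", length(peps))
  slot <- 0L
  for (pi in seq_len(nrow(proteins))) {
    s <- toupper(proteins$sequence[pi])
    n <- nchar(s)
    # cumulative count of ambiguous residues, for O(1) window checks
    if (config$skip_ambiguous) {
      amb <- as.integer(grepl(ambig_pat,
                              substring(s, seq_len(n), seq_len(n))))
      cum <- c(0L, cumsum(amb))
    }
    for (j in seq_along(ks)) {
      k <- ks[j]
      if (n < k) next
      starts <- seq_len(n - k + 1L)
      if (config$skip_ambiguous) {
        valid <- (cum[starts + k] - cum[starts]) == 0L
        starts <- starts[valid]
      }
      if (length(starts) == 0L) next
      win_counts[j] <- win_counts[j] + length(starts)
      slot <- slot + 1L
      peps[[slot]] <- substring(s, starts, starts + k - 1L)
      srcs[[slot]] <- rep(proteins$id[pi], length(starts))
    }
  }
  all_pep <- unlist(peps[seq_len(slot)], use.names = FALSE)
  all_src <- unlist(srcs[seq_len(slot)], use.names = FALSE)
  if (is.null(all_pep)) all_pep <- character()
  if (is.null(all_src)) all_src <- character()

  first <- !duplicated(all_pep)
  out <- data.frame(peptide = all_pep[first],
                    length = nchar(all_pep[first]),
                    source = all_src[first], stringsAsFactors = FALSE)
  if (full_source && length(all_pep)) {
    src_map <- lapply(split(all_src, all_pep), unique)
    out$source_all <- unname(src_map[out$peptide])
  }
  uc <- table(factor(out$length, levels = ks))
  structure(list(peptides = out,
                 window_counts = win_counts,
                 unique_counts = stats::setNames(as.integer(uc),
                                                 as.character(ks)),
                 config = config),
            class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat("Unspecific k-mer set:", nrow(x$peptides), "unique peptides\n")
  cat("  lengths ", x$config$min_length, "-", x$config$max_length, "\n",
      sep = "")
  for (k in names(x$window_counts))
    cat(sprintf("  %s-mers: %d windows, %d unique\n", k,
                x$window_counts[[k]], x$unique_counts[[k]]))
  invisible(x)
}
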