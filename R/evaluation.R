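# Motif similarity between peptide sets: Pearson correlation of positional
# amino acid frequency profiles (PCC_aaf).

#' Positional amino acid frequency profile of a peptide set
#'
#' @param peptides Character vector of equal-length peptides (standard
#'   residues only).
#' @return An object of class `freq_profile`: list with `pmf` (L x 20 matrix,
#'   rows summing to 1, columns in [aa_alphabet()] order), `length`, `n`.
#' @export
amino_acid_frequencies <- function(peptides) {
  peptides <- as.character(peptides)
  if (length(peptides) < 1L) stop("no peptides", call. = FALSE)
  lens <- unique(nchar(peptides))
  if (length(lens) != 1L)
    stop("peptides have mixed lengths: ", paste(sort(lens), collapse = ", "),
         call. = FALSE)
  enc <- aa_encode(peptides)
  pmf <- matrix(0, lens, 20, dimnames = list(NULL, AA20))
  for (i in seq_len(lens))
    pmf[i, ] <- tabulate(enc[, i], nbins = 20) / length(peptides)
  structure(list(pmf = pmf, length = lens, n = length(peptides)),
            class = "freq_profile")
}

#' @export
print.freq_profile <- function(x, ...) {
  cat("Frequency profile: length", x$length, "from", x$n, "peptides\n")
  cons <- AA20[apply(x$pmf, 1, which.max)]
  cat("  modal residues:", paste(cons, collapse = ""), "\n")
  invisible(x)
}

#' Pearson correlation of positional amino acid frequencies
#'
#' For each position, the 20 residue frequencies of the two profiles are
#' treated as paired observations and their Pearson correlation is computed;
#' the mean over the requested positions is returned alongside.  A position
#' where either profile has zero variance (a uniform row) has an undefined
#' correlation: it is reported as `NA`, excluded from the mean, and a warning
#' is raised.
#'
#' @param x,y [amino_acid_frequencies()] profiles of equal length, or
#'   equal-length peptide vectors (converted internally).
#' @param positions `"all"` or an integer vector of 1-based positions
#'   (immunology convention: P1..P9 for a 9-mer).
#' @return List with `position` (integer vector), `pcc` (per-position
#'   values, `NA` where undefined) and `mean` (over defined positions).
#' @export
pcc_aaf <- function(x, y, positions = "all") {
  if (!inherits(x, "freq_profile")) x <- amino_acid_frequencies(x)
  if (!inherits(y, "freq_profile")) y <- amino_acid_frequencies(y)
  if (x$length != y$length)
    stop("profiles have different lengths", call. = FALSE)
  pos <- if (identical(positions, "all")) seq_len(x$length)
         else as.integer(positions)
  if (any(pos < 1L | pos > x$length))
    stop("positions out of range 1..", x$length, call. = FALSE)
  pcc <- vapply(pos, function(i) {
    px <- x$pmf[i, ]; py <- y$pmf[i, ]
    if (stats::sd(px) == 0 || stats::sd(py) == 0) return(NA_real_)
    stats::cor(px, py)
  }, numeric(1))
  if (anyNA(pcc))
    warning("position(s) ", paste(pos[is.na(pcc)], collapse = ", "),
            " have zero variance; excluded from the mean", call. = FALSE)
  list(position = pos, pcc = pcc, mean = mean(pcc, na.rm = TRUE))
}
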