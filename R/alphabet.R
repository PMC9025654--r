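# Residue alphabet, encoding helpers and seeded-RNG scaffolding shared by all
# modules.

#' The 20-residue amino acid alphabet
#'
#' Residues in the fixed column order used by every matrix in the package
#' (frequency profiles, PSSMs, serialized matrix files).
#'
#' @return Character vector of the 20 standard one-letter residue codes.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() AA20

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Ambiguity / non-standard codes tolerated in protein records but never in
# peptides ('*' only as a trailing stop codon, stripped at parse time).
AA_AMBIG <- c("B", "J", "O", "U", "X", "Z")

# lookup: residue character -> 1-based column index (NA for anything else)
.aa_lookup <- local({
  x <- rep(NA_integer_, 127L)
  for (i in seq_along(AA20)) x[utf8ToInt(AA20[i])] <- i
  x
})

# Encode peptides to a matrix of 1-based residue indices (rows = peptides,
# padded with NA beyond each peptide's length).  Errors on non-standard
# residues unless allow_na.
aa_encode <- function(peptides, allow_na = FALSE) {
  n <- length(peptides)
  lens <- nchar(peptides)
  m <- matrix(NA_integer_, n, max(lens, 1L))
  for (i in seq_len(n)) {
    idx <- .aa_lookup[utf8ToInt(peptides[i])]
    if (!allow_na && anyNA(idx)) {
      bad <- substr(peptides[i], which(is.na(idx))[1], which(is.na(idx))[1])
      stop("peptide '", peptides[i], "' contains non-standard residue '",
           bad, "'", call. = FALSE)
    }
    m[i, seq_len(lens[i])] <- idx
  }
  m
}

# TRUE for peptides made only of the 20 standard residues
is_standard_peptide <- function(peptides) {
  !grepl(sprintf("[^%s]", paste(AA20, collapse = "")), peptides)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed (< 2^31) from a base seed and stream labels.
derive_seed <- function(seed, ...) {
  parts <- c(as.integer(seed), as.integer(c(...)))
  s <- 0
  for (p in parts) s <- (s * 69069 + p + 12345) %% 2147483647
  as.integer(s)
}

uniform_background <- function() {
  b <- rep(1 / 20, 20)
  names(b) <- AA20
  b
}

#' Approximate vertebrate proteome residue frequencies
#'
#' Rounded average amino acid usage of a vertebrate proteome (leucine most
#' common at ~10%, tryptophan rarest at ~1%), normalized to sum 1.  Useful as
#' a realistic skewed background for the synthetic generators when no
#' proteome FASTA is at hand; [background_frequencies()] computes the real
#' thing from sequences.
#'
#' @return Named numeric 20-vector in [aa_alphabet()] order.
#' @export
reference_background <- function() {
  b <- c(A = 8.25, C = 1.38, D = 5.45, E = 6.75, F = 3.86, G = 7.07,
         H = 2.27, I = 5.96, K = 5.84, L = 9.66, M = 2.42, N = 4.06,
         P = 4.70, Q = 3.93, R = 5.53, S = 6.56, T = 5.34, V = 6.87,
         W = 1.08, Y = 2.92)
  b / sum(b)
}
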