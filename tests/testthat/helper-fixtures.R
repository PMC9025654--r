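# Shared fixtures and independent oracles.  Everything is generated in code;
# no binary data.

AAs <- aa_alphabet()

# two disjoint HLA-like motifs: anchors at P2 and the C-terminus
motif_LV <- function() motif_spec(anchors = list("2" = c("L", 0.7),
                                                 "9" = c("V", 0.7)))
motif_KR <- function() motif_spec(anchors = list("2" = c("K", 0.7),
                                                 "9" = c("R", 0.7)))

random_peptides <- function(n, length = 9L, seed = 1L) {
  set.seed(seed)
  replicate(n, paste(sample(AAs, length, replace = TRUE), collapse = ""))
}

write_fasta_lines <- function(path, ids, seqs, desc = NULL) {
  headers <- if (is.null(desc)) paste0(">", ids)
             else paste0(">", ids, " ", desc)
  writeLines(as.vector(rbind(headers, seqs)), path)
}

# independent naive PSSM oracle: plain counting + the smoothing/score formula
oracle_pssm <- function(peptides, background, omega,
                        form = c("log_odds", "as_printed")) {
  form <- match.arg(form)
  L <- nchar(peptides[1])
  counts <- matrix(0, L, 20)
  for (p in peptides) {
    r <- strsplit(p, "")[[1]]
    for (i in seq_len(L)) {
      j <- which(AAs == r[i])
      counts[i, j] <- counts[i, j] + 1
    }
  }
  F_ai <- counts / length(peptides)
  P <- matrix(0, L, 20)
  for (i in seq_len(L)) for (j in 1:20) {
    f <- (F_ai[i, j] + omega * background[j]) / (1 + omega)
    P[i, j] <- if (form == "log_odds") log2(f / background[j])
               else log2(F_ai[i, j] + omega * background[j])
  }
  P
}

oracle_score <- function(P, peptide) {
  r <- strsplit(peptide, "")[[1]]
  s <- 0
  for (i in seq_along(r)) s <- s + P[i, which(AAs == r[i])]
  s
}

# brute-force k-mer window enumeration
oracle_kmers <- function(seqs, k, skip_ambiguous = TRUE) {
  out <- character()
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (skip_ambiguous && grepl("[BJOUXZ*]", w)) next
      out <- c(out, w)
    }
  }
  out
}

# textbook Pearson correlation over the 20 residue categories
oracle_pcc <- function(px, py) {
  mx <- mean(px); my <- mean(py)
  covxy <- mean((px - mx) * (py - my))
  covxy / (sqrt(mean((px - mx)^2)) * sqrt(mean((py - my)^2)))
}
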