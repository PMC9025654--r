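# FASTA and peptide-table I/O.  Proteome FASTA parsing is delegated to
# Biostrings; peptide-hit tables (Percolator peptide-level "pout" dialect or a
# plain list) are header-driven tab-separated text.

#' Read a protein database from FASTA
#'
#' Reads a proteome (or contaminant) FASTA into a data frame of protein
#' records.  Sequences are uppercased and a single trailing stop codon `*` is
#' stripped.  The record id is the header up to the first whitespace.
#'
#' Ambiguity codes (`B J O U X Z`) are tolerated in protein sequences -- the
#' digestion module skips windows containing them -- but any other character,
#' or an internal `*`, is an error naming the offending record and character.
#'
#' @param path Path to a FASTA file.
#' @param contaminant Logical flag recorded on every returned record, marking
#'   the database as a contaminant collection (e.g. keratins, serum proteins).
#' @return A data frame with columns `id`, `description`, `sequence`,
#'   `is_contaminant`, one row per FASTA entry, in file order.
#' @seealso [write_peptide_fasta()], [enumerate_kmers()]
#' @export
read_protein_fasta <- function(path, contaminant = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("failed to parse FASTA '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0L) stop("no sequences in '", path, "'", call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)  # trailing stop codon
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA ids: ", paste(dups, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record ", ids[!nzchar(seqs)][1], call. = FALSE)
  }
  allowed <- sprintf("[^%s]", paste(c(AA20, AA_AMBIG), collapse = ""))
  bad <- grepl(allowed, seqs)
  if (any(bad)) {
    i <- which(bad)[1]
    ch <- regmatches(seqs[i], regexpr(allowed, seqs[i]))
    stop("illegal character '", ch, "' in record ", ids[i], call. = FALSE)
  }
  data.frame(id = ids, description = desc, sequence = seqs,
             is_contaminant = contaminant, stringsAsFactors = FALSE)
}

#' Strip search-engine annotation from peptide strings
#'
#' Reduces annotated peptide strings to bare residue sequences: flanking
#' residues (`K.PEPTIDE.V`), bracketed or parenthesized mass tags
#' (`n[42.01]`, `M(ox)`), lowercase tags and any remaining non-letter
#' characters are removed, and the result is uppercased only where it already
#' was uppercase (lowercase characters are treated as annotation, not
#' residues).
#'
#' @param x Character vector of annotated peptide strings.
#' @return Character vector of bare residue strings.
#' @export
#' @examples
#' strip_peptide_mods("K.AIFQSSM[15.99]TK.V")
strip_peptide_mods <- function(x) {
  x <- sub("^[A-Za-z*-]\\.", "", x)
  x <- sub("\\.[A-Za-z*-]$", "", x)
  x <- gsub("\\[[^]]*\\]", "", x)
  x <- gsub("\\([^)]*\\)", "", x)
  gsub("[^A-Z]", "", x)
}

#' Read first-round peptide identifications
#'
#' Parses the peptide-level output of a first-round (unspecific digestion)
#' database search.  Two dialects are supported: `"percolator_pout"`, a
#' tab-separated table with a header naming at least a peptide and a q-value
#' column (extra columns ignored; all columns from the protein-id column
#' onward are collected as protein ids); and `"plain_list"`, one peptide per
#' line with `#` comments.
#'
#' Peptides are stripped to bare sequences ([strip_peptide_mods()]); hits with
#' a q-value above `q_threshold` are removed; hits containing non-standard
#' residues are dropped with a warning count; duplicate sequences are
#' collapsed to one hit keeping the minimum q-value and the union of protein
#' ids.
#'
#' @param path Path to the table.
#' @param dialect `"percolator_pout"` or `"plain_list"`.
#' @param q_threshold Peptide-level q-value cutoff (default 0.01, i.e. 1% FDR).
#' @param drop_contaminants If `TRUE`, remove hits whose entire protein-id set
#'   lies within `contaminant_ids`.
#' @param contaminant_ids Character vector of contaminant protein ids.
#' @return A data frame with columns `sequence`, `length`, `q_value`,
#'   `search_score` and a list column `protein_ids`.
#' @export
read_peptide_hits <- function(path,
                              dialect = c("percolator_pout", "plain_list"),
                              q_threshold = 0.01,
                              drop_contaminants = FALSE,
                              contaminant_ids = character()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)

  if (dialect == "plain_list") {
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    hits <- data.frame(raw = lines, q_value = NA_real_,
                       search_score = NA_real_, stringsAsFactors = FALSE)
    hits$protein_ids <- replicate(nrow(hits), character(), simplify = FALSE)
  } else {
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 1L) stop("empty table: ", path, call. = FALSE)
    header <- tolower(strsplit(lines[[1]], "\t", fixed = TRUE)[[1]])
    find_col <- function(aliases, required = TRUE, label = aliases[1]) {
      i <- which(header %in% aliases)
      if (length(i) == 0L) {
        if (required) stop("missing required column '", label,
                           "' in ", path, call. = FALSE)
        return(NA_integer_)
      }
      i[1]
    }
    pep_col <- find_col(c("peptide", "sequence"), label = "peptide")
    q_col <- find_col(c("q-value", "q.value", "qvalue", "q_value"),
                      label = "q-value")
    score_col <- find_col(c("score", "search_score"), required = FALSE)
    prot_col <- find_col(c("proteinids", "proteinid", "protein_ids",
                           "proteins"), required = FALSE)
    rows <- strsplit(lines[-1], "\t", fixed = TRUE)
    if (length(rows) == 0L) stop("empty first-round set", call. = FALSE)
    get <- function(r, j) {
      if (!is.na(j) && length(r) >= j) r[[j]] else NA_character_
    }
    hits <- data.frame(
      raw = vapply(rows, get, "", j = pep_col),
      q_value = as.numeric(vapply(rows, get, "", j = q_col)),
      search_score = if (is.na(score_col)) NA_real_ else
        as.numeric(vapply(rows, get, "", j = score_col)),
      stringsAsFactors = FALSE)
    hits$protein_ids <- if (is.na(prot_col)) {
      replicate(nrow(hits), character(), simplify = FALSE)
    } else {
      lapply(rows, function(r)
        if (length(r) >= prot_col) r[prot_col:length(r)] else character())
    }
  }

  hits$sequence <- strip_peptide_mods(hits$raw)
  ok <- is_standard_peptide(hits$sequence) & nzchar(hits$sequence)
  if (any(!ok)) {
    warning(sum(!ok), " hit(s) with non-standard residues rejected",
            call. = FALSE)
    hits <- hits[ok, , drop = FALSE]
  }
  keep <- is.na(hits$q_value) | hits$q_value <= q_threshold
  hits <- hits[keep, , drop = FALSE]
  if (drop_contaminants && nrow(hits)) {
    only_cont <- vapply(hits$protein_ids, function(p)
      length(p) > 0 && all(p %in% contaminant_ids), logical(1))
    hits <- hits[!only_cont, , drop = FALSE]
  }
  if (nrow(hits) == 0L) stop("empty first-round set", call. = FALSE)

  # collapse duplicates: min q-value, union of protein ids
  ord <- order(hits$q_value, na.last = TRUE)
  hits <- hits[ord, , drop = FALSE]
  prot_union <- lapply(split(hits$protein_ids, hits$sequence),
                       function(l) unique(unlist(l)))
  first <- !duplicated(hits$sequence)
  hits <- hits[first, , drop = FALSE]
  hits$protein_ids <- unname(prot_union[hits$sequence])
  out <- data.frame(sequence = hits$sequence,
                    length = nchar(hits$sequence),
                    q_value = hits$q_value,
                    search_score = hits$search_score,
                    stringsAsFactors = FALSE)
  out$protein_ids <- hits$protein_ids
  rownames(out) <- NULL
  out
}

#' Write a targeted peptide database as FASTA
#'
#' Writes one FASTA record per unique peptide, in deterministic lexicographic
#' (byte) order, so that identical databases produce byte-identical files.
#' The header carries a stable serial, the provenance tag(s)
#' (`motif`, `first_round`, `contaminant`, `;`-joined) and the best motif
#' score where one exists.  The resulting file is meant to be searched with
#' no-cleavage (unspecific) settings, each entry being one candidate peptide.
#'
#' @param db A [build_targeted_database()] result, or a data frame with
#'   columns `peptide`, `provenance` and optionally `best_score`.
#' @param path Output path.
#' @return Invisibly, the number of records written.
#' @export
write_peptide_fasta <- function(db, path) {
  if (inherits(db, "targeted_db")) db <- db$peptides
  if (is.character(db)) db <- data.frame(peptide = db, provenance = "motif",
                                         stringsAsFactors = FALSE)
  if (is.null(db$best_score)) db$best_score <- NA_real_
  if (nrow(db) == 0L) stop("empty database", call. = FALSE)
  db <- db[!duplicated(db$peptide), , drop = FALSE]
  db <- db[order(db$peptide, method = "radix"), , drop = FALSE]
  score <- ifelse(is.na(db$best_score), "NA",
                  sprintf("%.4f", db$best_score))
  headers <- sprintf(">pep%06d prov=%s score=%s",
                     seq_len(nrow(db)), db$provenance, score)
  con <- file(path, open = "wb")  # fixed "\n" endings for byte determinism
  on.exit(close(con))
  writeLines(as.vector(rbind(headers, db$peptide)), con, sep = "\n")
  invisible(nrow(db))
}
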