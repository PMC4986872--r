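# Shared data model and readers/writers for the delimited formats the
# pipeline touches. Coordinates are 1-based and inclusive on both ends
# throughout, matching the superscript convention of N-terminal peptide
# papers (e.g. residues 44..56 written ^44^FSTPSDLDSELTR^56^).

#' The twenty standard amino acids
#'
#' One-letter codes in alphabetical order. 'X' is additionally accepted in
#' protein sequences as an unknown residue; it never contributes to counts,
#' frequencies or charge.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.valid_protein <- function(x) grepl(paste0("^[", paste(c(AA_STANDARD, "X"), collapse = ""), "]+$"), x)
.valid_peptide <- function(x) grepl(paste0("^[", paste(AA_STANDARD, collapse = ""), "]+$"), x)

#' Read a protein FASTA file
#'
#' Accessions are taken from the first whitespace-delimited token of each
#' header; the remainder becomes the description. Sequences are uppercased on
#' read and must use the 20 standard residues plus 'X'.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `accession`, `description`, `sequence`,
#'   one row per record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no FASTA records in ", path)
  headers <- names(aa)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  sequence <- toupper(as.character(aa))
  names(sequence) <- NULL
  dup <- unique(accession[duplicated(accession)])
  if (length(dup) > 0L)
    stop("duplicate accession(s) in FASTA: ", paste(dup, collapse = ", "))
  bad <- which(!.valid_protein(sequence))
  if (length(bad) > 0L)
    stop("invalid residues in record(s): ", paste(accession[bad], collapse = ", "))
  data.frame(accession = accession, description = description,
             sequence = sequence, stringsAsFactors = FALSE)
}

#' Write proteins to FASTA
#'
#' @param proteins data.frame with `accession`, `sequence` and optionally
#'   `description` columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  x <- Biostrings::AAStringSet(proteins$sequence)
  desc <- if ("description" %in% names(proteins)) proteins$description else ""
  names(x) <- ifelse(nzchar(desc), paste(proteins$accession, desc), proteins$accession)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.PEPTIDE_COLS <- c("accession", "peptide", "nterm_mod", "comparison_id",
                   "ratio_mut_over_wt")

#' Read a quantified N-terminal peptide table
#'
#' Tab-separated, UTF-8, '#' comment lines ignored. Required columns:
#' `accession`, `peptide`, `nterm_mod`, `comparison_id`, `ratio_mut_over_wt`;
#' `start` is optional (mapped later when absent). The ratio is oriented
#' mutant/wild-type: "upregulated in the knockout" means ratio above 1.
#'
#' Rows with a missing or non-positive ratio, or a peptide containing
#' characters outside the 20-residue alphabet, are rejected rather than
#' fatal; they are returned for inspection.
#'
#' @param path Path to the table.
#' @return A list with elements `peptides` (clean rows, with `start`/`end`
#'   columns present, `NA` when unmapped, and a logical `confidence` flag)
#'   and `rejected` (offending rows with a `reason` column).
#' @export
read_peptide_table <- function(path) {
  if (!file.exists(path)) stop("peptide table not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(.PEPTIDE_COLS, names(df))
  if (length(missing) > 0L)
    stop("peptide table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  df$peptide <- toupper(trimws(as.character(df$peptide)))
  df$ratio_mut_over_wt <- suppressWarnings(as.numeric(df$ratio_mut_over_wt))
  if (!"start" %in% names(df)) df$start <- NA_integer_
  df$start <- suppressWarnings(as.integer(df$start))
  if (!"confidence" %in% names(df)) df$confidence <- TRUE
  reason <- rep(NA_character_, nrow(df))
  reason[!nzchar(df$peptide)] <- "missing_peptide"
  reason[is.na(reason) & !.valid_peptide(df$peptide)] <- "invalid_peptide_alphabet"
  reason[is.na(reason) & (is.na(df$ratio_mut_over_wt) | df$ratio_mut_over_wt <= 0)] <-
    "nonpositive_or_missing_ratio"
  bad <- !is.na(reason)
  rejected <- df[bad, , drop = FALSE]
  rejected$reason <- reason[bad]
  peptides <- df[!bad, , drop = FALSE]
  peptides$end <- ifelse(is.na(peptides$start), NA_integer_,
                         peptides$start + nchar(peptides$peptide) - 1L)
  rownames(peptides) <- NULL
  rownames(rejected) <- NULL
  list(peptides = peptides, rejected = rejected)
}

#' Write a quantified peptide table
#'
#' @param peptides Peptide data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  utils::write.table(peptides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Locate a peptide inside a protein sequence
#'
#' Exact substring matching; I and L are distinct characters (collapsing them
#' would create false ambiguities for database-assigned proteins).
#'
#' @param sequence Protein sequence string.
#' @param peptide Peptide string.
#' @return Integer vector of 1-based start positions of every exact match
#'   (length 0 when absent).
#' @export
locate_peptide <- function(sequence, peptide) {
  hits <- gregexpr(peptide, sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Map peptides onto their proteins
#'
#' Assigns `start`/`end` coordinates by unique exact substring match. Peptides
#' whose accession is unknown, that do not match, or that match more than once
#' are excluded with a per-row diagnostic.
#'
#' @param peptides Peptide data.frame (see [read_peptide_table()]).
#' @param proteins Protein data.frame (see [read_fasta()]).
#' @return List with `mapped` (peptides with filled `start`/`end`) and
#'   `unmapped` (excluded rows with a `reason` column).
#' @export
map_peptides_to_proteins <- function(peptides, proteins) {
  seqs <- stats::setNames(proteins$sequence, proteins$accession)
  n <- nrow(peptides)
  start <- integer(n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    acc <- peptides$accession[i]
    if (!acc %in% names(seqs)) {
      reason[i] <- "unknown_accession"
      next
    }
    hits <- locate_peptide(seqs[[acc]], peptides$peptide[i])
    if (length(hits) == 0L) {
      reason[i] <- "no_match"
    } else if (length(hits) > 1L) {
      reason[i] <- "ambiguous_match"
    } else {
      start[i] <- hits
    }
  }
  ok <- is.na(reason)
  mapped <- peptides[ok, , drop = FALSE]
  mapped$start <- start[ok]
  mapped$end <- mapped$start + nchar(mapped$peptide) - 1L
  unmapped <- peptides[!ok, , drop = FALSE]
  unmapped$reason <- reason[!ok]
  rownames(mapped) <- NULL
  rownames(unmapped) <- NULL
  list(mapped = mapped, unmapped = unmapped)
}

#' Read a protein localization table
#'
#' Two tab-separated columns, accession and location label (SUBAcon-style
#' consensus call). Labels are normalized to lowercase. A duplicated
#' accession is tolerated when the labels agree and an error otherwise.
#'
#' @param path Path to the table.
#' @return Named character vector, accession -> location label.
#' @export
read_localization_table <- function(path) {
  if (!file.exists(path)) stop("localization table not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          header = TRUE)
  if (ncol(df) < 2L) stop("localization table needs two columns")
  acc <- as.character(df[[1]])
  lab <- tolower(trimws(as.character(df[[2]])))
  for (a in unique(acc[duplicated(acc)])) {
    if (length(unique(lab[acc == a])) > 1L)
      stop("conflicting localization labels for accession ", a)
  }
  keep <- !duplicated(acc)
  stats::setNames(lab[keep], acc[keep])
}

#' Write a localization table
#' @param localization Named character vector, accession -> label.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_localization_table <- function(localization, path) {
  utils::write.table(
    data.frame(accession = names(localization), location = unname(localization)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
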