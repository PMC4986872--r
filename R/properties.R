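# Targeting-presequence property statistics: length, net charge at a given
# pH, residue composition, group comparisons, cleavage-prediction scoring
# and N-termini set comparison across studies.

#' Side-chain and terminal pKa values
#'
#' Defaults follow a standard peptide-calculator table: D 3.65, E 4.25,
#' C 8.3, Y 10.07, H 6.0, K 10.53, R 12.48, N-terminus 8.0, C-terminus 3.1.
#' Free termini are included by default, matching the behaviour of pasting a
#' bare presequence into a peptide calculator; exclude them for charge
#' contributions of internal segments.
#'
#' @param positive Named pKa vector of basic residues.
#' @param negative Named pKa vector of acidic residues.
#' @param nterm,cterm Terminal pKa values.
#' @param include_n_terminus,include_c_terminus Whether the free termini
#'   contribute.
#' @return A list of class `pka_set`.
#' @export
pka_set <- function(positive = c(K = 10.53, R = 12.48, H = 6.0),
                    negative = c(D = 3.65, E = 4.25, C = 8.3, Y = 10.07),
                    nterm = 8.0, cterm = 3.1,
                    include_n_terminus = TRUE, include_c_terminus = TRUE) {
  all_pka <- c(positive, negative, nterm, cterm)
  if (any(all_pka <= 0 | all_pka >= 14)) stop("pKa values must lie in (0, 14)")
  structure(list(positive = positive, negative = negative,
                 nterm = nterm, cterm = cterm,
                 include_n_terminus = include_n_terminus,
                 include_c_terminus = include_c_terminus),
            class = "pka_set")
}

#' Henderson-Hasselbalch net charge of a peptide
#'
#' Sum of fractional charges of the ionizable side chains (K, R, H positive;
#' D, E, C, Y negative) and, when included, the free termini:
#' positive groups contribute `1 / (1 + 10^(pH - pKa))`, negative groups
#' `-1 / (1 + 10^(pKa - pH))`. 'X' residues contribute nothing.
#'
#' @param sequence Peptide or presequence string.
#' @param pH The pH (default 7).
#' @param pka A [pka_set()].
#' @return The net charge (signed real).
#' @export
net_charge <- function(sequence, pH = 7, pka = pka_set()) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (any(!chars %in% c(AA_STANDARD, "X")))
    stop("invalid residue in sequence")
  pos <- sum(vapply(names(pka$positive), function(r)
    sum(chars == r) / (1 + 10^(pH - pka$positive[[r]])), numeric(1)))
  neg <- sum(vapply(names(pka$negative), function(r)
    sum(chars == r) / (1 + 10^(pka$negative[[r]] - pH)), numeric(1)))
  if (pka$include_n_terminus) pos <- pos + 1 / (1 + 10^(pH - pka$nterm))
  if (pka$include_c_terminus) neg <- neg + 1 / (1 + 10^(pka$cterm - pH))
  pos - neg
}

#' Per-group presequence summaries
#'
#' For each group: the number of sequences, mean/min/max length, mean net
#' charge at the stated pH, and the pooled residue frequency vector (counts
#' over all residues of the group).
#'
#' @param records data.frame with columns `group` and `sequence` (e.g.
#'   `at_mito`, `sc_mito`, `at_chloro`, `at_dual`).
#' @param pH pH for the net charge.
#' @param pka A [pka_set()].
#' @return List with `summary` (one row per group) and `frequencies`
#'   (residue-by-group matrix, columns summing to 1).
#' @export
group_stats <- function(records, pH = 7, pka = pka_set()) {
  if (nrow(records) == 0L) stop("no presequence records")
  groups <- unique(records$group)
  len <- nchar(records$sequence)
  charge <- vapply(records$sequence, net_charge, numeric(1), pH = pH,
                   pka = pka, USE.NAMES = FALSE)
  summary <- do.call(rbind, lapply(groups, function(g) {
    sel <- records$group == g
    data.frame(group = g, n = sum(sel),
               mean_length = mean(len[sel]),
               min_length = min(len[sel]), max_length = max(len[sel]),
               mean_net_charge = mean(charge[sel]),
               stringsAsFactors = FALSE)
  }))
  frequencies <- vapply(groups, function(g) {
    chars <- unlist(strsplit(records$sequence[records$group == g], ""))
    tab <- table(factor(chars[chars %in% AA_STANDARD], levels = AA_STANDARD))
    as.numeric(tab) / sum(tab)
  }, numeric(length(AA_STANDARD)))
  rownames(frequencies) <- AA_STANDARD
  list(summary = summary, frequencies = frequencies)
}

#' Compare a property between two presequence groups
#'
#' Two-sided two-sample location test allowing unequal variances (Welch's
#' t-test; the test behind the published group P-values is unspecified, so
#' this choice is an assumption of the package). Degenerate identical
#' zero-variance groups return p = 1 by convention.
#'
#' @param values_a,values_b Numeric vectors (each length >= 2).
#' @return List with `statistic` and `p_value`.
#' @export
compare_groups <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least two values")
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    same <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    return(list(statistic = 0, p_value = if (same) 1 else 0))
  }
  t <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(statistic = unname(t$statistic), p_value = t$p.value)
}

#' Score cleavage-site predictions against observed sites
#'
#' A prediction is correct when it falls within `tolerance` residues of the
#' observed mature start. Proteins in the truth set without a prediction
#' count as incorrect.
#'
#' @param predicted Named integer vector, accession -> predicted position.
#' @param truth Named integer vector, accession -> observed position.
#' @param tolerance Allowed absolute offset (default 1).
#' @return The accuracy fraction in [0, 1].
#' @export
score_cleavage_predictions <- function(predicted, truth, tolerance = 1) {
  shared <- intersect(names(predicted), names(truth))
  if (length(shared) == 0L) stop("prediction and truth sets share no accession")
  correct <- sum(abs(predicted[shared] - truth[shared]) <= tolerance)
  correct / length(truth)
}

#' Compare two N-termini sets across studies
#'
#' @param current,previous Named integer vectors, accession -> mature start.
#' @return List with `n_shared`, `n_identical`, `n_different`, and `offsets`
#'   (named current-minus-previous offsets of the differing proteins).
#' @export
compare_nterm_sets <- function(current, previous) {
  shared <- intersect(names(current), names(previous))
  offsets <- current[shared] - previous[shared]
  differing <- offsets[offsets != 0]
  list(n_shared = length(shared),
       n_identical = sum(offsets == 0),
       n_different = length(differing),
       offsets = differing)
}

#' Read a presequence data set
#'
#' Tab-separated `accession`, `group`, `sequence` layout.
#'
#' @param path Path to the table.
#' @return data.frame of presequence records.
#' @export
read_presequence_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("accession", "group", "sequence")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("presequence table lacks column(s): ", paste(missing, collapse = ", "))
  df$sequence <- toupper(df$sequence)
  if (any(nchar(df$sequence) < 1L)) stop("empty presequence in table")
  df
}
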