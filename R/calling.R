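# Substrate calling for the two mitochondrial intermediate peptidases.
#
# ICP55 removes one (occasionally two) residues from the N-terminus left by
# the processing peptidase MPP; OCT1 removes a longer segment. In a knockout,
# the intermediate terminus accumulates (ratio mutant/wild-type >= fold) and
# the mature terminus is depleted (ratio <= 1/fold). Substrates are called
# from paired termini where possible, and from single differential termini
# under N-end-rule stability criteria otherwise.

#' N-end-rule residue stability table
#'
#' Classifies each of the 20 residues as a stable or destabilizing N-terminal
#' residue. The default follows the classical destabilizing classes (bulky
#' hydrophobic, basic, acidic and their amidated forms); small uncharged
#' residues are stable. Met and Cys sit on the boundary of the rule and are
#' stable by default; pass them through `extra_unstable` for analyses of
#' organisms where their removal is observed.
#'
#' @param unstable Character vector of destabilizing residues.
#' @param extra_unstable Residues to add to the destabilizing set.
#' @return Named character vector over all 20 residues with values
#'   `"stable"`/`"unstable"`.
#' @export
stability_table <- function(unstable = c("F", "L", "W", "Y", "I", "R", "K",
                                         "H", "D", "E", "N", "Q"),
                            extra_unstable = character(0)) {
  unstable <- union(unstable, extra_unstable)
  if (!all(unstable %in% AA_STANDARD))
    stop("unknown residue(s) in stability table: ",
         paste(setdiff(unstable, AA_STANDARD), collapse = ", "))
  stats::setNames(ifelse(AA_STANDARD %in% unstable, "unstable", "stable"),
                  AA_STANDARD)
}

.is_unstable <- function(res, stability) {
  !is.na(res) & res %in% names(stability) & stability[res] == "unstable"
}

#' Enumerate candidate intermediate/mature terminus pairs
#'
#' All ordered pairs of peptides of one protein whose starts differ by
#' 1..`max_offset` residues; the offset is the number of residues spanned
#' between the upstream (intermediate) and downstream (mature) terminus.
#'
#' @param peptides Mapped peptides of a single protein.
#' @param max_offset Largest removable segment considered (2 for ICP55,
#'   20 for OCT1).
#' @return data.frame with `up` and `down` row indices into `peptides` and
#'   the `offset`; zero rows when no pair exists.
#' @export
pair_candidate_termini <- function(peptides, max_offset) {
  n <- nrow(peptides)
  out <- list()
  if (n >= 2L) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        off <- peptides$start[j] - peptides$start[i]
        if (off >= 1L && off <= max_offset)
          out[[length(out) + 1L]] <- c(i, j, off)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(up = integer(0), down = integer(0), offset = integer(0)))
  m <- do.call(rbind, out)
  data.frame(up = m[, 1], down = m[, 2], offset = m[, 3])
}

.call_row <- function(accession, peptidase, tier, evidence, removed,
                      intermediate_start, mature_start, fold, comparisons) {
  data.frame(accession = accession, peptidase = peptidase, tier = tier,
             evidence = evidence, removed = removed,
             intermediate_start = intermediate_start,
             mature_start = mature_start, fold = fold,
             comparisons_supporting = comparisons, stringsAsFactors = FALSE)
}

.EVIDENCE_RANK <- c(paired = 3, single_down = 2, single_up = 1, ladder = 3)

.dedupe_calls <- function(calls) {
  if (nrow(calls) == 0L) return(calls)
  ord <- order(calls$accession,
               -.EVIDENCE_RANK[calls$evidence],
               -calls$fold,
               -nchar(calls$removed),
               calls$intermediate_start)
  calls <- calls[ord, , drop = FALSE]
  calls <- calls[!duplicated(calls$accession), , drop = FALSE]
  rownames(calls) <- NULL
  calls[order(calls$accession), , drop = FALSE]
}

#' Call ICP55 substrates
#'
#' Rules, applied per protein in order:
#' \describe{
#'   \item{paired}{a pair of termini 1-2 residues apart where the upstream
#'     peptide is upregulated in the knockout (ratio >= fold) or the
#'     downstream peptide is downregulated (ratio <= 1/fold); the removed
#'     residues are the protein subsequence spanned by the pair.}
#'   \item{single_up}{a lone upregulated peptide whose first residue is
#'     destabilizing: the knockout exposes an unstable terminus that ICP55
#'     would have removed.}
#'   \item{single_down}{a lone downregulated peptide whose preceding protein
#'     residue is destabilizing: the wild-type mature terminus depleted in
#'     the knockout.}
#' }
#' Calls qualify at `secondary_fold` and are tiered by the maximal supporting
#' fold change: `primary` at or above `primary_fold`, `secondary` below it.
#' One call is kept per protein (paired > single_down > single_up, then
#' larger fold, then longer removal).
#'
#' @param peptides Mapped peptide data.frame.
#' @param proteins Protein data.frame with sequences.
#' @param stability Stability table from [stability_table()].
#' @param primary_fold Primary-tier fold-change threshold (inclusive).
#' @param secondary_fold Minimum fold change to call at all (inclusive).
#' @param max_offset Largest removal covered by pairing (default 2, covering
#'   the observed two-residue removals).
#' @param comparison `comparison_id` of the knockout/wild-type comparison.
#' @param exclude_acetylated Drop endogenously acetylated termini from the
#'   evidence (they mark in-vivo blocked termini, not free intermediates).
#' @return data.frame of substrate calls (one row per protein).
#' @export
call_icp55 <- function(peptides, proteins, stability = stability_table(),
                       primary_fold = 3, secondary_fold = 1.5,
                       max_offset = 2, comparison = "icp55",
                       exclude_acetylated = TRUE) {
  peptides <- peptides[peptides$comparison_id == comparison, , drop = FALSE]
  if (exclude_acetylated)
    peptides <- peptides[peptides$nterm_mod != "acetyl", , drop = FALSE]
  if (any(is.na(peptides$start))) stop("peptides must be mapped before calling")
  seqs <- stats::setNames(proteins$sequence, proteins$accession)
  calls <- list()
  for (acc in unique(peptides$accession)) {
    pp <- peptides[peptides$accession == acc, , drop = FALSE]
    seq <- seqs[[acc]]
    if (is.null(seq)) stop("no protein sequence for accession ", acc)
    pairs <- pair_candidate_termini(pp, max_offset)
    in_pair <- rep(FALSE, nrow(pp))
    if (nrow(pairs) > 0L) in_pair[unique(c(pairs$up, pairs$down))] <- TRUE
    for (k in seq_len(nrow(pairs))) {
      up <- pp[pairs$up[k], ]
      dn <- pp[pairs$down[k], ]
      qual <- c(
        if (up$ratio_mut_over_wt >= secondary_fold) up$ratio_mut_over_wt,
        if (dn$ratio_mut_over_wt <= 1 / secondary_fold) 1 / dn$ratio_mut_over_wt)
      if (length(qual) == 0L) next
      fold <- max(qual)
      calls[[length(calls) + 1L]] <- .call_row(
        acc, "ICP55",
        if (fold >= primary_fold) "primary" else "secondary",
        "paired", substr(seq, up$start, dn$start - 1L),
        up$start, dn$start, fold, comparison)
    }
    lone <- pp[!in_pair, , drop = FALSE]
    for (k in seq_len(nrow(lone))) {
      p <- lone[k, ]
      r <- p$ratio_mut_over_wt
      first <- substr(p$peptide, 1L, 1L)
      if (r >= secondary_fold && .is_unstable(first, stability)) {
        calls[[length(calls) + 1L]] <- .call_row(
          acc, "ICP55", if (r >= primary_fold) "primary" else "secondary",
          "single_up", first, p$start, p$start + 1L, r, comparison)
      } else if (r <= 1 / secondary_fold) {
        if (p$start == 1L) {
          message("single_down rule skipped for ", acc,
                  ": peptide starts at residue 1 (no preceding residue)")
          next
        }
        prev <- substr(seq, p$start - 1L, p$start - 1L)
        if (.is_unstable(prev, stability)) {
          calls[[length(calls) + 1L]] <- .call_row(
            acc, "ICP55", if (1 / r >= primary_fold) "primary" else "secondary",
            "single_down", prev, p$start - 1L, p$start, 1 / r, comparison)
        }
      }
    }
  }
  .dedupe_calls(do.call(rbind, c(calls, list(.call_row(
    character(0), character(0), character(0), character(0), character(0),
    integer(0), integer(0), numeric(0), character(0))))))
}

#' Call OCT1 substrates
#'
#' A protein is called when at least `min_lines` knockout lines show a
#' peptide at or beyond the fold-change threshold in either direction.
#' Removed segments are inferred from paired termini (an upregulated
#' intermediate upstream of a downregulated mature terminus, up to
#' `max_offset` residues apart) when both directions are seen; otherwise the
#' evidence class records the single direction and the removal is left
#' undetermined.
#'
#' @param peptides Mapped peptide data.frame covering the knockout-line
#'   comparisons.
#' @param proteins Protein data.frame.
#' @param fold Fold-change threshold (inclusive, both directions).
#' @param min_lines Knockout lines required to support a call (default 1;
#'   set 2 for a strict mode).
#' @param max_offset Largest removable segment for pairing (default 20).
#' @param comparisons `comparison_id` values of the knockout lines.
#' @param exclude_acetylated Drop acetylated termini from the evidence.
#' @return data.frame of substrate calls with supporting lines recorded.
#' @export
call_oct1 <- function(peptides, proteins, fold = 3, min_lines = 1,
                      max_offset = 20, comparisons = c("oct1_1", "oct1_2"),
                      exclude_acetylated = TRUE) {
  peptides <- peptides[peptides$comparison_id %in% comparisons, , drop = FALSE]
  if (exclude_acetylated)
    peptides <- peptides[peptides$nterm_mod != "acetyl", , drop = FALSE]
  if (any(is.na(peptides$start))) stop("peptides must be mapped before calling")
  seqs <- stats::setNames(proteins$sequence, proteins$accession)
  is_up <- peptides$ratio_mut_over_wt >= fold
  is_dn <- peptides$ratio_mut_over_wt <= 1 / fold
  calls <- list()
  for (acc in unique(peptides$accession)) {
    sel <- peptides$accession == acc
    pp <- peptides[sel, , drop = FALSE]
    up <- pp[is_up[sel], , drop = FALSE]
    dn <- pp[is_dn[sel], , drop = FALSE]
    supporting <- sort(unique(pp$comparison_id[is_up[sel] | is_dn[sel]]))
    if (length(supporting) < min_lines) next
    max_fold <- max(c(up$ratio_mut_over_wt, 1 / dn$ratio_mut_over_wt))
    seq <- seqs[[acc]]
    paired <- FALSE
    if (nrow(up) > 0L && nrow(dn) > 0L) {
      i_start <- min(up$start)
      m_start <- max(dn$start)
      off <- m_start - i_start
      if (off >= 1L && off <= max_offset) {
        paired <- TRUE
        calls[[length(calls) + 1L]] <- .call_row(
          acc, "OCT1", "primary", "paired",
          substr(seq, i_start, m_start - 1L), i_start, m_start, max_fold,
          paste(supporting, collapse = ","))
      }
    }
    if (!paired) {
      if (nrow(dn) > 0L) {
        calls[[length(calls) + 1L]] <- .call_row(
          acc, "OCT1", "primary", "single_down", "",
          NA_integer_, min(dn$start), max_fold,
          paste(supporting, collapse = ","))
      } else {
        calls[[length(calls) + 1L]] <- .call_row(
          acc, "OCT1", "primary", "single_up", "",
          min(up$start), NA_integer_, max_fold,
          paste(supporting, collapse = ","))
      }
    }
  }
  out <- do.call(rbind, c(calls, list(.call_row(
    character(0), character(0), character(0), character(0), character(0),
    integer(0), integer(0), numeric(0), character(0)))))
  rownames(out) <- NULL
  out[order(out$accession), , drop = FALSE]
}

#' Detect sequential-cleavage ladders
#'
#' Maximal chains of three or more termini of one protein with consecutive or
#' near-consecutive starts (gap at most `max_gap`) whose regulation is
#' non-increasing from upstream to downstream (intermediates up in the
#' knockout, mature products down), the signature of a peptidase cleaving
#' residue by residue.
#'
#' @param peptides Mapped peptides of one comparison.
#' @param proteins Optional protein data.frame; when given, the removed
#'   residue path spanned by each ladder is reported.
#' @param max_gap Largest start-to-start gap inside a chain.
#' @param min_length Minimum chain length (default 3).
#' @param comparison Restrict to one `comparison_id` (NULL = use all rows).
#' @return data.frame with one row per ladder: accession, first/last start,
#'   number of termini, and the removed-residue path.
#' @export
detect_ladders <- function(peptides, proteins = NULL, max_gap = 2,
                           min_length = 3, comparison = NULL) {
  if (!is.null(comparison))
    peptides <- peptides[peptides$comparison_id == comparison, , drop = FALSE]
  seqs <- if (is.null(proteins)) NULL else
    stats::setNames(proteins$sequence, proteins$accession)
  out <- list()
  for (acc in unique(peptides$accession)) {
    pp <- peptides[peptides$accession == acc, , drop = FALSE]
    pp <- pp[order(pp$start), , drop = FALSE]
    pp <- pp[!duplicated(pp$start), , drop = FALSE]
    if (nrow(pp) < min_length) next
    runs <- split(seq_len(nrow(pp)),
                  cumsum(c(1L, diff(pp$start) > max_gap)))
    for (run in runs) {
      if (length(run) < min_length) next
      ratios <- pp$ratio_mut_over_wt[run]
      if (any(diff(ratios) > 1e-9)) next  # regulation must not increase downstream
      first <- pp$start[run[1]]
      last <- pp$start[run[length(run)]]
      path <- if (is.null(seqs) || is.null(seqs[[acc]])) NA_character_
              else substr(seqs[[acc]], first, last - 1L)
      out[[length(out) + 1L]] <- data.frame(
        accession = acc, start_first = first, start_last = last,
        n_termini = length(run), removed_path = path,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(accession = character(0), start_first = integer(0),
                      start_last = integer(0), n_termini = integer(0),
                      removed_path = character(0)))
  do.call(rbind, out)
}
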