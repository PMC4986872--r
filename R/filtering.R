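# Curation of credible N-terminal peptides: the three criteria used to turn
# a raw identified-peptide list into per-protein N-terminus assignments.

.empty_discard <- function(peptides) {
  d <- peptides[0, , drop = FALSE]
  d$reason <- character(0)
  d
}

#' Keep peptides from proteins with the required localization
#'
#' Peptides are kept iff their accession carries the required consensus
#' label. Accessions absent from the map are discarded with reason
#' `"no_localization"`.
#'
#' @param peptides Mapped peptide data.frame.
#' @param localization Named character vector, accession -> label.
#' @param required_label Label to require (default `"mitochondrial"`).
#' @return List with `kept` and `discarded` (the latter with a `reason`
#'   column); together they partition the input.
#' @export
filter_localization <- function(peptides, localization,
                                required_label = "mitochondrial") {
  lab <- localization[peptides$accession]
  reason <- rep(NA_character_, nrow(peptides))
  reason[is.na(lab)] <- "no_localization"
  reason[!is.na(lab) & lab != required_label] <- "wrong_localization"
  ok <- is.na(reason)
  discarded <- peptides[!ok, , drop = FALSE]
  discarded$reason <- reason[!ok]
  list(kept = peptides[ok, , drop = FALSE], discarded = discarded)
}

#' Discard peptides starting beyond a position cutoff
#'
#' Peptides identified after the cutoff residue of the full-length protein
#' are treated as internal degradation products. The boundary is
#' inclusive-keep: a start equal to `max_start` survives, a start of
#' `max_start + 1` ("after the 120th residue" with the default) is discarded.
#'
#' @param peptides Mapped peptide data.frame; unmapped starts are an error.
#' @param max_start Largest credible start position (default 120).
#' @return List with `kept` and `discarded`.
#' @export
filter_start_position <- function(peptides, max_start = 120) {
  if (any(is.na(peptides$start)))
    stop("filter_start_position requires mapped peptides (NA start found)")
  ok <- peptides$start <= max_start
  discarded <- peptides[!ok, , drop = FALSE]
  if (nrow(discarded) > 0L) discarded$reason <- "start_beyond_cutoff"
  else discarded <- .empty_discard(peptides)
  list(kept = peptides[ok, , drop = FALSE], discarded = discarded)
}

#' Select the representative N-terminus per protein
#'
#' The most N-terminal peptide of each protein defines its mature start;
#' ties at the minimal start all remain as evidence. Peptides with larger
#' starts are normally internal and dropped, with one exception: peptides
#' whose abundance differs between genotypes (ratio at or beyond the
#' differential threshold in either direction, in any comparison) are
#' retained, because differential downstream termini are processing
#' intermediates, not degradation.
#'
#' @param peptides Curated, mapped peptide data.frame.
#' @param differential_threshold Fold change treated as differential
#'   (default 3; the exception rule reuses the global substrate threshold).
#' @return List with `assignments` (accession, mature_start, n_evidence),
#'   `evidence` (peptides at the minimal start), `retained` (differential
#'   non-minimal peptides), and `dropped` (internal peptides).
#' @export
select_representative_ntermini <- function(peptides, differential_threshold = 3) {
  if (nrow(peptides) == 0L) stop("no peptides to assign N-termini from")
  if (any(is.na(peptides$start))) stop("peptides must be mapped")
  acc <- unique(peptides$accession)
  min_start <- vapply(acc, function(a)
    min(peptides$start[peptides$accession == a]), integer(1))
  assignments <- data.frame(accession = acc,
                            mature_start = unname(min_start),
                            stringsAsFactors = FALSE)
  is_min <- peptides$start == min_start[peptides$accession]
  diff <- peptides$ratio_mut_over_wt >= differential_threshold |
    peptides$ratio_mut_over_wt <= 1 / differential_threshold
  evidence <- peptides[is_min, , drop = FALSE]
  retained <- peptides[!is_min & diff, , drop = FALSE]
  dropped <- peptides[!is_min & !diff, , drop = FALSE]
  if (nrow(dropped) > 0L) dropped$reason <- "internal_non_differential"
  else dropped <- .empty_discard(peptides)
  assignments$n_evidence <- vapply(assignments$accession, function(a)
    sum(evidence$accession == a), integer(1))
  rownames(assignments) <- NULL
  list(assignments = assignments, evidence = evidence,
       retained = retained, dropped = dropped)
}

#' Classify presequence status of N-terminus assignments
#'
#' A protein whose mature start is at residue 1 or 2 (initiator methionine
#' retained or removed) carries no cleavable presequence; anything further in
#' is a processed protein and the residues upstream of the mature start are
#' its presequence.
#'
#' @param assignments Assignment data.frame from
#'   [select_representative_ntermini()].
#' @param proteins Protein data.frame used to attach presequence strings.
#' @return The assignments with `status` (`"processed"`/`"no_presequence"`)
#'   and `presequence` columns added.
#' @export
classify_presequence_status <- function(assignments, proteins) {
  seqs <- stats::setNames(proteins$sequence, proteins$accession)
  assignments$status <- ifelse(assignments$mature_start <= 2L,
                               "no_presequence", "processed")
  assignments$presequence <- vapply(seq_len(nrow(assignments)), function(i) {
    m <- assignments$mature_start[i]
    if (m <= 2L) return("")
    s <- seqs[[assignments$accession[i]]]
    if (is.null(s)) stop("no sequence for accession ", assignments$accession[i])
    substr(s, 1L, m - 1L)
  }, character(1))
  assignments
}

#' Run the full N-terminus curation
#'
#' Applies the three criteria in order (localization, start-position cutoff,
#' most-N-terminal selection with the differential exception) and reports
#' per-stage counts. Acetylated and dimethylated N-termini are curated
#' jointly.
#'
#' @param peptides Mapped peptide data.frame (all comparisons together).
#' @param localization Named accession -> label vector.
#' @param proteins Protein data.frame.
#' @param required_label Localization label to require.
#' @param max_start Start-position cutoff.
#' @param differential_threshold Differential-exception fold change.
#' @return List with `assignments`, `kept` (evidence plus retained
#'   differential peptides), `discarded` (all removed peptides with reasons),
#'   and `report` (stage counts: n_input, n_after_localization,
#'   n_after_position, n_final).
#' @export
curate_ntermini <- function(peptides, localization, proteins,
                            required_label = "mitochondrial",
                            max_start = 120, differential_threshold = 3) {
  n_input <- nrow(peptides)
  st1 <- filter_localization(peptides, localization, required_label)
  st2 <- filter_start_position(st1$kept, max_start)
  st3 <- select_representative_ntermini(st2$kept, differential_threshold)
  assignments <- classify_presequence_status(st3$assignments, proteins)
  kept <- rbind(st3$evidence, st3$retained)
  discarded <- rbind(st1$discarded, st2$discarded, st3$dropped)
  report <- data.frame(
    n_input = n_input,
    n_after_localization = nrow(st1$kept),
    n_after_position = nrow(st2$kept),
    n_final = nrow(kept))
  stopifnot(n_input == nrow(kept) + nrow(discarded))
  list(assignments = assignments, kept = kept, discarded = discarded,
       report = report)
}
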