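# End-to-end orchestration: ingest -> map -> curate -> call substrates ->
# motifs -> presequence properties, with every intermediate returned (and
# optionally written) so any stage can be re-run in isolation.

#' Run the full N-terminomics analysis
#'
#' @param peptides Quantified peptide data.frame covering all comparisons
#'   (mapped or unmapped; unmapped peptides are located first).
#' @param proteins Protein data.frame (accession, sequence).
#' @param localization Named accession -> label vector.
#' @param icp55_comparison,oct1_comparisons `comparison_id` values of the
#'   knockout/wild-type comparisons.
#' @param primary_fold,secondary_fold Substrate-calling fold thresholds.
#' @param max_start Start-position curation cutoff.
#' @param stability Residue stability table for the single-terminus rules.
#' @param oct1_min_lines Knockout lines required for an OCT1 call.
#' @param alpha iceLogo per-cell significance level.
#' @param out_dir Optional directory; when given, all result tables are
#'   written as tab-separated text.
#' @return List with `mapping` (mapping diagnostics), `curated` (assignments,
#'   kept/discarded peptides, stage report), `calls_icp55`, `calls_oct1`,
#'   `ladders`, `motif_icp55`, `motif_oct1` (profiles with differentials and
#'   `consensus` strings), and `properties` (group statistics of the derived
#'   presequences).
#' @export
run_pipeline <- function(peptides, proteins, localization,
                         icp55_comparison = "icp55",
                         oct1_comparisons = c("oct1_1", "oct1_2"),
                         primary_fold = 3, secondary_fold = 1.5,
                         max_start = 120,
                         stability = stability_table(),
                         oct1_min_lines = 1, alpha = 0.05,
                         out_dir = NULL) {
  if (nrow(peptides) == 0L) stop("ingest: empty peptide table")
  mapping <- if (any(is.na(peptides$start)))
    map_peptides_to_proteins(peptides, proteins)
  else list(mapped = peptides, unmapped = peptides[0, , drop = FALSE])
  curated <- curate_ntermini(mapping$mapped, localization, proteins,
                             max_start = max_start,
                             differential_threshold = primary_fold)
  kept <- curated$kept
  calls_icp55 <- call_icp55(kept, proteins, stability = stability,
                            primary_fold = primary_fold,
                            secondary_fold = secondary_fold,
                            comparison = icp55_comparison)
  calls_oct1 <- call_oct1(kept, proteins, fold = primary_fold,
                          min_lines = oct1_min_lines,
                          comparisons = oct1_comparisons)
  ladders <- do.call(rbind, lapply(
    c(icp55_comparison, oct1_comparisons), function(cmp)
      detect_ladders(kept, proteins, comparison = cmp)))

  ref <- reference_frequencies(proteins)
  seqs <- stats::setNames(proteins$sequence, proteins$accession)
  motif_icp55 <- NULL
  if (nrow(calls_icp55) > 0L) {
    win <- vapply(seq_len(nrow(calls_icp55)), function(i)
      extract_window(seqs[[calls_icp55$accession[i]]],
                     calls_icp55$mature_start[i]), character(1))
    motif_icp55 <- icelogo_diff(build_pfm(win), ref, alpha)
    motif_icp55$consensus <- consensus_string(motif_icp55)
  }
  motif_oct1 <- NULL
  if (nrow(calls_oct1) > 0L) {
    anchor <- ifelse(is.na(calls_oct1$mature_start),
                     calls_oct1$intermediate_start, calls_oct1$mature_start)
    win <- vapply(seq_len(nrow(calls_oct1)), function(i)
      extract_window(seqs[[calls_oct1$accession[i]]], anchor[i]), character(1))
    motif_oct1 <- icelogo_diff(build_pfm(win), ref, alpha)
    motif_oct1$consensus <- consensus_string(motif_oct1)
  }

  processed <- curated$assignments[curated$assignments$status == "processed", ]
  properties <- if (nrow(processed) > 0L)
    group_stats(data.frame(group = "observed",
                           sequence = processed$presequence,
                           stringsAsFactors = FALSE))
  else NULL

  result <- list(mapping = mapping, curated = curated,
                 calls_icp55 = calls_icp55, calls_oct1 = calls_oct1,
                 ladders = ladders, motif_icp55 = motif_icp55,
                 motif_oct1 = motif_oct1, properties = properties)
  if (!is.null(out_dir)) .write_pipeline_outputs(result, out_dir)
  result
}

.write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    if (!is.null(df) && nrow(df) > 0L)
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  wt(result$mapping$unmapped, "unmapped_peptides.tsv")
  wt(result$curated$assignments, "nterm_assignments.tsv")
  wt(result$curated$discarded, "discarded_peptides.tsv")
  wt(result$curated$report, "filter_report.tsv")
  wt(result$calls_icp55, "calls_icp55.tsv")
  wt(result$calls_oct1, "calls_oct1.tsv")
  wt(result$ladders, "ladders.tsv")
  for (m in c("motif_icp55", "motif_oct1")) {
    if (!is.null(result[[m]])) {
      write_motif_profile(result[[m]], file.path(out_dir, m))
      writeLines(as.character(result[[m]]$consensus),
                 file.path(out_dir, paste0(m, "_consensus.txt")))
    }
  }
  if (!is.null(result$properties)) {
    wt(result$properties$summary, "presequence_summary.tsv")
    utils::write.table(result$properties$frequencies,
                       file.path(out_dir, "presequence_frequencies.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  invisible(out_dir)
}
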