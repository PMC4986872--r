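# Cleavage-site motif analysis: aligned sequence windows around the mature
# N-terminus, position frequency matrices, iceLogo-style reference
# differentials with per-cell significance, and consensus motif strings.
#
# Window convention: positions -20..-1 are the last presequence residues
# (-1 immediately precedes the cleavage), +1..+10 the first mature residues;
# the cleavage arrow sits between -1 and +1.

.window_labels <- function(up = 20, down = 10) as.character(c(-up:-1, seq_len(down)))

#' Extract an aligned cleavage-site window
#'
#' Residues `mature_start - up .. mature_start + down - 1` of the protein,
#' padded with `'-'` where the presequence is shorter than `up` residues or
#' the sequence ends before `down` mature residues.
#'
#' @param sequence Protein sequence string.
#' @param mature_start 1-based position of the first mature residue.
#' @param up,down Residues taken upstream/downstream of the cleavage.
#' @return A single string of width `up + down`.
#' @export
extract_window <- function(sequence, mature_start, up = 20, down = 10) {
  n <- nchar(sequence)
  if (mature_start < 1L || mature_start > n)
    stop("mature_start ", mature_start, " outside sequence of length ", n)
  left <- substr(sequence, max(1L, mature_start - up), mature_start - 1L)
  left <- paste0(strrep("-", up - nchar(left)), left)
  right <- substr(sequence, mature_start, min(n, mature_start + down - 1L))
  right <- paste0(right, strrep("-", down - nchar(right)))
  paste0(left, right)
}

#' Build a position frequency matrix from aligned windows
#'
#' Pad characters are excluded both from the counts and from the per-position
#' observation count, so frequencies at each position are taken over the
#' windows that actually reach it.
#'
#' @param windows Character vector of equal-width windows from
#'   [extract_window()].
#' @param up,down Window geometry (defaults 20/10 as in the windows).
#' @return An object of class `motif_profile`: residue-by-position `counts`
#'   matrix, per-position observation count `n`, per-position `freq`, and
#'   `n_windows`.
#' @export
build_pfm <- function(windows, up = 20, down = 10) {
  if (length(windows) == 0L) stop("no windows supplied")
  w <- up + down
  if (any(nchar(windows) != w))
    stop("all windows must have width ", w)
  mat <- do.call(rbind, strsplit(windows, ""))
  counts <- matrix(0L, nrow = length(AA_STANDARD), ncol = w,
                   dimnames = list(AA_STANDARD, .window_labels(up, down)))
  for (p in seq_len(w)) {
    tab <- table(factor(mat[, p], levels = AA_STANDARD))
    counts[, p] <- as.integer(tab)
  }
  n <- colSums(counts)
  freq <- sweep(counts, 2, pmax(n, 1L), "/")
  freq[, n == 0L] <- NA_real_
  structure(list(counts = counts, n = n, freq = freq,
                 n_windows = length(windows), up = up, down = down),
            class = "motif_profile")
}

#' Position-independent residue frequencies of a proteome
#'
#' The iceLogo reference set: amino-acid frequencies over all supplied
#' protein sequences ('X' excluded).
#'
#' @param proteins Protein data.frame with a `sequence` column.
#' @return Named numeric vector over the 20 residues, summing to 1.
#' @export
reference_frequencies <- function(proteins) {
  chars <- unlist(strsplit(paste(proteins$sequence, collapse = ""), ""))
  tab <- table(factor(chars[chars %in% AA_STANDARD], levels = AA_STANDARD))
  stats::setNames(as.numeric(tab) / sum(tab), AA_STANDARD)
}

#' iceLogo reference differential with significance
#'
#' For every residue r and position p, the percentage-point difference
#' `(f_obs - f_ref) * 100` and a two-sided one-sample proportion z-test of
#' the observed count at that position against the reference frequency,
#' with variance `f_ref (1 - f_ref) / n_p`. Positions observed in no window
#' are left undefined. No multiple-testing correction is applied across
#' cells, mirroring iceLogo's own convention.
#'
#' @param profile A `motif_profile` from [build_pfm()].
#' @param ref Reference frequencies from [reference_frequencies()].
#' @param alpha Per-cell significance level (default 0.05).
#' @return The profile with `ref`, `difference`, `z`, `p_value`,
#'   `significant` and `alpha` elements added.
#' @export
icelogo_diff <- function(profile, ref, alpha = 0.05) {
  stopifnot(inherits(profile, "motif_profile"))
  if (abs(sum(ref) - 1) > 1e-6) stop("reference frequencies must sum to 1")
  ref <- ref[AA_STANDARD]
  diff <- (profile$freq - ref) * 100
  se <- sqrt(outer(ref * (1 - ref), pmax(profile$n, 1L), "/"))
  z <- (profile$freq - ref) / se
  z[, profile$n == 0L] <- NA_real_
  p <- 2 * stats::pnorm(-abs(z))
  profile$ref <- ref
  profile$difference <- diff
  profile$z <- z
  profile$p_value <- p
  profile$significant <- !is.na(p) & p < alpha
  profile$alpha <- alpha
  profile
}

#' Consensus motif string
#'
#' At each position of interest, the residues whose observed frequency
#' reaches `freq_threshold` (and, when required, whose over-representation is
#' significant in the iceLogo differential) are listed in decreasing
#' frequency; `X` marks positions where none qualifies. The cleavage arrow is
#' printed between -1 and +1, e.g. `RX(F/Y)` followed by the arrow and
#' `(S/A)(S/T)`.
#'
#' @param profile A `motif_profile`; must carry significance annotations
#'   (see [icelogo_diff()]) when `require_significant` is TRUE.
#' @param freq_threshold Minimum observed frequency (default 0.20).
#' @param require_significant Additionally require a significant positive
#'   differential.
#' @param positions Window positions rendered (default -3..+2, the span of
#'   the motifs of interest).
#' @return The consensus string; attribute `per_position` holds the residue
#'   lists.
#' @export
consensus_string <- function(profile, freq_threshold = 0.20,
                             require_significant = TRUE,
                             positions = c(-3L, -2L, -1L, 1L, 2L)) {
  stopifnot(inherits(profile, "motif_profile"))
  if (require_significant && is.null(profile$significant))
    stop("profile lacks significance annotations; run icelogo_diff() first")
  lab <- as.character(positions)
  if (!all(lab %in% colnames(profile$freq)))
    stop("position(s) outside the window: ",
         paste(setdiff(lab, colnames(profile$freq)), collapse = ", "))
  per <- lapply(lab, function(p) {
    f <- profile$freq[, p]
    ok <- !is.na(f) & f >= freq_threshold
    if (require_significant)
      ok <- ok & profile$significant[, p] & profile$difference[, p] > 0
    res <- names(f)[ok]
    res[order(-f[ok])]
  })
  names(per) <- lab
  render <- vapply(per, function(res) {
    if (length(res) == 0L) "X"
    else if (length(res) == 1L) res
    else paste0("(", paste(res, collapse = "/"), ")")
  }, character(1))
  arrow_at <- sum(positions < 0)
  txt <- paste0(paste(render[seq_len(arrow_at)], collapse = ""), "\u2193",
                paste(render[-seq_len(arrow_at)], collapse = ""))
  structure(txt, per_position = per)
}

#' @export
print.motif_profile <- function(x, ...) {
  cat("motif_profile:", x$n_windows, "windows, positions",
      colnames(x$counts)[1], "..", colnames(x$counts)[ncol(x$counts)], "\n")
  if (!is.null(x$significant))
    cat("iceLogo differential attached (alpha =", x$alpha, ")\n")
  invisible(x)
}

#' Write motif profile matrices
#'
#' Writes counts, frequencies and (when present) differences and p-values as
#' separate tab-separated residue-by-position matrices.
#'
#' @param profile A `motif_profile`.
#' @param prefix Output path prefix; files `<prefix>_counts.tsv` etc. are
#'   created.
#' @return The file paths, invisibly.
#' @export
write_motif_profile <- function(profile, prefix) {
  parts <- list(counts = profile$counts, freq = profile$freq)
  if (!is.null(profile$difference)) {
    parts$difference <- profile$difference
    parts$p_value <- profile$p_value
  }
  paths <- character(0)
  for (nm in names(parts)) {
    path <- paste0(prefix, "_", nm, ".tsv")
    utils::write.table(parts[[nm]], path, sep = "\t", quote = FALSE,
                       col.names = NA)
    paths <- c(paths, path)
  }
  invisible(paths)
}
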