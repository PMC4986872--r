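# Independent oracles used by the tests. These deliberately re-derive the
# expected behaviour with naive code paths separate from the package
# implementation.

# Literal re-statement of the ICP55 calling rules: enumerate every ordered
# peptide pair by brute force, then the lone-peptide rules, then keep the
# strongest call per protein.
oracle_call_icp55 <- function(peptides, sequence, stability,
                              primary_fold = 3, secondary_fold = 1.5,
                              max_offset = 2) {
  n <- nrow(peptides)
  cand <- list()
  paired_members <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    off <- peptides$start[j] - peptides$start[i]
    if (off >= 1 && off <= max_offset) {
      paired_members[c(i, j)] <- TRUE
      folds <- c()
      if (peptides$ratio_mut_over_wt[i] >= secondary_fold)
        folds <- c(folds, peptides$ratio_mut_over_wt[i])
      if (peptides$ratio_mut_over_wt[j] <= 1 / secondary_fold)
        folds <- c(folds, 1 / peptides$ratio_mut_over_wt[j])
      if (length(folds) > 0) {
        cand[[length(cand) + 1]] <- list(
          evidence = "paired", fold = max(folds),
          removed = substr(sequence, peptides$start[i], peptides$start[j] - 1),
          intermediate = peptides$start[i], mature = peptides$start[j])
      }
    }
  }
  for (i in seq_len(n)) {
    if (paired_members[i]) next
    r <- peptides$ratio_mut_over_wt[i]
    first <- substr(peptides$peptide[i], 1, 1)
    if (r >= secondary_fold && stability[first] == "unstable") {
      cand[[length(cand) + 1]] <- list(
        evidence = "single_up", fold = r, removed = first,
        intermediate = peptides$start[i], mature = peptides$start[i] + 1)
    } else if (r <= 1 / secondary_fold && peptides$start[i] > 1) {
      prev <- substr(sequence, peptides$start[i] - 1, peptides$start[i] - 1)
      if (stability[prev] == "unstable") {
        cand[[length(cand) + 1]] <- list(
          evidence = "single_down", fold = 1 / r, removed = prev,
          intermediate = peptides$start[i] - 1, mature = peptides$start[i])
      }
    }
  }
  if (length(cand) == 0) return(NULL)
  rank <- c(paired = 3, single_down = 2, single_up = 1)
  best <- cand[[1]]
  for (c2 in cand[-1]) {
    better <- FALSE
    if (rank[c2$evidence] != rank[best$evidence])
      better <- rank[c2$evidence] > rank[best$evidence]
    else if (c2$fold != best$fold) better <- c2$fold > best$fold
    else if (nchar(c2$removed) != nchar(best$removed))
      better <- nchar(c2$removed) > nchar(best$removed)
    else better <- c2$intermediate < best$intermediate
    if (better) best <- c2
  }
  best$tier <- if (best$fold >= primary_fold) "primary" else "secondary"
  best
}

# normal-approximation tail of a binomial proportion, computed directly
oracle_prop_p <- function(count, n, p0) {
  z <- (count / n - p0) / sqrt(p0 * (1 - p0) / n)
  2 * stats::pnorm(-abs(z))
}

# random but consistent peptide sets over a random protein, for the
# brute-force equivalence checks
random_case <- function(seed) {
  set.seed(seed)
  sequence <- paste(sample(AA_STANDARD, 80, replace = TRUE), collapse = "")
  k <- sample(1:6, 1)
  start <- sample(2:50, k)
  len <- sample(8:15, k, replace = TRUE)
  ratio <- sample(c(0.01, 0.1, 0.4, 0.9, 1, 1.8, 2.5, 4, 30, 100), k,
                  replace = TRUE)
  peptides <- data.frame(
    accession = "CASE", peptide = substr(rep(sequence, k), start, start + len - 1),
    start = start, end = start + len - 1, nterm_mod = "dimethyl",
    comparison_id = "icp55", ratio_mut_over_wt = ratio, confidence = TRUE,
    stringsAsFactors = FALSE)
  list(sequence = sequence, peptides = peptides)
}
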