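# Forward simulator of mitochondrial presequence processing and of the
# quantified N-terminal peptide observations a charge-based N-terminal
# enrichment experiment would report. Every simulated protein carries its
# ground truth, so the downstream callers can be scored for parameter
# recovery.
#
# The processing model: an imported precursor is cleaved by MPP at the end
# of its presequence (with an arginine at -2 or -3 of the site, or no
# arginine); ICP55 substrates then lose one (rarely two) destabilizing
# residues, OCT1 substrates a longer segment. Knockouts freeze the cascade
# at the MPP intermediate; a B13-like minority of OCT1 substrates is not cut
# by MPP at all and matures only through OCT1.

# background amino-acid frequencies (approximate eukaryote proteome); the
# presequence table enriches R/S/A/L and depletes acidic residues
.BG_FREQ <- c(A = 0.080, C = 0.018, D = 0.053, E = 0.063, F = 0.040,
              G = 0.071, H = 0.022, I = 0.054, K = 0.058, L = 0.092,
              M = 0.022, N = 0.043, P = 0.050, Q = 0.040, R = 0.052,
              S = 0.072, T = 0.054, V = 0.066, W = 0.013, Y = 0.032)

.preseq_freq <- function() {
  w <- .BG_FREQ
  w[c("R", "S", "A", "L")] <- w[c("R", "S", "A", "L")] * c(2.0, 2.2, 1.6, 1.5)
  w[c("D", "E")] <- w[c("D", "E")] * 0.35
  w / sum(w)
}

.sample_seq <- function(n, freq) {
  if (n <= 0L) return("")
  paste(sample(names(freq), n, replace = TRUE, prob = freq), collapse = "")
}

.rtruncnorm_int <- function(n, mean, sd, lo, hi) {
  out <- integer(0)
  while (length(out) < n) {
    x <- round(stats::rnorm(2L * (n - length(out)), mean, sd))
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulation configuration
#'
#' Defaults are the study conditions the simulator emulates: half of the
#' proteins ICP55 substrates, a small OCT1 fraction, presequence lengths
#' from a truncated normal with mean 43.3 and range 7-117, a 3:2 split of
#' -3R over -2R sites among the classified ones, log-normal ratio noise and
#' a 100-fold reporting cap.
#'
#' @param n_proteins Number of simulated proteins.
#' @param fraction_mito Probability that a non-substrate protein is
#'   mitochondrial (substrates always are).
#' @param fraction_icp55_substrate,fraction_oct1_substrate Probability that
#'   a protein is a substrate of the respective peptidase (mutually
#'   exclusive; the sum must stay below 1).
#' @param fraction_no_presequence Probability that a mitochondrial
#'   non-substrate lacks a cleavable presequence.
#' @param mpp_class_weights Probabilities of the -3R / -2R / no-R site
#'   classes for non-ICP55 proteins.
#' @param preseq_mean,preseq_sd,preseq_min,preseq_max Truncated-normal
#'   presequence length distribution (residues).
#' @param two_residue_prob Probability that an ICP55 substrate loses two
#'   residues instead of one.
#' @param mpp_independent_prob Probability that an OCT1 substrate is matured
#'   by OCT1 alone, without MPP (B13-like), from residue 2.
#' @param ratio_noise_sd Standard deviation of Gaussian noise on log2
#'   mutant/wild-type ratios.
#' @param ratio_cap Largest reported fold change; termini absent from one
#'   channel are reported at the cap.
#' @param leak Residual abundance of the unprocessed intermediate species.
#' @param peptide_min,peptide_max Reported N-terminal peptide length bounds;
#'   peptides end at the first arginine reachable within them (lysines are
#'   dimethyl-blocked, so only R is cut).
#' @param seed Integer seed; all outputs are deterministic given it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 200, fraction_mito = 0.8,
                       fraction_icp55_substrate = 0.5,
                       fraction_oct1_substrate = 0.05,
                       fraction_no_presequence = 0.2,
                       mpp_class_weights = c("-3R" = 0.55, "-2R" = 0.25,
                                             "no-R" = 0.20),
                       preseq_mean = 43.3, preseq_sd = 20,
                       preseq_min = 7, preseq_max = 117,
                       two_residue_prob = 0.1,
                       mpp_independent_prob = 0.15,
                       ratio_noise_sd = 0.2, ratio_cap = 100, leak = 0.02,
                       peptide_min = 7, peptide_max = 45, seed = 1) {
  cfg <- as.list(environment())
  probs <- c(fraction_mito, fraction_icp55_substrate, fraction_oct1_substrate,
             fraction_no_presequence, two_residue_prob, mpp_independent_prob,
             leak)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (fraction_icp55_substrate + fraction_oct1_substrate > 1)
    stop("substrate fractions must sum to at most 1")
  if (abs(sum(mpp_class_weights) - 1) > 1e-9)
    stop("mpp_class_weights must sum to 1")
  if (any(mpp_class_weights < 0)) stop("mpp_class_weights must be non-negative")
  if (ratio_cap < 1) stop("ratio_cap must be >= 1")
  if (preseq_sd <= 0 || preseq_min < 1 || preseq_max < preseq_min)
    stop("invalid presequence length distribution")
  if (n_proteins < 1) stop("n_proteins must be positive")
  structure(cfg, class = "sim_config")
}

.UNSTABLE_FIRST <- c("F", "Y", "L", "I")

#' Generate a ground-truthed synthetic proteome
#'
#' Presequences are drawn from a fixed composition table enriched in R, S, A
#' and L; ICP55 substrates receive a destabilizing residue at the MPP site
#' and an arginine three residues upstream of the final mature start (the
#' -3R environment of the cleavage motif), followed by a small/hydroxylated
#' mature start. Presequence-less proteins keep or lose the initiator
#' methionine (probability 0.5 of removal when residue 2 is small).
#'
#' @param config A [sim_config()].
#' @return data.frame of class `sim_proteome`, one protein per row, with the
#'   full ground truth (`type`, `mpp_site`, `mpp_class`, `icp55_removed`,
#'   `oct1_removed_len`, `has_presequence`, `imet_removed`).
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pw <- .preseq_freq()
  n <- config$n_proteins
  rows <- vector("list", n)
  type <- sample(c("icp55", "oct1", "none"), n, replace = TRUE,
                 prob = c(config$fraction_icp55_substrate,
                          config$fraction_oct1_substrate,
                          1 - config$fraction_icp55_substrate -
                            config$fraction_oct1_substrate))
  for (i in seq_len(n)) {
    acc <- sprintf("SIM%05d", i)
    ty <- type[i]
    loc <- if (ty != "none" || stats::runif(1) < config$fraction_mito)
      "mitochondrial" else sample(c("plastid", "other"), 1L)
    has_pre <- TRUE
    imet <- FALSE
    mpp_class <- "none"
    mpp_site <- NA_integer_
    icp_removed <- ""
    oct_len <- 0L
    mat_len <- sample(150:300, 1L)
    mature <- strsplit(.sample_seq(mat_len, .BG_FREQ), "")[[1]]
    if (ty == "none" && (loc != "mitochondrial" ||
                         stats::runif(1) < config$fraction_no_presequence)) {
      has_pre <- FALSE
      if (mature[1] %in% c("A", "S", "T", "G", "V", "C", "P"))
        imet <- stats::runif(1) < 0.5
      sequence <- paste0("M", paste(mature, collapse = ""))
      rows[[i]] <- data.frame(
        accession = acc, sequence = sequence, location_label = loc,
        type = ty, has_presequence = FALSE, imet_removed = imet,
        mpp_site = NA_integer_, mpp_class = "none", icp55_removed = "",
        oct1_removed_len = 0L, stringsAsFactors = FALSE)
      next
    }
    if (ty == "oct1" && stats::runif(1) < config$mpp_independent_prob) {
      # B13-like: no MPP site; OCT1 removes a short leader from residue 2
      oct_len <- sample(6:19, 1L)
      mature[1] <- sample(c("F", "I", "L"), 1L)  # unstable without cleavage
      sequence <- paste0("M", paste(mature, collapse = ""))
      rows[[i]] <- data.frame(
        accession = acc, sequence = sequence, location_label = loc,
        type = ty, has_presequence = TRUE, imet_removed = FALSE,
        mpp_site = NA_integer_, mpp_class = "none", icp55_removed = "",
        oct1_removed_len = oct_len, stringsAsFactors = FALSE)
      next
    }
    L <- .rtruncnorm_int(1L, config$preseq_mean, config$preseq_sd,
                         config$preseq_min, config$preseq_max)
    pre <- strsplit(.sample_seq(L, pw), "")[[1]]
    pre[1] <- "M"
    mpp_site <- L + 1L
    if (ty == "icp55") {
      k <- 1L + stats::rbinom(1L, 1L, config$two_residue_prob)
      removed <- sample(.UNSTABLE_FIRST, 1L, prob = c(0.5, 0.25, 0.15, 0.1))
      if (k == 2L) removed <- paste0(removed, sample(c("C", "T", "N"), 1L))
      icp_removed <- removed
      rem <- strsplit(removed, "")[[1]]
      mature[seq_len(k)] <- rem
      mature[k + 1L] <- sample(c("S", "A"), 1L, prob = c(0.7, 0.3))
      mature[k + 2L] <- sample(c("S", "T"), 1L)
      # plant R three residues upstream of the final mature start
      r_at <- mpp_site + k - 3L
      if (r_at >= 2L && r_at <= L) pre[r_at] <- "R"
    } else {
      mpp_class <- sample(names(config$mpp_class_weights), 1L,
                          prob = config$mpp_class_weights)
      if (mpp_class == "-3R" && L >= 3L) pre[L - 2L] <- "R"
      if (mpp_class == "-2R" && L >= 2L) pre[L - 1L] <- "R"
      if (ty == "oct1") {
        oct_len <- sample(5:17, 1L)
        mature[1] <- sample(c("F", "I", "L"), 1L)
        mature[oct_len + 1L] <- sample(c("S", "A", "G"), 1L)
      } else {
        mature[1] <- sample(c("S", "A", "T", "G", "V"), 1L)
      }
    }
    sequence <- paste0(paste(pre, collapse = ""), paste(mature, collapse = ""))
    # record the class actually realized in the sequence
    chars <- strsplit(sequence, "")[[1]]
    mpp_class <- if (mpp_site >= 3L && chars[mpp_site - 2L] == "R") "-2R"
      else if (mpp_site >= 4L && chars[mpp_site - 3L] == "R") "-3R"
      else "no-R"
    rows[[i]] <- data.frame(
      accession = acc, sequence = sequence, location_label = loc,
      type = ty, has_presequence = TRUE, imet_removed = FALSE,
      mpp_site = mpp_site, mpp_class = mpp_class, icp55_removed = icp_removed,
      oct1_removed_len = oct_len, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$description <- "synthetic protein"
  class(out) <- c("sim_proteome", "data.frame")
  out
}

.GENOTYPES <- c("WT", "delta_icp55", "delta_oct1")

#' Simulate the processing cascade of one protein under a genotype
#'
#' Returns the N-terminal species of the protein and their relative
#' abundances (summing to 1). The wild type is dominated by the fully
#' processed terminus with a residual intermediate at the leak fraction;
#' knocking out a peptidase swaps dominance to its intermediate.
#' Non-substrates are identical across genotypes. A B13-like MPP-independent
#' OCT1 substrate reverts to its precursor-like terminus (residue 2) in the
#' OCT1 knockout.
#'
#' @param protein One row of a [generate_proteome()] data.frame (or an
#'   equivalent list).
#' @param genotype One of `"WT"`, `"delta_icp55"`, `"delta_oct1"`.
#' @param leak Residual intermediate fraction (default 0.02).
#' @return data.frame with `nterm_position` and `relative_abundance`.
#' @export
simulate_processing <- function(protein, genotype, leak = 0.02) {
  if (!genotype %in% .GENOTYPES)
    stop("unknown genotype '", genotype, "'")
  p <- as.list(protein)
  species <- function(pos, ab) {
    keep <- ab > 0
    data.frame(nterm_position = as.integer(pos[keep]),
               relative_abundance = ab[keep] / sum(ab[keep]))
  }
  if (!isTRUE(p$has_presequence))
    return(species(if (isTRUE(p$imet_removed)) 2L else 1L, 1))
  if (p$type == "icp55") {
    int <- p$mpp_site
    mat <- int + nchar(p$icp55_removed)
    if (genotype == "delta_icp55") species(c(int, mat), c(1 - leak, leak))
    else species(c(int, mat), c(leak, 1 - leak))
  } else if (p$type == "oct1") {
    if (is.na(p$mpp_site)) {
      # matured by OCT1 alone from residue 2; knockout stays precursor-like
      mat <- 2L + p$oct1_removed_len
      if (genotype == "delta_oct1") species(2L, 1)
      else species(c(2L, mat), c(leak, 1 - leak))
    } else {
      int <- p$mpp_site
      mat <- int + p$oct1_removed_len
      if (genotype == "delta_oct1") species(c(int, mat), c(1 - leak, leak))
      else species(c(int, mat), c(leak, 1 - leak))
    }
  } else {
    species(p$mpp_site, 1)
  }
}

.nterm_peptide <- function(sequence, start, min_len = 7, max_len = 45) {
  n <- nchar(sequence)
  if (start + min_len - 1L > n) return(NULL)
  chars <- strsplit(substr(sequence, start, min(n, start + max_len - 1L)),
                    "")[[1]]
  r_at <- which(chars == "R")
  r_at <- r_at[r_at >= min_len]
  end_off <- if (length(r_at) > 0L) r_at[1] else length(chars)
  substr(sequence, start, start + end_off - 1L)
}

#' Simulate a quantified N-terminal peptide table for one comparison
#'
#' For every protein, processing is simulated under the wild type and the
#' mutant; every observed terminus yields one N-terminal peptide ending at
#' the first arginine at or beyond the minimum length (ArgC-like C-terminal
#' specificity: lysines are dimethyl-blocked). The reported ratio is
#' (mutant abundance)/(wild-type abundance) with log2-normal noise, clipped
#' to the reporting cap; termini absent from one genotype are reported at
#' the cap.
#'
#' @param proteome A [generate_proteome()] data.frame.
#' @param config The [sim_config()] used.
#' @param mutant `"delta_icp55"` or `"delta_oct1"`.
#' @param comparison_id Label written into the `comparison_id` column.
#' @param seed Optional seed for the noise draws (NULL leaves the RNG
#'   stream untouched).
#' @return Peptide data.frame sorted by accession then start, with mapped
#'   `start`/`end` coordinates.
#' @export
simulate_observations <- function(proteome, config, mutant,
                                  comparison_id = mutant, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!mutant %in% c("delta_icp55", "delta_oct1"))
    stop("mutant must be delta_icp55 or delta_oct1")
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", nrow(proteome))
  for (i in seq_len(nrow(proteome))) {
    p <- proteome[i, ]
    wt <- simulate_processing(p, "WT", config$leak)
    mu <- simulate_processing(p, mutant, config$leak)
    pos <- sort(union(wt$nterm_position, mu$nterm_position))
    ab_wt <- wt$relative_abundance[match(pos, wt$nterm_position)]
    ab_mu <- mu$relative_abundance[match(pos, mu$nterm_position)]
    ab_wt[is.na(ab_wt)] <- 0
    ab_mu[is.na(ab_mu)] <- 0
    out <- vector("list", length(pos))
    for (k in seq_along(pos)) {
      pep <- .nterm_peptide(p$sequence, pos[k], config$peptide_min,
                            config$peptide_max)
      if (is.null(pep)) next
      if (ab_wt[k] == 0) {
        ratio <- config$ratio_cap
      } else if (ab_mu[k] == 0) {
        ratio <- 1 / config$ratio_cap
      } else {
        ratio <- (ab_mu[k] / ab_wt[k]) *
          2^stats::rnorm(1L, 0, config$ratio_noise_sd)
        ratio <- min(max(ratio, 1 / config$ratio_cap), config$ratio_cap)
      }
      out[[k]] <- data.frame(
        accession = p$accession, peptide = pep, start = pos[k],
        end = pos[k] + nchar(pep) - 1L, nterm_mod = "dimethyl",
        comparison_id = comparison_id, ratio_mut_over_wt = ratio,
        confidence = TRUE, stringsAsFactors = FALSE)
    }
    rows[[i]] <- do.call(rbind, out)
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$accession, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Simulate a complete study
#'
#' One proteome and the three knockout/wild-type comparisons (`icp55`,
#' `oct1_1`, `oct1_2`; the two OCT1 lines share the genotype but draw
#' independent noise). Comparison seeds are derived from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `proteome`, `peptides` (all comparisons bound
#'   together), and `localization` (accession -> label).
#' @export
simulate_dataset <- function(config) {
  proteome <- generate_proteome(config)
  base <- config$seed %% 100000L
  peptides <- rbind(
    simulate_observations(proteome, config, "delta_icp55", "icp55",
                          seed = base * 10L + 1L),
    simulate_observations(proteome, config, "delta_oct1", "oct1_1",
                          seed = base * 10L + 2L),
    simulate_observations(proteome, config, "delta_oct1", "oct1_2",
                          seed = base * 10L + 3L))
  localization <- stats::setNames(proteome$location_label, proteome$accession)
  list(proteome = proteome, peptides = peptides, localization = localization)
}

#' Write a simulated study to disk
#'
#' Proteome as FASTA, peptides as one tab-separated table per comparison,
#' localization and ground truth as tab-separated tables.
#'
#' @param dataset A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sim_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$proteome, file.path(dir, "proteome.fasta"))
  for (cmp in unique(dataset$peptides$comparison_id)) {
    write_peptide_table(
      dataset$peptides[dataset$peptides$comparison_id == cmp, ],
      file.path(dir, paste0("peptides_", cmp, ".tsv")))
  }
  write_localization_table(dataset$localization,
                           file.path(dir, "localization.tsv"))
  truth <- dataset$proteome
  truth$sequence <- NULL
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
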