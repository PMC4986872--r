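test_that("seeded simulation runs are bit-reproducible", {
  cfg <- sim_config(n_proteins = 40, seed = 5)
  expect_identical(simulate_dataset(cfg), simulate_dataset(cfg))
  expect_identical(generate_proteome(cfg), generate_proteome(cfg))
})

test_that("generated proteomes satisfy their ground-truth invariants", {
  cfg <- sim_config(n_proteins = 150, seed = 2)
  prot <- generate_proteome(cfg)
  for (i in seq_len(nrow(prot))) {
    p <- prot[i, ]
    chars <- strsplit(p$sequence, "")[[1]]
    if (!is.na(p$mpp_site)) {
      expect_lte(p$mpp_site, nchar(p$sequence))
      if (p$mpp_class == "-2R") expect_equal(chars[p$mpp_site - 2], "R")
      if (p$mpp_class == "-3R") expect_equal(chars[p$mpp_site - 3], "R")
      if (p$icp55_removed != "")
        expect_equal(substr(p$sequence, p$mpp_site,
                            p$mpp_site + nchar(p$icp55_removed) - 1),
                     p$icp55_removed)
    }
    if (p$type == "icp55") {
      st <- stability_table()
      expect_equal(unname(st[substr(p$icp55_removed, 1, 1)]), "unstable")
    }
  }
  # substrate fractions behave binomially
  cfg2 <- sim_config(n_proteins = 2000, seed = 9)
  prot2 <- generate_proteome(cfg2)
  expect_lt(abs(mean(prot2$type == "icp55") - 0.5), 0.03)
})

test_that("processing cascades respond to genotype as designed", {
  prot <- data.frame(accession = "S1", sequence = strrep("MASRTLFSST", 20),
                     location_label = "mitochondrial", type = "icp55",
                     has_presequence = TRUE, imet_removed = FALSE,
                     mpp_site = 44L, mpp_class = "-2R", icp55_removed = "F",
                     oct1_removed_len = 0L, stringsAsFactors = FALSE)
  wt <- simulate_processing(prot, "WT")
  mu <- simulate_processing(prot, "delta_icp55")
  expect_equal(wt$nterm_position[which.max(wt$relative_abundance)], 45L)
  expect_equal(mu$nterm_position[which.max(mu$relative_abundance)], 44L)
  expect_equal(sum(wt$relative_abundance), 1)
  # B13-like: no MPP site, matured by OCT1 alone; knockout is precursor-like
  b13 <- prot
  b13$type <- "oct1"; b13$icp55_removed <- ""; b13$mpp_site <- NA_integer_
  b13$oct1_removed_len <- 19L
  ko <- simulate_processing(b13, "delta_oct1")
  expect_equal(ko$nterm_position, 2L)
  expect_equal(ko$relative_abundance, 1)
  # non-substrates are identical across genotypes
  none <- prot; none$type <- "none"; none$icp55_removed <- ""
  for (g in c("WT", "delta_icp55", "delta_oct1"))
    expect_equal(simulate_processing(none, g),
                 simulate_processing(none, "WT"))
  expect_error(simulate_processing(prot, "delta_mpp"), "unknown genotype")
})

test_that("observed ratios follow the abundance model, noise and cap", {
  cfg0 <- sim_config(n_proteins = 30, ratio_noise_sd = 0, seed = 4,
                     fraction_icp55_substrate = 0, fraction_oct1_substrate = 0)
  ds0 <- simulate_dataset(cfg0)
  # without noise, non-differential termini report ratio exactly 1
  expect_true(all(ds0$peptides$ratio_mut_over_wt == 1))

  # a terminus absent from one channel is reported exactly at the cap
  cfgc <- sim_config(n_proteins = 60, fraction_oct1_substrate = 1,
                     fraction_icp55_substrate = 0,
                     mpp_independent_prob = 1, seed = 6)
  dsc <- simulate_dataset(cfgc)
  oct <- dsc$peptides[dsc$peptides$comparison_id == "oct1_1", ]
  mature_rows <- oct[oct$start > 2, ]
  expect_true(all(mature_rows$ratio_mut_over_wt == 1 / cfgc$ratio_cap))

  # the log-normal tail keeps false differentials vanishingly rare
  cfg <- sim_config(n_proteins = 1000, ratio_noise_sd = 0.2, seed = 8,
                    fraction_icp55_substrate = 0, fraction_oct1_substrate = 0)
  ds <- simulate_dataset(cfg)
  icp <- ds$peptides[ds$peptides$comparison_id == "icp55", ]
  expect_lt(mean(icp$ratio_mut_over_wt >= 3), 0.001)
})

test_that("every reported peptide start is a simulated terminus", {
  cfg <- sim_config(n_proteins = 50, seed = 12)
  ds <- simulate_dataset(cfg)
  termini <- new.env()
  for (i in seq_len(nrow(ds$proteome))) {
    p <- ds$proteome[i, ]
    pos <- unique(unlist(lapply(c("WT", "delta_icp55", "delta_oct1"),
                                function(g)
                                  simulate_processing(p, g,
                                                      cfg$leak)$nterm_position)))
    assign(p$accession, pos, envir = termini)
  }
  ok <- vapply(seq_len(nrow(ds$peptides)), function(i)
    ds$peptides$start[i] %in% get(ds$peptides$accession[i], envir = termini),
    logical(1))
  expect_true(all(ok))
  # peptides are consistent substrings of their proteins
  seqs <- setNames(ds$proteome$sequence, ds$proteome$accession)
  same <- vapply(seq_len(nrow(ds$peptides)), function(i)
    substr(seqs[[ds$peptides$accession[i]]], ds$peptides$start[i],
           ds$peptides$end[i]) == ds$peptides$peptide[i], logical(1))
  expect_true(all(same))
})

test_that("simulated studies round-trip through the standard file formats", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_proteins = 25, seed = 13)
  ds <- simulate_dataset(cfg)
  write_sim_dataset(ds, dir)
  prot <- read_fasta(file.path(dir, "proteome.fasta"))
  expect_equal(prot$sequence, ds$proteome$sequence)
  loc <- read_localization_table(file.path(dir, "localization.tsv"))
  expect_equal(loc[names(ds$localization)], ds$localization)
  pep <- read_peptide_table(file.path(dir, "peptides_icp55.tsv"))
  orig <- ds$peptides[ds$peptides$comparison_id == "icp55", ]
  rownames(orig) <- NULL
  expect_equal(pep$peptides[names(orig)], orig)
  expect_equal(nrow(pep$rejected), 0L)
})
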