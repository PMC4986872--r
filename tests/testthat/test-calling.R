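pep_row <- function(acc, peptide, start, ratio, comparison = "icp55") {
  data.frame(accession = acc, peptide = peptide, start = start,
             end = start + nchar(peptide) - 1L, nterm_mod = "dimethyl",
             comparison_id = comparison, ratio_mut_over_wt = ratio,
             confidence = TRUE, stringsAsFactors = FALSE)
}

test_that("candidate terminus pairing enumerates ordered offsets", {
  p <- rbind(pep_row("A", "FSTPSDLDSELTR", 44L, 60),
             pep_row("A", "STPSDLDSELTR", 45L, 0.02))
  pairs <- pair_candidate_termini(p, 2)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$offset, 1L)

  p3 <- rbind(pep_row("A", "FTSEAAADGGQDQILSR", 38L, 100),
              pep_row("A", "TSEAAADGGQDQILSR", 39L, 0.1),
              pep_row("A", "SEAAADGGQDQILSR", 40L, 0.01))
  pairs3 <- pair_candidate_termini(p3, 2)
  expect_equal(nrow(pairs3), 3L)
  expect_setequal(pairs3$offset, c(1L, 2L, 1L))

  expect_equal(nrow(pair_candidate_termini(p[1, ], 2)), 0L)
})

oxa1_protein <- data.frame(
  accession = "OXA1", description = "",
  sequence = paste0("MLRSALSSRLAASSNPNLLRSASTSSS", strrep("SAR", 5), "G",
                    "FSTPSDLDSELTR", "AEGVKDEPNNKR"),
  stringsAsFactors = FALSE)

test_that("paired evidence calls the substrate and infers the removed residue", {
  peps <- rbind(pep_row("OXA1", "FSTPSDLDSELTR", 44L, 60),
                pep_row("OXA1", "STPSDLDSELTR", 45L, 0.02))
  calls <- call_icp55(peps, oxa1_protein)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$evidence, "paired")
  expect_equal(calls$removed, "F")
  expect_equal(calls$tier, "primary")
  expect_equal(calls$mature_start, 45L)
})

test_that("a pair qualifies from the downregulated mature terminus alone", {
  protein <- data.frame(
    accession = "BIO2", description = "",
    sequence = paste0(strrep("MASTL", 5), "YSSLSAASAEAER", "GDKVVR"),
    stringsAsFactors = FALSE)
  peps <- rbind(pep_row("BIO2", "YSSLSAASAEAER", 26L, 1.0),
                pep_row("BIO2", "SSLSAASAEAER", 27L, 0.01))
  calls <- call_icp55(peps, protein)
  expect_equal(calls$evidence, "paired")
  expect_equal(calls$removed, "Y")
  expect_equal(calls$tier, "primary")
})

test_that("single-terminus rules gate on N-end-rule stability", {
  protein <- data.frame(accession = "A", description = "",
                        sequence = paste0(strrep("MSTAL", 4), "Y",
                                          "ASSTVLDKGSGR", "GDKVVR"),
                        stringsAsFactors = FALSE)
  # lone upregulated peptide starting with a stable residue: no call
  up_stable <- pep_row("A", "ASSTVLDKGSGR", 22L, 5)
  expect_equal(nrow(call_icp55(up_stable, protein)), 0L)
  # lone downregulated peptide preceded by an unstable Y: called
  down <- pep_row("A", "ASSTVLDKGSGR", 22L, 0.2)
  calls <- call_icp55(down, protein)
  expect_equal(calls$evidence, "single_down")
  expect_equal(calls$removed, "Y")
  expect_equal(calls$tier, "primary")
  # no preceding residue at start 1: skipped with a diagnostic
  at1 <- pep_row("A", substr(protein$sequence, 1, 12), 1L, 0.1)
  expect_message(res <- call_icp55(at1, protein), "residue 1")
  expect_equal(nrow(res), 0L)
})

test_that("raising the primary threshold never adds a primary call", {
  ds <- simulate_dataset(sim_config(n_proteins = 80, seed = 11))
  p3 <- call_icp55(ds$peptides, ds$proteome, primary_fold = 3)
  p5 <- call_icp55(ds$peptides, ds$proteome, primary_fold = 5)
  prim3 <- p3$accession[p3$tier == "primary"]
  prim5 <- p5$accession[p5$tier == "primary"]
  expect_true(all(prim5 %in% prim3))
})

test_that("the caller agrees with a brute-force oracle on small peptide sets", {
  st <- stability_table()
  for (seed in 1:150) {
    case <- random_case(seed)
    prot <- data.frame(accession = "CASE", description = "",
                       sequence = case$sequence, stringsAsFactors = FALSE)
    got <- suppressMessages(call_icp55(case$peptides, prot, stability = st))
    want <- oracle_call_icp55(case$peptides, case$sequence, st)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L, info = paste("seed", seed))
    } else {
      expect_equal(nrow(got), 1L, info = paste("seed", seed))
      expect_equal(got$evidence, want$evidence, info = paste("seed", seed))
      expect_equal(got$removed, want$removed, info = paste("seed", seed))
      expect_equal(got$tier, want$tier, info = paste("seed", seed))
      expect_equal(got$intermediate_start, as.integer(want$intermediate),
                   info = paste("seed", seed))
    }
  }
})

test_that("removed residues always equal the spanned protein subsequence", {
  fx <- fixture_study()
  mapped <- map_peptides_to_proteins(fx$peptides, fx$proteins)$mapped
  calls <- call_icp55(mapped, fx$proteins,
                      stability = stability_table(extra_unstable = c("M", "C")))
  seqs <- setNames(fx$proteins$sequence, fx$proteins$accession)
  for (i in seq_len(nrow(calls))) {
    expect_equal(calls$removed[i],
                 substr(seqs[[calls$accession[i]]],
                        calls$intermediate_start[i],
                        calls$mature_start[i] - 1L))
  }
})

test_that("OCT1 calls honour supporting-line counts and infer long removals", {
  fx <- fixture_study()
  mapped <- map_peptides_to_proteins(fx$peptides, fx$proteins)$mapped
  calls <- call_oct1(mapped, fx$proteins)
  expect_equal(nrow(calls), 7L)
  b13 <- calls[calls$accession == "AT5G52840", ]
  expect_equal(b13$evidence, "single_down")
  expect_equal(b13$comparisons_supporting, "oct1_1,oct1_2")
  pmh1 <- calls[calls$accession == "AT3G22310", ]
  expect_equal(pmh1$comparisons_supporting, "oct1_2")
  pmh2 <- calls[calls$accession == "AT3G22330", ]
  expect_equal(pmh2$evidence, "paired")
  expect_equal(nchar(pmh2$removed), pmh2$mature_start - pmh2$intermediate_start)
  # strict mode requires both knockout lines
  strict <- call_oct1(mapped, fx$proteins, min_lines = 2)
  expect_false("AT3G22310" %in% strict$accession)
  expect_false("AT3G48110" %in% strict$accession)
  expect_equal(nrow(strict), 5L)
  # weak regulation in both lines is no call
  weak <- rbind(pep_row("AT5G52840", "AKVKQTTGIVGLDVVPNAR", 22L, 1.2, "oct1_1"),
                pep_row("AT5G52840", "AKVKQTTGIVGLDVVPNAR", 22L, 1.4, "oct1_2"))
  expect_equal(nrow(call_oct1(weak, fx$proteins)), 0L)
})

test_that("sequential-cleavage ladders are detected with their residue path", {
  fx <- fixture_study()
  seqs <- setNames(fx$proteins$sequence, fx$proteins$accession)
  acp3 <- fx$proteins[fx$proteins$accession == "AT5G47630", ]
  s0 <- locate_peptide(acp3$sequence, "FTSEAAADGGQDQILSR")
  peps <- rbind(
    pep_row("AT5G47630", "FTSEAAADGGQDQILSR", s0, 100),
    pep_row("AT5G47630", "TSEAAADGGQDQILSR", s0 + 1L, 0.1),
    pep_row("AT5G47630", "SEAAADGGQDQILSR", s0 + 2L, 0.01))
  lad <- detect_ladders(peps, fx$proteins, comparison = "icp55")
  expect_equal(nrow(lad), 1L)
  expect_equal(lad$n_termini, 3L)
  expect_equal(lad$removed_path, "FT")
  # large gaps break the chain
  sparse <- rbind(pep_row("A", strrep("S", 10), 10L, 10),
                  pep_row("A", strrep("S", 10), 30L, 1),
                  pep_row("A", strrep("S", 10), 50L, 0.1))
  expect_equal(nrow(detect_ladders(sparse)), 0L)
  # the five-terminus OCT1 ladder
  mapped <- map_peptides_to_proteins(fx$peptides, fx$proteins)$mapped
  lad2 <- detect_ladders(mapped, fx$proteins, comparison = "oct1_2")
  pmh2 <- lad2[lad2$accession == "AT3G22330", ]
  expect_equal(pmh2$n_termini, 5L)
})

test_that("every substrate call survives the curation filters", {
  fx <- fixture_study()
  res <- run_pipeline(fx$peptides, fx$proteins, fx$localization,
                      stability = stability_table(extra_unstable = c("M", "C")))
  kept_acc <- unique(res$curated$kept$accession)
  expect_true(all(res$calls_icp55$accession %in% kept_acc))
  expect_true(all(res$calls_oct1$accession %in% kept_acc))
})
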