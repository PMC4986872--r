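test_that("window extraction pads short presequences and sequence ends", {
  seq200 <- paste(rep("ARNDCEQGHILKMFPSTWYV", 10), collapse = "")
  w <- extract_window(seq200, 45)
  expect_equal(nchar(w), 30L)
  expect_equal(w, paste0(substr(seq200, 25, 44), substr(seq200, 45, 54)))
  # mature start 8: 13 leading pads, residues 1..7, then 8..17
  w2 <- extract_window(seq200, 8)
  expect_equal(w2, paste0(strrep("-", 13), substr(seq200, 1, 7),
                          substr(seq200, 8, 17)))
  # mature start 2 of a 5-residue protein
  w3 <- extract_window("MSTAV", 2)
  expect_equal(w3, paste0(strrep("-", 19), "M", "STAV", strrep("-", 6)))
  expect_error(extract_window("MSTAV", 6), "outside")
})

test_that("position frequency matrices are column-stochastic and ignore pads", {
  w1 <- paste0(strrep("-", 18), "RA", "SSTTTTTTTT")
  w2 <- paste0(strrep("-", 18), "RS", "SATTTTTTTT")
  pfm <- build_pfm(c(w1, w2))
  expect_equal(pfm$freq["R", "-2"], 1)
  expect_equal(pfm$n[["-3"]], 0L)
  expect_true(is.na(pfm$freq["R", "-3"]))
  sums <- colSums(pfm$counts) / pmax(pfm$n, 1)
  expect_true(all(abs(colSums(pfm$freq)[pfm$n > 0] - 1) < 1e-9))
  # a single window gives frequencies in {0, 1}
  pfm1 <- build_pfm(w1)
  expect_true(all(pfm1$freq[!is.na(pfm1$freq)] %in% c(0, 1)))
  # permuting window order leaves the profile unchanged
  expect_equal(build_pfm(c(w2, w1))$counts, pfm$counts)
})

test_that("iceLogo differentials match an independent proportion oracle", {
  # 88 windows, 44 with R at -3 (f_obs 0.5) against a 5% reference
  win <- c(replicate(44, paste0(strrep("A", 17), "R", "AA", strrep("S", 10))),
           replicate(44, paste0(strrep("A", 17), "G", "AA", strrep("S", 10))))
  pfm <- build_pfm(win)
  ref <- setNames(rep(0.05, 20), AA_STANDARD)
  prof <- icelogo_diff(pfm, ref)
  expect_equal(prof$difference["R", "-3"], 45)
  expect_lt(prof$p_value["R", "-3"], 1e-10)
  expect_equal(prof$z["R", "-3"], (0.5 - 0.05) / sqrt(0.05 * 0.95 / 88))
  # every defined cell agrees with the naive binomial-approximation oracle
  for (res in c("R", "G", "A", "S")) {
    for (pos in c("-3", "-1", "5")) {
      expect_equal(prof$p_value[res, pos],
                   oracle_prop_p(pfm$counts[res, pos], 88, 0.05))
    }
  }
  # identical observed and reference frequencies: zero difference, no signal
  ref_a <- setNames(rep(0, 20), AA_STANDARD); ref_a["A"] <- 1 - 1e-12
  ref_a["C"] <- 1e-12
  prof_a <- icelogo_diff(build_pfm(replicate(10, strrep("A", 30))), ref_a)
  expect_equal(max(abs(prof_a$difference["A", ])), 0, tolerance = 1e-6)
  expect_false(any(prof_a$significant["A", ]))
})

test_that("significance is monotone in the number of windows", {
  win <- c(replicate(3, paste0(strrep("A", 19), "R", strrep("S", 10))),
           replicate(4, paste0(strrep("A", 19), "G", strrep("S", 10))))
  ref <- setNames(rep(0.05, 20), AA_STANDARD)
  small <- icelogo_diff(build_pfm(win), ref)
  big <- icelogo_diff(build_pfm(rep(win, 2)), ref)
  sig_small <- small$significant & small$difference > 0
  sig_big <- big$significant & big$difference > 0
  expect_true(all(sig_big[sig_small]))
})

test_that("consensus strings render dominant residues and fall back to X", {
  arrow <- "\u2193"
  win <- vapply(seq_len(10), function(i) {
    minus1 <- if (i <= 6) "F" else "Y"
    plus1 <- if (i <= 6) "S" else "A"
    plus2 <- if (i <= 6) "S" else "T"
    minus2 <- AA_STANDARD[i]  # varied: stays below the frequency threshold
    paste0(strrep("A", 17), "R", minus2, minus1, plus1, plus2, strrep("G", 8))
  }, character(1))
  pfm <- build_pfm(win)
  cons <- consensus_string(pfm, require_significant = FALSE)
  expect_equal(as.character(cons), paste0("RX(F/Y)", arrow, "(S/A)(S/T)"))
  # a uniform profile renders all-X
  uni <- vapply(1:20, function(i) strrep(AA_STANDARD[i], 30), character(1))
  cons_uni <- consensus_string(build_pfm(uni), require_significant = FALSE)
  expect_equal(as.character(cons_uni), paste0("XXX", arrow, "XX"))
  # the significance gate needs annotations
  expect_error(consensus_string(pfm, require_significant = TRUE), "icelogo")
})

test_that("planted cleavage motifs are recovered from simulated substrates", {
  hits <- 0L
  for (seed in 1:50) {
    cfg <- sim_config(n_proteins = 50, seed = 1000L + seed)
    prot <- generate_proteome(cfg)
    sub <- prot[prot$type == "icp55", ]
    win <- vapply(seq_len(nrow(sub)), function(i)
      extract_window(sub$sequence[i],
                     sub$mpp_site[i] + nchar(sub$icp55_removed[i])),
      character(1))
    prof <- icelogo_diff(build_pfm(win), reference_frequencies(prot))
    per <- attr(consensus_string(prof), "per_position")
    ok <- identical(per[["-3"]], "R") &&
      length(per[["-1"]]) > 0 && all(per[["-1"]] %in% c("F", "Y", "L", "I"))
    if (ok) hits <- hits + 1L
  }
  expect_gte(hits, 48L)
})
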